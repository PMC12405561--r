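#' Component vocabulary for harmonized NPP records
#'
#' The controlled vocabulary of biomass-production components used throughout
#' the package. Source labels are harmonized onto this closed set; the original
#' label is kept verbatim in the `original_label` column of the NPP estimates
#' table.
#'
#' @return Character vector of component codes.
#' @export
#' @examples
#' npp_components()
npp_components <- function() {
  c(
    "stem", "branch", "foliage_litter", "extra_litter", "reproductive",
    "herb", "shrub", "non_vascular", "understory",
    "fine_root", "coarse_root",
    "herbivory", "tropical_leaf_decomposition", "voc_exudates_symbionts",
    "total_npp"
  )
}

#' Measurement-method catalogue with uncertainty reduction factors
#'
#' One row per accepted field method for measuring NPP, with its scope
#' (aboveground, belowground or total) and its dimensionless reduction factor
#' RF in (0, 1]. The RF shrinks the biome-level spread of a component class
#' into a per-measurement uncertainty: the more direct and complete the
#' method, the smaller the RF. Seven aboveground, eight belowground and four
#' total-NPP methods are catalogued; any other method is outside the
#' harmonization's accepted set.
#'
#' @return A tibble with columns `method_id`, `name`, `scope`, `rf`.
#' @export
#' @examples
#' npp_method_catalog()
npp_method_catalog <- function() {
  tibble::tribble(
    ~method_id, ~name, ~scope, ~rf,
    "AG1", "Isotope turnover", "aboveground", 0.1,
    "AG2", "Sum of increments in live biomass adjusted for decomposition", "aboveground", 0.2,
    "AG3", "Sum of increments in live biomass", "aboveground", 0.3,
    "AG4", "Peak standing crop", "aboveground", 0.4,
    "AG5", "Maximum minus minimum live biomass", "aboveground", 0.4,
    "AG6", "Allometric/biometric methods", "aboveground", 0.4,
    "AG7", "Fixed proportion of other NPP component", "aboveground", 0.8,
    "BG1", "Isotope turnover", "belowground", 0.2,
    "BG2", "Minirhizotron or root window (fine roots)", "belowground", 0.3,
    "BG3", "Ingrowth core (fine roots)", "belowground", 0.3,
    "BG4", "Allometric relations (coarse roots)", "belowground", 0.6,
    "BG5", "Carbon budget and mass balance (all roots)", "belowground", 0.6,
    "BG6", "Sequential coring, with sum of increments in live and dead biomass (fine roots)", "belowground", 0.7,
    "BG7", "Sequential biomass coring (fine roots)", "belowground", 0.8,
    "BG8", "Fixed proportion of other NPP component (coarse roots)", "belowground", 0.9,
    "TO1", "Radiocarbon", "total", 0.6,
    "TO2", "Peat formation in peatlands", "total", 0.6,
    "TO3", "Process-based model", "total", 0.6,
    "TO4", "Flux components, incl. eddy covariance measurements", "total", 1.0
  )
}

#' @keywords internal
npp_biomes <- function() {
  c("forest", "grassland", "cropland", "tundra", "peatland", "dry_shrubland")
}

#' @keywords internal
npp_climate_regions <- function() {
  c("tropical", "arid", "temperate", "cold", "polar")
}

# Scope each component can legitimately be measured under. VOC / exudates /
# transfer-to-symbionts entries occur on either side of the soil surface.
component_scope_table <- function() {
  tibble::tibble(
    component = npp_components(),
    scope = c(
      "aboveground", "aboveground", "aboveground", "aboveground", "aboveground",
      "aboveground", "aboveground", "aboveground", "aboveground",
      "belowground", "belowground",
      "aboveground", "aboveground", "any",
      "total"
    )
  )
}

#' Resolve a site to its component-expectation ecosystem type
#'
#' Sites are matched to one row of the main/minor component-expectation table
#' (see [component_expectations()]) from their biome, climate region and two
#' refinements: whether a forest is a plantation managed for fruit production,
#' and whether a tundra/peatland site carries substantial non-vascular
#' vegetation.
#'
#' @param biome One of `npp_biomes()`.
#' @param climate_region One of `npp_climate_regions()`, or `NA`.
#' @param fruit_plantation Logical; forest plantation managed for fruit
#'   production.
#' @param substantial_non_vascular Logical; tundra/peatland with substantial
#'   moss/lichen cover.
#' @return A single ecosystem-type code (character).
#' @export
ecosystem_type <- function(biome, climate_region = NA_character_,
                           fruit_plantation = FALSE,
                           substantial_non_vascular = FALSE) {
  stopifnot(length(biome) == 1L)
  if (!biome %in% npp_biomes()) {
    stop("unknown biome: ", biome, call. = FALSE)
  }
  if (biome == "forest") {
    if (isTRUE(fruit_plantation)) return("fruit_plantation")
    if (isTRUE(climate_region == "tropical")) return("tropical_forest")
    if (isTRUE(climate_region %in% c("cold", "polar"))) return("boreal_forest")
    return("other_forest")
  }
  if (biome %in% c("tundra", "peatland")) {
    if (isTRUE(substantial_non_vascular)) return("peatland_tundra_nonvascular")
    return("peatland_tundra")
  }
  if (biome == "dry_shrubland") return("woodland_savanna_shrubland")
  biome # grassland, cropland
}

#' Main and minor NPP components expected per ecosystem type
#'
#' The completeness contract used by [completeness_audit()]: per ecosystem
#' type, which components are main (a site missing one should be excluded from
#' harmonized analyses) and which are minor (missing ones are informational
#' only). For woody ecosystems coarse roots are minor even when substantial,
#' because they are almost always derived from aboveground components rather
#' than measured.
#'
#' @return A tibble with columns `ecosystem_type`, `component`, `class`
#'   (`"main"` or `"minor"`).
#' @export
component_expectations <- function() {
  spec <- list(
    boreal_forest = list(
      main = c("stem", "foliage_litter", "understory", "fine_root"),
      minor = c("reproductive", "herbivory", "coarse_root")
    ),
    tropical_forest = list(
      main = c("stem", "foliage_litter", "fine_root"),
      minor = c("understory", "reproductive", "herbivory",
                "tropical_leaf_decomposition", "coarse_root")
    ),
    other_forest = list(
      main = c("stem", "foliage_litter", "fine_root"),
      minor = c("understory", "reproductive", "herbivory", "coarse_root")
    ),
    fruit_plantation = list(
      main = c("stem", "foliage_litter", "reproductive", "fine_root"),
      minor = c("understory", "herbivory", "coarse_root")
    ),
    grassland = list(
      main = c("herb", "fine_root"),
      minor = c("stem", "foliage_litter", "herbivory")
    ),
    cropland = list(
      main = c("herb", "fine_root"),
      minor = c("stem", "foliage_litter", "herbivory")
    ),
    peatland_tundra = list(
      main = c("herb", "shrub", "fine_root"),
      minor = c("stem", "foliage_litter", "non_vascular", "reproductive",
                "herbivory", "coarse_root")
    ),
    peatland_tundra_nonvascular = list(
      main = c("herb", "shrub", "non_vascular", "fine_root"),
      minor = c("stem", "foliage_litter", "reproductive", "herbivory",
                "coarse_root")
    ),
    woodland_savanna_shrubland = list(
      main = c("herb", "stem", "foliage_litter", "fine_root"),
      minor = c("herbivory", "coarse_root")
    )
  )
  purrr::imap_dfr(spec, function(x, nm) {
    tibble::tibble(
      ecosystem_type = nm,
      component = c(x$main, x$minor),
      class = rep(c("main", "minor"), c(length(x$main), length(x$minor)))
    )
  })
}
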