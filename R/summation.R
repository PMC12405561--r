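#' @keywords internal
npp_levels <- function() {
  c("herb_shrub_anpp", "non_tree_anpp", "wood_anpp", "total_litterfall_anpp",
    "tree_anpp", "bnpp", "total_npp_1", "total_npp_2")
}

tree_components <- function() c("stem", "branch", "foliage_litter", "extra_litter")

# biomes where a tree layer is not expected; their tree branch is
# not_applicable unless a tree component is actually reported
treeless_biomes <- function() c("grassland", "cropland", "tundra", "peatland")

#' Hierarchical summation levels for one site
#'
#' Computes the eight gated aggregates of the component hierarchy:
#' herb+shrub ANPP, non-tree ANPP, wood ANPP, total litterfall ANPP,
#' tree ANPP, BNPP, total NPP 1 and total NPP 2. A level is `complete` (and
#' carries a value) only when every constituent component is either measured
#' or verified absent at the site; otherwise it is `incomplete` and no value
#' is emitted. A level all of whose constituents are absent — or, for the tree
#' branch in treeless biomes, simply not reported — is `not_applicable` and
#' contributes zero to the levels above it.
#'
#' Gating rules: understory measurements satisfy both the herb and the shrub
#' slot of the non-tree branch (overstory = tree ANPP). In non-forested biomes
#' coarse roots are assumed to be contained in the fine-root estimate and are
#' auto-flagged absent. Total NPP 2 adds herbivory, reproductive material
#' (unless reported inside extra litter, `in_litterfall`) and — for tropical
#' forests only — leaf litter lost to rapid decomposition. Reproductive
#' material reported both inside litterfall and as a separate entry raises a
#' double-count error.
#'
#' @param records Tibble of one site's harmonized records with columns
#'   `component`, `value`, and optionally `component_absent` (logical) and
#'   `in_litterfall` (logical, for reproductive material).
#' @param biome One of [npp_biomes()].
#' @param climate_region Optional climate region; `"tropical"` switches on the
#'   tropical-forest leaf-decomposition term.
#' @param mixed_campaign Logical; set when the site's components were measured
#'   in different years or with different methods, in which case every level
#'   is stamped with a `mixed_campaign` provenance flag (values are still
#'   computed on the site-mean view).
#' @return Tibble with columns `level`, `value`, `status`
#'   (`complete`/`incomplete`/`not_applicable`) and `provenance`.
#' @export
compute_levels <- function(records, biome, climate_region = NA_character_,
                           mixed_campaign = FALSE) {
  if (!biome %in% npp_biomes()) stop("unknown biome: ", biome, call. = FALSE)
  if (!"component_absent" %in% names(records)) records$component_absent <- FALSE
  if (!"in_litterfall" %in% names(records)) records$in_litterfall <- FALSE
  records$component_absent[is.na(records$component_absent)] <- FALSE
  records$in_litterfall[is.na(records$in_litterfall)] <- FALSE

  rep_rec <- records[records$component == "reproductive", , drop = FALSE]
  if (nrow(rep_rec) && any(rep_rec$in_litterfall) && any(!rep_rec$in_litterfall)) {
    stop("reproductive material counted both in litterfall and separately",
         call. = FALSE)
  }
  reproductive_in_litterfall <- nrow(rep_rec) > 0 && all(rep_rec$in_litterfall)

  # component status: measured / absent / unknown, value = site mean
  comp <- records |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(
      status = dplyr::if_else(all(.data$component_absent), "absent", "measured"),
      value = dplyr::if_else(
        all(.data$component_absent), 0,
        mean(.data$value[!.data$component_absent])
      ),
      .groups = "drop"
    )
  status_of <- function(x) {
    s <- comp$status[match(x, comp$component)]
    s[is.na(s)] <- "unknown"
    s
  }
  value_of <- function(x) {
    v <- comp$value[match(x, comp$component)]
    v[is.na(v) & status_of(x) == "absent"] <- 0
    v
  }

  # Applicability adjustments, each treated like a verified absence for
  # gating but remembered so an all-auto level reads not_applicable:
  #  - non-forested biomes: all roots assumed contained in the fine-root
  #    estimate, so an unreported coarse-root component counts as absent;
  #  - treeless biomes (grassland, cropland, tundra, peatland): unreported
  #    tree-layer components are not expected and do not block gating.
  auto_absent <- character(0)
  if (biome != "forest" && status_of("coarse_root") == "unknown") {
    auto_absent <- "coarse_root"
  }
  if (biome %in% treeless_biomes()) {
    unreported <- tree_components()[status_of(tree_components()) == "unknown"]
    auto_absent <- c(auto_absent, unreported)
  }
  status2 <- function(x) {
    s <- status_of(x)
    s[x %in% auto_absent] <- "auto_absent"
    s
  }
  val2 <- function(x) {
    v <- value_of(x)
    v[x %in% auto_absent] <- 0
    v
  }

  understory_measured <- status2("understory") == "measured"

  gate <- function(parts) {
    s <- status2(parts)
    if (all(s %in% c("absent", "auto_absent")) && any(s == "auto_absent")) {
      return("not_applicable")
    }
    if (all(s == "absent")) return("not_applicable")
    if (any(s == "unknown")) return("incomplete")
    "complete"
  }
  level_value <- function(parts, status) {
    if (status != "complete") return(NA_real_)
    sum(val2(parts)[status2(parts) == "measured"])
  }

  # non-tree branch: understory satisfies herb + shrub jointly
  nt_parts <- c("herb", "shrub")
  hs_status <- if (understory_measured) "complete" else gate(nt_parts)
  hs_value <- if (hs_status == "complete") {
    sum(val2(c(nt_parts, "understory"))[status2(c(nt_parts, "understory")) == "measured"])
  } else NA_real_

  ntree_parts <- c("herb", "shrub", "non_vascular")
  nt_status <- if (understory_measured) {
    if (status2("non_vascular") == "unknown") "incomplete"
    else "complete"
  } else gate(ntree_parts)
  nt_value <- if (nt_status == "complete") {
    sum(val2(c(ntree_parts, "understory"))[status2(c(ntree_parts, "understory")) == "measured"])
  } else NA_real_

  wood_status <- gate(c("stem", "branch"))
  wood_value <- level_value(c("stem", "branch"), wood_status)
  litter_status <- gate(c("foliage_litter", "extra_litter"))
  litter_value <- level_value(c("foliage_litter", "extra_litter"), litter_status)
  tree_status <- combine_status(c(wood_status, litter_status))
  tree_value <- if (tree_status == "complete") {
    sum(c(wood_value, litter_value), na.rm = TRUE)
  } else NA_real_

  bnpp_status <- gate(c("fine_root", "coarse_root"))
  bnpp_value <- level_value(c("fine_root", "coarse_root"), bnpp_status)

  t1_status <- combine_status(c(tree_status, nt_status, bnpp_status))
  t1_value <- if (t1_status == "complete") {
    sum(c(tree_value, nt_value, bnpp_value), na.rm = TRUE)
  } else NA_real_

  # extras for total NPP 2
  extras <- "herbivory"
  if (!reproductive_in_litterfall) extras <- c(extras, "reproductive")
  tropical_forest <- biome == "forest" && isTRUE(climate_region == "tropical")
  if (tropical_forest) extras <- c(extras, "tropical_leaf_decomposition")
  ex_status <- status2(extras)
  t2_status <- if (t1_status == "incomplete" || any(ex_status == "unknown")) {
    "incomplete"
  } else if (t1_status == "not_applicable" && all(ex_status == "absent")) {
    "not_applicable"
  } else "complete"
  t2_value <- if (t2_status == "complete") {
    sum(c(t1_value, val2(extras)[ex_status == "measured"]), na.rm = TRUE)
  } else NA_real_

  tibble::tibble(
    level = npp_levels(),
    value = c(hs_value, nt_value, wood_value, litter_value, tree_value,
              bnpp_value, t1_value, t2_value),
    status = c(hs_status, nt_status, wood_status, litter_status, tree_status,
               bnpp_status, t1_status, t2_status),
    provenance = if (isTRUE(mixed_campaign)) "mixed_campaign" else "single_campaign"
  )
}

# status of a parent from its sub-level statuses: any incomplete blocks it;
# all not_applicable stays not_applicable; otherwise complete (n/a parts = 0)
combine_status <- function(parts) {
  if (any(parts == "incomplete")) return("incomplete")
  if (all(parts == "not_applicable")) return("not_applicable")
  "complete"
}

#' Summation levels for every site of a database
#'
#' Applies [compute_levels()] to each site's record set, using the site's
#' stored biome and climate region. Sites whose above- and belowground
#' campaigns differ in measurement years are stamped `mixed_campaign`.
#'
#' @param db An `npp_database`.
#' @return Tibble with one row per site and level: `site_id`, `level`,
#'   `value`, `status`, `provenance`.
#' @export
summarize_levels <- function(db) {
  si <- db$site_information
  recs <- dplyr::group_split(db$npp_estimates, site_id)
  purrr::map_dfr(recs, function(r) {
    sid <- r$site_id[[1]]
    i <- match(sid, si$site_id)
    if (is.na(i)) return(NULL)
    mixed <- dplyr::n_distinct(paste(r$year_start, r$year_end)) > 1
    compute_levels(r, biome = si$biome[[i]],
                   climate_region = si$climate_region[[i]],
                   mixed_campaign = mixed) |>
      dplyr::mutate(site_id = sid, .before = 1)
  })
}

#' Audit a site against its expected main and minor components
#'
#' Looks up the site's ecosystem type in [component_expectations()] and
#' reports which expected main components are neither measured nor verified
#' absent (such a site should be excluded from harmonized analyses) and which
#' minor components are missing (informational). The understory expectation is
#' satisfied by an understory record or by herb and shrub records; coarse
#' roots are auto-satisfied in non-forested biomes.
#'
#' @inheritParams compute_levels
#' @param fruit_plantation,substantial_non_vascular Refinements passed to
#'   [ecosystem_type()].
#' @return List with elements `ecosystem_type`, `missing_main`,
#'   `missing_minor` (character vectors of component codes).
#' @export
completeness_audit <- function(records, biome, climate_region = NA_character_,
                               fruit_plantation = FALSE,
                               substantial_non_vascular = NULL) {
  if (!"component_absent" %in% names(records)) records$component_absent <- FALSE
  records$component_absent[is.na(records$component_absent)] <- FALSE
  present <- unique(records$component)
  if (is.null(substantial_non_vascular)) {
    substantial_non_vascular <- "non_vascular" %in%
      records$component[!records$component_absent]
  }
  etype <- ecosystem_type(biome, climate_region, fruit_plantation,
                          substantial_non_vascular)
  exp <- dplyr::filter(component_expectations(), .data$ecosystem_type == etype)
  satisfied <- function(comp) {
    if (comp == "understory") {
      return("understory" %in% present ||
               all(c("herb", "shrub") %in% present))
    }
    if (comp == "coarse_root" && biome != "forest") return(TRUE)
    comp %in% present
  }
  miss <- exp$component[!purrr::map_lgl(exp$component, satisfied)]
  list(
    ecosystem_type = etype,
    missing_main = intersect(miss, exp$component[exp$class == "main"]),
    missing_minor = intersect(miss, exp$component[exp$class == "minor"])
  )
}
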