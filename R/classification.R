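#' Rule-based biome classification
#'
#' Assigns one of the six biomes from site attributes, following the
#' production-share based definitions: any ecosystem above the treeline is
#' tundra; grain/tuber cropping means cropland; woody-dominated (> 50% of
#' production) ecosystems outside arid climates are forest; herb-dominated
#' ones below the treeline are grassland; shrub/herb co-dominated systems
#' (each < 50%) in cold climate are peatland; dry ecosystems with reduced,
#' patchy vegetation cover are dry shrubland. Transition zones (woody
#' grasslands) resolve to whichever component has the larger production.
#'
#' @param attrs A one-row data frame / list of site attributes:
#'   `woody_production_share`, `herb_production_share` (fractions),
#'   `above_treeline`, `arid_climate`, `crop` (logicals),
#'   `cold_climate` (logical; boreal/hemiboreal),
#'   `vegetation_cover` (`"continuous"`/`"reduced_patchy"`).
#'   Missing attributes are treated as unknown.
#' @return A single biome code, or `"unclassifiable"` with a `reasons`
#'   attribute listing what was missing.
#' @export
#' @examples
#' classify_biome(list(woody_production_share = 0.7, arid_climate = FALSE))
classify_biome <- function(attrs) {
  g <- function(nm, default = NA) {
    v <- attrs[[nm]]
    if (is.null(v) || length(v) == 0 || is.na(v)) default else v
  }
  woody <- g("woody_production_share")
  herb <- g("herb_production_share")
  if (isTRUE(g("above_treeline", FALSE))) return("tundra")
  if (isTRUE(g("crop", FALSE))) return("cropland")
  arid <- isTRUE(g("arid_climate", FALSE))
  cold <- isTRUE(g("cold_climate", FALSE))
  patchy <- identical(g("vegetation_cover"), "reduced_patchy")
  if (!is.na(woody) && woody > 0.5 && !arid) return("forest")
  if (!is.na(herb) && herb > 0.5) return("grassland")
  if (!is.na(woody) && !is.na(herb)) {
    if (cold && woody <= 0.5 && herb <= 0.5) return("peatland")
    if ((arid || patchy) && woody <= 0.5 && herb <= 0.5) return("dry_shrubland")
    # woody-dominated but arid: forests are defined outside arid climates
    if (woody > 0.5 && arid) return("dry_shrubland")
    # transition zone: larger production share decides
    return(if (woody >= herb) "forest" else "grassland")
  }
  reasons <- c(
    if (is.na(woody)) "woody_production_share missing",
    if (is.na(herb)) "herb_production_share missing"
  )
  structure("unclassifiable", reasons = reasons)
}

#' Rule-based management classification
#'
#' Classifies a site as managed or unmanaged given its biome. Forests are
#' managed when thinned or harvested within 50 years, fertilized within 25
#' years, newly (< 10 years) established plantations, or managed for
#' fruit/rubber production; planted forests untouched for at least 10 years
#' count as unmanaged. Grasslands under annual burning or low-moderate
#' grazing/mowing are unmanaged; fertilization, irrigation, or establishment
#' in the measurement year makes them managed. Croplands are always managed.
#' Tundra, peatland and dry shrubland are unmanaged unless fertilized as part
#' of a manipulation experiment.
#'
#' @param biome Biome code.
#' @param attrs List of management antecedents:
#'   `years_since_thinning_or_harvest`, `years_since_fertilization`,
#'   `years_since_planting` (numeric, NA if never), `fruit_plantation`,
#'   `irrigated`, `annual_burning`, `established_measurement_year`,
#'   `fertilization_experiment` (logicals),
#'   `grazing_intensity` (`"none"`/`"low_moderate"`/`"intensive"`).
#'   Missing antecedents default to the unmanaged side, with a
#'   low-confidence attribute on the result.
#' @return `"managed"` or `"unmanaged"` (attribute `confidence` is
#'   `"low"` when unknown antecedents defaulted).
#' @export
classify_management <- function(biome, attrs = list()) {
  g <- function(nm) {
    v <- attrs[[nm]]
    if (is.null(v) || length(v) == 0) NA else v
  }
  if (biome == "cropland") return("managed")
  known <- function(x) !is.na(x)
  low_conf <- FALSE
  res <- if (biome == "forest") {
    th <- g("years_since_thinning_or_harvest")
    fe <- g("years_since_fertilization")
    pl <- g("years_since_planting")
    low_conf <- !known(th) && !known(fe)
    if ((known(th) && th <= 50) || (known(fe) && fe <= 25) ||
        (known(pl) && pl < 10) || isTRUE(g("fruit_plantation"))) {
      "managed"
    } else "unmanaged"
  } else if (biome == "grassland") {
    fe <- g("years_since_fertilization")
    fertilized <- known(fe) && fe <= 1
    low_conf <- !known(fe) && !isTRUE(g("irrigated")) &&
      !isTRUE(g("annual_burning")) && is.na(g("grazing_intensity"))
    if (fertilized || isTRUE(g("irrigated")) ||
        isTRUE(g("established_measurement_year")) ||
        identical(g("grazing_intensity"), "intensive")) {
      "managed"
    } else "unmanaged"
  } else { # tundra, peatland, dry_shrubland
    if (isTRUE(g("fertilization_experiment"))) "managed" else "unmanaged"
  }
  if (low_conf) attr(res, "confidence") <- "low"
  res
}

#' Aridity index and class
#'
#' The aridity index AI is annual precipitation over annual potential
#' evapotranspiration; values well below 1 indicate a water deficit. Sites are
#' binned into five classes; with the pinned boundary convention the classes
#' partition `[0, Inf)`: hyper-arid `[0, 0.03)`, arid `[0.03, 0.2)`, semi-arid
#' `[0.2, 0.5)`, dry sub-humid `[0.5, 0.65]` and humid `> 0.65`. The index is
#' undefined when PET is zero.
#'
#' @param pre_annual Annual precipitation, mm (>= 0).
#' @param pet_annual Annual potential evapotranspiration, mm (> 0).
#' @return Tibble with columns `ai` and `aridity_class`. Vectorized.
#' @export
#' @examples
#' aridity(1300, 1000)
aridity <- function(pre_annual, pet_annual) {
  if (any(pet_annual == 0, na.rm = TRUE)) {
    stop("aridity index undefined: PET is zero", call. = FALSE)
  }
  if (any(pre_annual < 0 | pet_annual < 0, na.rm = TRUE)) {
    stop("precipitation and PET must be non-negative", call. = FALSE)
  }
  ai <- pre_annual / pet_annual
  tibble::tibble(ai = ai, aridity_class = aridity_class(ai))
}

#' @rdname aridity
#' @param ai Aridity-index values.
#' @export
aridity_class <- function(ai) {
  dplyr::case_when(
    is.na(ai) ~ NA_character_,
    ai < 0.03 ~ "hyper_arid",
    ai < 0.2 ~ "arid",
    ai < 0.5 ~ "semi_arid",
    ai <= 0.65 ~ "dry_subhumid",
    TRUE ~ "humid"
  )
}

#' Koppen-Geiger main climate class from monthly normals
#'
#' Assigns the main Koppen-Geiger class from 12 monthly temperature and
#' precipitation normals: polar (E) when the warmest month stays below 10
#' degC; otherwise arid (B) when annual precipitation falls below 10 times the
#' dryness threshold (2 MAT, plus 28 if at least 70% of precipitation falls in
#' the high-sun half-year, plus 14 if neither half dominates); otherwise
#' tropical (A) when the coldest month is at least 18 degC; temperate (C) when
#' the coldest month is above the cold bound (0 degC in the modern
#' formulation used here); cold (D) otherwise. The high-sun half-year is
#' April-September in the northern hemisphere and October-March in the
#' southern; equatorial sites use the April-September convention.
#'
#' @param temperature,precipitation Numeric length-12 monthly normals
#'   (degC, mm), January first.
#' @param latitude Site latitude, used only for the hemisphere of the
#'   high-sun half-year.
#' @param cold_month_bound Coldest-month temperature separating temperate
#'   from cold climates; 0 degC by default, -3 degC in older formulations.
#' @return One of `"tropical"`, `"arid"`, `"temperate"`, `"cold"`, `"polar"`.
#' @export
koppen_main_class <- function(temperature, precipitation, latitude = 45,
                              cold_month_bound = 0) {
  if (length(temperature) != 12 || length(precipitation) != 12 ||
      any(is.na(temperature)) || any(is.na(precipitation))) {
    stop("need 12 non-missing monthly temperature and precipitation values",
         call. = FALSE)
  }
  if (any(precipitation < 0)) {
    stop("precipitation must be non-negative", call. = FALSE)
  }
  t_max <- max(temperature)
  t_min <- min(temperature)
  if (t_max < 10) return("polar")

  mat <- mean(temperature)
  pann <- sum(precipitation)
  summer <- if (latitude >= 0) 4:9 else c(10:12, 1:3)
  p_summer <- sum(precipitation[summer])
  frac_summer <- if (pann > 0) p_summer / pann else 0.5
  p_threshold <- if (frac_summer >= 0.7) {
    2 * mat + 28
  } else if (frac_summer <= 0.3) { # >= 70% in the low-sun half
    2 * mat
  } else {
    2 * mat + 14
  }
  if (pann < 10 * p_threshold) return("arid")

  if (t_min >= 18) return("tropical")
  if (t_min > cold_month_bound) return("temperate")
  "cold"
}

#' Classify every site of a database
#'
#' Convenience wrapper that derives, per site, the Koppen-Geiger main class
#' and the aridity index/class from the long-term monthly normals, and
#' compares the stored biome label with the rule-based classifier where the
#' production shares are derivable from the site's records (the stored labels
#' encode expert judgment the rules only approximate, so the comparison is a
#' validation aid, not a replacement).
#'
#' @param db An `npp_database` with a `climate_normals` table.
#' @return Tibble `site_id`, `stored_climate_region`, `koppen_class`,
#'   `climate_match`, `ai`, `aridity_class`.
#' @export
classify_sites <- function(db) {
  cn <- db$climate_normals
  if (!nrow(cn)) stop("database has no climate_normals table", call. = FALSE)
  si <- db$site_information
  cn |>
    dplyr::arrange(.data$site_id, .data$month) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      koppen_class = koppen_main_class(
        .data$temperature, .data$precipitation,
        latitude = si$latitude[match(.data$site_id[[1]], si$site_id)]
      ),
      ai = sum(.data$precipitation) / sum(.data$pet),
      .groups = "drop"
    ) |>
    dplyr::mutate(aridity_class = aridity_class(.data$ai)) |>
    dplyr::left_join(
      dplyr::select(si, "site_id", stored_climate_region = "climate_region"),
      by = "site_id"
    ) |>
    dplyr::mutate(climate_match =
                    .data$koppen_class == .data$stored_climate_region) |>
    dplyr::relocate("stored_climate_region", .after = "site_id")
}
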