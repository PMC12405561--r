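# Shared fixture builders. Everything is constructed in code; the only
# on-disk fixture is the 12-site CSV set under inst/extdata/synthdb12.

make_site <- function(site_id = "T1", biome = "forest",
                      climate_region = "temperate", latitude = 48.0,
                      management = "unmanaged") {
  tibble::tibble(
    site_id = site_id, latitude = latitude, longitude = 7.5, elevation = 250,
    biome = biome, management = management, climate_region = climate_region,
    study_type = "field_assessment", species_info = NA_character_,
    fertility = "unknown"
  )
}

make_record <- function(site_id = "T1", component, value = NA_real_,
                        method_id = NA_character_, absent = FALSE,
                        series_length = 1, year_start = 2010,
                        year_end = 2010, carbon_content = NA_real_,
                        unit = "g_dry_mass", in_litterfall = FALSE,
                        record_id = NULL) {
  n <- max(length(component), length(value))
  tibble::tibble(
    record_id = record_id %||% paste0(site_id, "-", component),
    site_id = site_id, component = component, original_label = component,
    value = value, unit = unit, carbon_content = carbon_content,
    year_start = year_start, year_end = year_end,
    series_length = series_length, method_id = method_id,
    component_absent = absent, in_litterfall = in_litterfall
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_db <- function(sites, npp, validate = TRUE) {
  m <- npp_method_catalog()
  npp_database(list(
    site_information = sites,
    npp_estimates = npp,
    methods_aboveground = m[m$scope == "aboveground", ],
    methods_belowground = m[m$scope == "belowground", ],
    methods_total = m[m$scope == "total", ]
  ), validate = validate)
}

# the worked forest site of the summation examples
forest_records <- function(site_id = "T1") {
  dplyr::bind_rows(
    make_record(site_id, "stem", 400, "AG3"),
    make_record(site_id, "branch", 80, "AG3"),
    make_record(site_id, "foliage_litter", 300, "AG2"),
    make_record(site_id, "extra_litter", 50, "AG3"),
    make_record(site_id, "herb", 0, absent = TRUE),
    make_record(site_id, "shrub", 0, absent = TRUE),
    make_record(site_id, "non_vascular", 0, absent = TRUE),
    make_record(site_id, "fine_root", 350, "BG2"),
    make_record(site_id, "coarse_root", 90, "BG4")
  )
}

level_row <- function(levels, name) {
  levels[levels$level == name, , drop = FALSE]
}
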