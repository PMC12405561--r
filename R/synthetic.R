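#' Configuration for the synthetic database generator
#'
#' Defaults encode the marginal structure of the harmonized database the
#' generator emulates: 456 sites split over six biomes
#' (forest/grassland/cropland/peatland/tundra/dry shrubland in proportions
#' 206/145/34/34/21/16) and five climate regions (cold/temperate/tropical/
#' arid/polar, 191/125/80/45/14), measurement series of 1-16 years (42%
#' single-year, 50% spanning 2-5 years, the rest 6-16), about 11% of sites
#' carrying only a total-NPP estimate, and 1/3 of sites managed. True NPP
#' follows a Miami surface over the site climate; observed component values
#' add method-dependent heteroscedastic noise whose spread scales with the
#' method reduction factor and shrinks with the square root of the series
#' length.
#'
#' @param n_sites Number of sites.
#' @param biome_mix Named probability vector over the six biomes.
#' @param climate_mix Named probability vector over the five climate regions.
#' @param miami_params Parameters of the generating Miami surface.
#' @param noise_model Multiplier on the method-dependent noise spread
#'   (0 = noise-free).
#' @param total_only_fraction Fraction of sites with only a total-NPP record.
#' @param incomplete_fraction Fraction of component-resolved sites with one
#'   main component deliberately left unmeasured and unflagged (for gating
#'   tests).
#' @param carbon_fraction Fraction of records carrying carbon-content
#'   conversion metadata.
#' @param managed_fraction Overall fraction of managed sites (croplands are
#'   always managed; the remainder is spread over the other biomes).
#' @param series_length_probs Length-16 probability vector for series lengths
#'   1-16 yr.
#' @param seed Integer seed; one global seed drives named sub-streams per
#'   table so adding a table never perturbs existing draws.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_sites = 456,
                         biome_mix = c(forest = 206, grassland = 145,
                                       cropland = 34, peatland = 34,
                                       tundra = 21, dry_shrubland = 16) / 456,
                         climate_mix = c(tropical = 80, arid = 45,
                                         temperate = 125, cold = 191,
                                         polar = 14) / 455,
                         miami_params = miami_params_classic(),
                         noise_model = 1,
                         total_only_fraction = 50 / 456,
                         incomplete_fraction = 0.1,
                         carbon_fraction = 0.3,
                         managed_fraction = 152 / 456,
                         series_length_probs = c(0.42, rep(0.50 / 4, 4),
                                                 rep(0.08 / 11, 11)),
                         seed = 17) {
  stopifnot(
    n_sites >= 1,
    abs(sum(biome_mix) - 1) < 1e-8,
    abs(sum(climate_mix) - 1) < 1e-8,
    abs(sum(series_length_probs) - 1) < 1e-8,
    length(series_length_probs) == 16,
    total_only_fraction >= 0, total_only_fraction <= 1,
    incomplete_fraction >= 0, incomplete_fraction <= 1,
    noise_model >= 0
  )
  if (!setequal(names(biome_mix), npp_biomes()) ||
      !setequal(names(climate_mix), npp_climate_regions())) {
    stop("biome_mix / climate_mix must be named over the full vocabularies",
         call. = FALSE)
  }
  structure(
    list(
      n_sites = n_sites, biome_mix = biome_mix, climate_mix = climate_mix,
      miami_params = miami_params, noise_model = noise_model,
      total_only_fraction = total_only_fraction,
      incomplete_fraction = incomplete_fraction,
      carbon_fraction = carbon_fraction,
      managed_fraction = managed_fraction,
      series_length_probs = series_length_probs,
      seed = seed
    ),
    class = "synth_config"
  )
}

# run code under a named RNG sub-stream of the global seed, restoring the
# caller's RNG state afterwards
with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, globalenv())
  })
  hash <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  set.seed((as.numeric(seed) * 7919 + hash * 104729) %% 2147483647)
  force(code)
}

# climate regions a biome can plausibly occupy
biome_region_compat <- function() {
  list(
    forest = c("tropical", "temperate", "cold"),
    grassland = c("tropical", "arid", "temperate", "cold"),
    cropland = c("tropical", "arid", "temperate", "cold"),
    peatland = c("cold", "polar"),
    tundra = c("cold", "polar"),
    dry_shrubland = c("arid", "temperate")
  )
}

# draw monthly normals consistent with a Koppen main class
region_normals <- function(region, hemisphere_north) {
  par <- switch(region,
    tropical = list(mat = stats::runif(1, 24, 28), amp = stats::runif(1, 0.5, 2),
                    pann = stats::runif(1, 1400, 2800)),
    arid = list(mat = stats::runif(1, 12, 24), amp = stats::runif(1, 6, 10),
                pann = stats::runif(1, 80, 250)),
    temperate = list(mat = stats::runif(1, 8, 16), amp = stats::runif(1, 5, 7),
                     pann = stats::runif(1, 700, 1600)),
    cold = list(mat = stats::runif(1, 0, 6), amp = stats::runif(1, 12, 18),
                pann = stats::runif(1, 450, 900)),
    polar = list(mat = stats::runif(1, -12, -4), amp = stats::runif(1, 8, 12),
                 pann = stats::runif(1, 150, 400))
  )
  m <- 1:12
  phase <- if (hemisphere_north) 7 else 1 # warmest month
  temp <- par$mat + par$amp * cos(2 * pi * (m - phase) / 12)
  prec <- par$pann / 12 * (1 + 0.3 * cos(2 * pi * (m - phase) / 12))
  pet <- pmax(0, 35 + 5.5 * temp)
  list(temperature = temp, precipitation = prec, pet = pet,
       mat = mean(temp), pann = sum(prec))
}

region_latitude <- function(region) {
  switch(region,
    tropical = stats::runif(1, -20, 20),
    arid = sample(c(-1, 1), 1) * stats::runif(1, 15, 35),
    temperate = sample(c(-1, 1), 1, prob = c(0.25, 0.75)) *
      stats::runif(1, 32, 48),
    cold = stats::runif(1, 46, 64),
    polar = stats::runif(1, 62, 75)
  )
}

# measured component shares of total NPP and components verified absent,
# per biome (tropical forests get a leaf-decomposition absence flag so their
# second total level gates cleanly)
biome_component_spec <- function(biome, tropical = FALSE) {
  spec <- switch(biome,
    forest = list(
      shares = c(stem = 0.28, branch = 0.07, foliage_litter = 0.24,
                 extra_litter = 0.03, fine_root = 0.30, coarse_root = 0.08),
      absent = c("herb", "shrub", "non_vascular", "herbivory", "reproductive")
    ),
    grassland = list(
      shares = c(herb = 0.60, fine_root = 0.40),
      absent = c("shrub", "non_vascular", "herbivory", "reproductive",
                 "coarse_root")
    ),
    cropland = list(
      shares = c(herb = 0.62, fine_root = 0.38),
      absent = c("shrub", "non_vascular", "herbivory", "reproductive",
                 "coarse_root")
    ),
    tundra = list(
      shares = c(herb = 0.35, shrub = 0.20, non_vascular = 0.10,
                 fine_root = 0.35),
      absent = c("herbivory", "reproductive", "coarse_root")
    ),
    peatland = list(
      shares = c(herb = 0.30, shrub = 0.20, non_vascular = 0.20,
                 fine_root = 0.30),
      absent = c("herbivory", "reproductive", "coarse_root")
    ),
    dry_shrubland = list(
      shares = c(herb = 0.25, stem = 0.12, branch = 0.04,
                 foliage_litter = 0.12, extra_litter = 0.02,
                 fine_root = 0.40, coarse_root = 0.05),
      absent = c("shrub", "non_vascular", "herbivory", "reproductive")
    )
  )
  if (biome == "forest" && tropical) {
    spec$absent <- c(spec$absent, "tropical_leaf_decomposition")
  }
  spec
}

# candidate method ids per component (scope-compatible by construction)
component_methods <- function(component) {
  switch(component,
    stem = , branch = c("AG3", "AG6"),
    foliage_litter = c("AG2", "AG3"),
    extra_litter = c("AG3", "AG7"),
    reproductive = c("AG4"),
    herb = c("AG3", "AG4", "AG5"),
    shrub = , understory = c("AG3", "AG6"),
    non_vascular = c("AG3", "AG4"),
    tropical_leaf_decomposition = c("AG2"),
    herbivory = c("AG7"),
    fine_root = c("BG2", "BG3", "BG6", "BG7"),
    coarse_root = c("BG4", "BG5", "BG8"),
    voc_exudates_symbionts = c("BG5"),
    total_npp = c("TO1", "TO2", "TO3", "TO4")
  )
}

#' Generate a synthetic multi-table NPP database
#'
#' Builds a full 12-table database with the statistical structure the
#' harmonization pipeline assumes: sites draw a biome and a compatible
#' climate region, monthly climate normals consistent with that region's
#' Koppen-Geiger class, a true NPP from the Miami surface of the
#' configuration, component records split per the biome's expected component
#' set with scope-matched methods from the catalogue, heteroscedastic
#' method-dependent noise, carbon-content metadata on a random subset of
#' records, a configured fraction of total-NPP-only sites, and a configured
#' fraction of deliberately incomplete sites (one main component unreported)
#' for gating tests. Reported aggregate levels are stored alongside so
#' summation consistency can be checked.
#'
#' Deterministic given `config$seed`: the same configuration yields a
#' bit-identical database.
#'
#' @param config A [synth_config()].
#' @return A validated `npp_database` with a `synth_truth` attribute (tibble
#'   of per-site true NPP, climate and generation flags).
#' @export
generate_database <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_sites
  compat <- biome_region_compat()

  sites <- with_substream(config$seed, "sites", {
    biome <- sample(names(config$biome_mix), n, replace = TRUE,
                    prob = config$biome_mix)
    region <- purrr::map_chr(biome, function(b) {
      ok <- compat[[b]]
      p <- config$climate_mix[ok]
      if (sum(p) <= 0) stop("infeasible config: biome ", b,
                            " has no compatible climate region with mass",
                            call. = FALSE)
      sample(ok, 1, prob = p / sum(p))
    })
    lat <- purrr::map_dbl(region, region_latitude)
    lon <- stats::runif(n, -180, 180)
    clim <- purrr::map2(region, lat >= 0, region_normals)
    n_crop <- sum(biome == "cropland")
    p_rest <- max(0, (config$managed_fraction * n - n_crop)) /
      max(1, n - n_crop)
    managed <- ifelse(biome == "cropland", TRUE,
                      stats::runif(n) < p_rest)
    tibble::tibble(
      site_id = sprintf("S%03d", seq_len(n)),
      biome = biome, climate_region = region,
      latitude = round(lat, 4), longitude = round(lon, 4),
      elevation = round(stats::runif(n, 5, 1500)),
      management = ifelse(managed, "managed", "unmanaged"),
      study_type = sample(c("field_assessment", "manipulation_control",
                            "manipulation_treatment"), n, replace = TRUE,
                          prob = c(0.9, 0.05, 0.05)),
      fertility = sample(c("L", "M", "H", "unknown"), n, replace = TRUE),
      species_info = NA_character_,
      clim = clim,
      series_length = sample(1:16, n, replace = TRUE,
                             prob = config$series_length_probs),
      total_only = stats::runif(n) < config$total_only_fraction,
      incomplete = stats::runif(n) < config$incomplete_fraction
    )
  })
  sites$incomplete <- sites$incomplete & !sites$total_only
  sites$mat <- purrr::map_dbl(sites$clim, "mat")
  sites$map <- purrr::map_dbl(sites$clim, "pann")
  sites$npp_true <- miami_predict(sites$mat, sites$map, config$miami_params)

  methods <- npp_method_catalog()
  records <- with_substream(config$seed, "npp_records", {
    purrr::map_dfr(seq_len(n), function(i) {
      s <- sites[i, ]
      l <- s$series_length
      year_end <- sample(2000:2018, 1)
      year_start <- year_end - l + 1
      out <- if (s$total_only) {
        mid <- sample(component_methods("total_npp"), 1)
        rf <- methods$rf[methods$method_id == mid]
        sd <- config$noise_model * 0.2 * s$npp_true * rf / sqrt(l)
        tibble::tibble(
          site_id = s$site_id, component = "total_npp",
          value = max(0, s$npp_true + stats::rnorm(1, 0, sd)),
          method_id = mid, component_absent = FALSE
        )
      } else {
        spec <- biome_component_spec(s$biome,
                                     tropical = s$climate_region == "tropical")
        comps <- names(spec$shares)
        if (s$incomplete) {
          # silently drop one main component (no absence flag): the site
          # should gate incomplete downstream
          drop <- sample(intersect(comps, c("fine_root", "stem", "herb",
                                            "foliage_litter")), 1)
          spec$shares <- spec$shares[comps != drop]
          comps <- names(spec$shares)
        }
        mid <- purrr::map_chr(comps, ~ sample(component_methods(.x), 1))
        rf <- methods$rf[match(mid, methods$method_id)]
        truth <- s$npp_true * spec$shares
        sd <- config$noise_model * 0.2 * truth * rf / sqrt(l)
        obs <- pmax(0, truth + stats::rnorm(length(truth), 0, sd))
        dplyr::bind_rows(
          tibble::tibble(site_id = s$site_id, component = comps,
                         value = obs, method_id = mid,
                         component_absent = FALSE),
          tibble::tibble(site_id = s$site_id, component = spec$absent,
                         value = 0, method_id = NA_character_,
                         component_absent = TRUE)
        )
      }
      dplyr::mutate(out, year_start = year_start, year_end = year_end,
                    series_length = l)
    })
  })

  records <- with_substream(config$seed, "carbon", {
    k <- nrow(records)
    conv <- stats::runif(k) < config$carbon_fraction & !records$component_absent
    records$carbon_content <- ifelse(conv,
                                     sample(c(0.45, 0.475, 0.5), k,
                                            replace = TRUE), NA_real_)
    records$unit <- "g_dry_mass"
    records
  })
  records <- records |>
    dplyr::mutate(
      record_id = sprintf("R%05d", dplyr::row_number()),
      original_label = .data$component,
      in_litterfall = FALSE
    )

  cn <- purrr::map2_dfr(sites$site_id, sites$clim, function(sid, cl) {
    tibble::tibble(site_id = sid, month = 1:12,
                   temperature = round(cl$temperature, 2),
                   precipitation = round(cl$precipitation, 2),
                   pet = round(cl$pet, 2))
  })

  ancillary <- with_substream(config$seed, "ancillary", {
    list(
      soil_properties = tibble::tibble(
        site_id = sites$site_id,
        soil_texture = sample(c("sand", "loam", "clay", "silt"), n, TRUE),
        ph = round(stats::runif(n, 4, 8), 1),
        fertility_class = sites$fertility
      ),
      site_history = tibble::tibble(
        site_id = sites$site_id,
        years_since_disturbance = NA_real_,
        years_since_thinning_or_harvest = ifelse(
          sites$biome == "forest" & sites$management == "managed",
          sample(0:50, n, TRUE), NA_real_),
        years_since_fertilization = ifelse(
          sites$management == "managed" & sites$biome != "forest",
          sample(0:1, n, TRUE), NA_real_),
        years_since_planting = NA_real_,
        years_protected = NA_real_,
        grazing_intensity = ifelse(sites$biome == "grassland",
                                   sample(c("none", "low_moderate"), n, TRUE),
                                   NA_character_),
        irrigated = sites$biome == "cropland",
        annual_burning = FALSE,
        crop = sites$biome == "cropland",
        fruit_plantation = FALSE,
        above_treeline = sites$biome == "tundra"
      ),
      climate_short_term = tibble::tibble(
        site_id = sites$site_id, year = 2010,
        temperature = round(sites$mat + stats::rnorm(n, 0, 0.5), 2),
        precipitation = round(sites$map * stats::runif(n, 0.9, 1.1), 1)
      ),
      bioclim = tibble::tibble(
        site_id = rep(sites$site_id, 2),
        variable = rep(c("mat", "map"), each = n),
        value = c(round(sites$mat, 2), round(sites$map, 1))
      ),
      data_sources = tibble::tibble(
        site_id = sites$site_id,
        source_type = sample(c("peer_reviewed", "global_database",
                               "meta_analysis", "other"), n, TRUE,
                             prob = c(0.67, 0.20, 0.11, 0.02)),
        reference = paste0("synthetic-source-", seq_len(n))
      )
    )
  })

  si <- dplyr::select(sites, "site_id", "latitude", "longitude", "elevation",
                      "biome", "management", "climate_region", "study_type",
                      "species_info", "fertility")
  db <- npp_database(c(
    list(
      site_information = si,
      npp_estimates = dplyr::select(
        records, "record_id", "site_id", "component", "original_label",
        "value", "unit", "carbon_content", "year_start", "year_end",
        "series_length", "method_id", "component_absent", "in_litterfall"
      ),
      methods_aboveground = methods[methods$scope == "aboveground", ],
      methods_belowground = methods[methods$scope == "belowground", ],
      methods_total = methods[methods$scope == "total", ],
      climate_normals = cn
    ),
    ancillary
  ), validate = FALSE)

  # stored aggregates: the complete recomputed levels stand in for the
  # source-reported values, so the shipped database is self-consistent
  lv <- summarize_levels(db)
  db$reported_levels <- lv |>
    dplyr::filter(.data$status == "complete") |>
    dplyr::select("site_id", "level", "value")

  attr(db, "validation") <- validate_npp_database(db)
  attr(db, "synth_truth") <- dplyr::select(
    sites, "site_id", "biome", "climate_region", "mat", "map", "npp_true",
    "series_length", "total_only", "incomplete"
  )
  db
}

#' Minimal worked-example fixture for reduction-factor averaging
#'
#' One forest site with exactly two belowground records: fine roots measured
#' with minirhizotrons (RF 0.3) and coarse roots with allometric relations
#' (RF 0.6). Averaging the two factors in favour of the dominant fine-root
#' component reports a total-BNPP reduction factor of 0.4.
#'
#' @return A validated `npp_database`.
#' @export
generate_worked_example <- function() {
  methods <- npp_method_catalog()
  npp_database(list(
    site_information = tibble::tibble(
      site_id = "WX1", latitude = 52.1, longitude = 5.2, elevation = 30,
      biome = "forest", management = "unmanaged",
      climate_region = "temperate", study_type = "field_assessment",
      species_info = NA_character_, fertility = "unknown"
    ),
    npp_estimates = tibble::tibble(
      record_id = c("WX1-FR", "WX1-CR"),
      site_id = "WX1",
      component = c("fine_root", "coarse_root"),
      original_label = c("fine root production", "coarse root production"),
      value = c(420, 95),
      unit = "g_dry_mass",
      carbon_content = NA_real_,
      year_start = 2005, year_end = 2005, series_length = 1,
      method_id = c("BG2", "BG4"), # minirhizotron; allometric relations
      component_absent = FALSE, in_litterfall = FALSE
    ),
    methods_belowground = methods[methods$scope == "belowground", ]
  ))
}
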