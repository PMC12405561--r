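test_that("biome rules follow production shares with the pinned precedence", {
  expect_equal(classify_biome(list(woody_production_share = 0.7,
                                   arid_climate = FALSE)), "forest")
  # above the treeline always wins, whatever dominates
  expect_equal(classify_biome(list(herb_production_share = 0.8,
                                   above_treeline = TRUE)), "tundra")
  # cold-climate co-dominance (neither share above 50%) is peatland
  expect_equal(
    classify_biome(list(woody_production_share = 0.5,
                        herb_production_share = 0.5,
                        cold_climate = TRUE)),
    "peatland"
  )
  expect_equal(classify_biome(list(crop = TRUE)), "cropland")
  expect_equal(
    classify_biome(list(woody_production_share = 0.3,
                        herb_production_share = 0.4,
                        arid_climate = TRUE,
                        vegetation_cover = "reduced_patchy")),
    "dry_shrubland"
  )
  # woody transition zone: the larger production share decides
  expect_equal(
    classify_biome(list(woody_production_share = 0.45,
                        herb_production_share = 0.55)),
    "grassland"
  )
  u <- classify_biome(list(above_treeline = FALSE))
  expect_equal(as.character(u), "unclassifiable")
  expect_true(length(attr(u, "reasons")) > 0)
})

test_that("management rules encode the per-biome intervention windows", {
  expect_equal(
    classify_management("forest", list(years_since_thinning_or_harvest = 30)),
    "managed"
  )
  expect_equal(
    classify_management("forest", list(years_since_thinning_or_harvest = 80)),
    "unmanaged"
  )
  expect_equal(
    classify_management("forest", list(years_since_fertilization = 20)),
    "managed"
  )
  # planted forest untouched for 40 years counts as natural
  expect_equal(
    as.character(classify_management("forest",
                                     list(years_since_planting = 40))),
    "unmanaged"
  )
  expect_equal(
    as.character(classify_management("forest",
                                     list(years_since_planting = 5))),
    "managed"
  )
  # annual burning alone keeps a grassland unmanaged
  expect_equal(
    classify_management("grassland", list(annual_burning = TRUE)),
    "unmanaged"
  )
  expect_equal(
    classify_management("grassland", list(grazing_intensity = "low_moderate")),
    "unmanaged"
  )
  expect_equal(
    classify_management("grassland", list(irrigated = TRUE)),
    "managed"
  )
  expect_equal(classify_management("cropland"), "managed")
  expect_equal(classify_management("tundra"), "unmanaged")
  expect_equal(
    classify_management("peatland", list(fertilization_experiment = TRUE)),
    "managed"
  )
  # unknown antecedents default to unmanaged with a low-confidence flag
  res <- classify_management("forest", list())
  expect_equal(as.character(res), "unmanaged")
  expect_equal(attr(res, "confidence"), "low")
})

test_that("aridity index bins partition the whole non-negative line", {
  a <- aridity(1300, 1000)
  expect_equal(a$ai, 1.3)
  expect_equal(a$aridity_class, "humid")
  z <- aridity(0, 1000)
  expect_equal(z$ai, 0)
  expect_equal(z$aridity_class, "hyper_arid")
  expect_error(aridity(500, 0), "PET is zero")

  # every AI value maps to exactly one class; boundaries pinned
  grid <- c(0, 0.0299, 0.03, 0.1, 0.1999, 0.2, 0.49, 0.5, 0.64, 0.65,
            0.650001, 1, 5, seq(0, 3, by = 0.01))
  cls <- aridity_class(grid)
  expect_false(any(is.na(cls)))
  expect_true(all(cls %in% c("hyper_arid", "arid", "semi_arid",
                             "dry_subhumid", "humid")))
  expect_equal(aridity_class(c(0.03, 0.2, 0.5, 0.65, 0.6500001)),
               c("arid", "semi_arid", "dry_subhumid", "dry_subhumid", "humid"))
})

test_that("Koppen main classes follow the monthly-normal criteria", {
  expect_equal(koppen_main_class(rep(27, 12), rep(200, 12)), "tropical")
  # warmest month below 10 C is polar regardless of precipitation
  expect_equal(koppen_main_class(rep(5, 12), rep(100, 12)), "polar")
  # flat 20 C with 60 mm yr-1: dryness threshold far above annual total
  expect_equal(koppen_main_class(rep(20, 12), rep(5, 12)), "arid")
  # mild winters: temperate; freezing winters: cold
  t_seasonal <- 12 + 8 * cos(2 * pi * (1:12 - 7) / 12)
  expect_equal(koppen_main_class(t_seasonal, rep(80, 12)), "temperate")
  t_cont <- 3 + 18 * cos(2 * pi * (1:12 - 7) / 12)
  expect_equal(koppen_main_class(t_cont, rep(60, 12)), "cold")
  expect_error(koppen_main_class(rep(10, 6), rep(10, 12)), "12")
})

test_that("main-class assignment matches an independent rule oracle", {
  # independently coded, scalar, rule-by-rule
  oracle <- function(tt, pp, lat) {
    if (max(tt) < 10) return("polar")
    mat <- sum(tt) / 12
    pann <- sum(pp)
    hs <- if (lat >= 0) pp[4:9] else pp[c(10, 11, 12, 1, 2, 3)]
    fr <- if (pann > 0) sum(hs) / pann else 0.5
    thr <- 2 * mat + (if (fr >= 0.7) 28 else if (fr <= 0.3) 0 else 14)
    if (pann < 10 * thr) return("arid")
    if (min(tt) >= 18) return("tropical")
    if (min(tt) > 0) return("temperate")
    "cold"
  }
  set.seed(99)
  for (i in 1:300) {
    tt <- runif(12, -25, 32)
    pp <- runif(12, 0, 300)
    lat <- runif(1, -70, 70)
    expect_equal(koppen_main_class(tt, pp, lat), oracle(tt, pp, lat),
                 info = paste("case", i))
  }
})

test_that("classify_sites derives climate classes that match the generator's", {
  db <- generate_database(synth_config(n_sites = 80, seed = 13))
  cls <- classify_sites(db)
  expect_equal(nrow(cls), 80)
  expect_gte(mean(cls$climate_match), 0.95)
  expect_false(any(is.na(cls$aridity_class)))
})
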