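test_that("forest site sums through the hierarchy with strict extras gating", {
  lv <- compute_levels(forest_records(), biome = "forest",
                       climate_region = "temperate")
  expect_equal(level_row(lv, "wood_anpp")$value, 480)
  expect_equal(level_row(lv, "total_litterfall_anpp")$value, 350)
  expect_equal(level_row(lv, "tree_anpp")$value, 830)
  expect_equal(level_row(lv, "bnpp")$value, 440)
  expect_equal(level_row(lv, "total_npp_1")$value, 1270)
  # herb/shrub/non-vascular verified absent: the non-tree branch drops out
  expect_equal(level_row(lv, "non_tree_anpp")$status, "not_applicable")
  # herbivory unmeasured and unflagged blocks the second total
  expect_equal(level_row(lv, "total_npp_2")$status, "incomplete")
  expect_true(is.na(level_row(lv, "total_npp_2")$value))
})

test_that("non-tree gating is strict: unflagged non-vascular blocks the level", {
  recs <- dplyr::bind_rows(
    make_record("G1", "herb", 600, "AG4"),
    make_record("G1", "shrub", 0, absent = TRUE),
    make_record("G1", "fine_root", 500, "BG3")
  )
  lv <- compute_levels(recs, biome = "grassland")
  expect_equal(level_row(lv, "herb_shrub_anpp")$value, 600)
  expect_equal(level_row(lv, "herb_shrub_anpp")$status, "complete")
  expect_equal(level_row(lv, "non_tree_anpp")$status, "incomplete")
})

test_that("treeless biomes treat unreported tree components as not applicable", {
  recs <- dplyr::bind_rows(
    make_record("U1", "herb", 150, "AG4"),
    make_record("U1", "shrub", 50, "AG3"),
    make_record("U1", "non_vascular", 80, "AG3"),
    make_record("U1", "fine_root", 120, "BG3"),
    make_record("U1", "coarse_root", 0, absent = TRUE)
  )
  lv <- compute_levels(recs, biome = "tundra")
  expect_equal(level_row(lv, "non_tree_anpp")$value, 280)
  expect_equal(level_row(lv, "tree_anpp")$status, "not_applicable")
  expect_equal(level_row(lv, "total_npp_1")$value, 400)
  expect_equal(level_row(lv, "total_npp_1")$status, "complete")
})

test_that("understory satisfies the herb and shrub slots in forests", {
  recs <- dplyr::bind_rows(
    forest_records()[!forest_records()$component %in% c("herb", "shrub"), ],
    make_record("T1", "understory", 120, "AG3")
  )
  lv <- compute_levels(recs, biome = "forest")
  expect_equal(level_row(lv, "herb_shrub_anpp")$value, 120)
  expect_equal(level_row(lv, "non_tree_anpp")$value, 120)
  expect_equal(level_row(lv, "total_npp_1")$value, 1270 + 120)
})

test_that("reproductive material is counted exactly once", {
  base <- forest_records()
  plus_extras <- dplyr::bind_rows(
    base,
    make_record("T1", "herbivory", 10, "AG7"),
    make_record("T1", "reproductive", 20, "AG4")
  )
  lv <- compute_levels(plus_extras, "forest")
  expect_equal(level_row(lv, "total_npp_2")$value, 1270 + 30)

  # flagged as inside litterfall: not added again, gate satisfied
  inside <- dplyr::bind_rows(
    base,
    make_record("T1", "herbivory", 10, "AG7"),
    make_record("T1", "reproductive", 20, "AG4", in_litterfall = TRUE)
  )
  lv2 <- compute_levels(inside, "forest")
  expect_equal(level_row(lv2, "total_npp_2")$value, 1280)

  # both at once is a double-count error
  both <- dplyr::bind_rows(
    inside,
    make_record("T1", "reproductive", 5, "AG4", in_litterfall = FALSE,
                record_id = "T1-rep2")
  )
  expect_error(compute_levels(both, "forest"), "double|litterfall")
})

test_that("tropical forests additionally gate on rapid leaf decomposition", {
  recs <- dplyr::bind_rows(
    forest_records(),
    make_record("T1", "herbivory", 0, absent = TRUE),
    make_record("T1", "reproductive", 0, absent = TRUE)
  )
  lv_temp <- compute_levels(recs, "forest", climate_region = "temperate")
  expect_equal(level_row(lv_temp, "total_npp_2")$value, 1270)
  lv_trop <- compute_levels(recs, "forest", climate_region = "tropical")
  expect_equal(level_row(lv_trop, "total_npp_2")$status, "incomplete")
  with_decomp <- dplyr::bind_rows(
    recs, make_record("T1", "tropical_leaf_decomposition", 60, "AG2")
  )
  lv3 <- compute_levels(with_decomp, "forest", climate_region = "tropical")
  expect_equal(level_row(lv3, "total_npp_2")$value, 1330)
})

test_that("mixed-campaign sites carry the provenance flag", {
  recs <- forest_records()
  lv <- compute_levels(recs, "forest", mixed_campaign = TRUE)
  expect_true(all(lv$provenance == "mixed_campaign"))
  expect_true(all(compute_levels(recs, "forest")$provenance == "single_campaign"))
})

test_that("adding information never flips a level from complete to incomplete", {
  set.seed(31)
  comps <- setdiff(npp_components(), "total_npp")
  for (rep in 1:60) {
    biome <- sample(c("forest", "grassland", "tundra", "peatland",
                      "cropland", "dry_shrubland"), 1)
    picked <- sample(comps, sample(3:9, 1))
    recs <- dplyr::bind_rows(purrr::map(picked, function(cc) {
      if (stats::runif(1) < 0.3) make_record("P", cc, 0, absent = TRUE)
      else make_record("P", cc, stats::runif(1, 10, 500))
    }))
    before <- compute_levels(recs, biome)
    unknown <- setdiff(comps, c(picked, "reproductive"))
    if (!length(unknown)) next
    add <- sample(unknown, 1)
    extra <- if (stats::runif(1) < 0.5) make_record("P", add, 0, absent = TRUE)
    else make_record("P", add, stats::runif(1, 10, 500))
    after <- compute_levels(dplyr::bind_rows(recs, extra), biome)
    flipped <- before$status == "complete" & after$status == "incomplete"
    expect_false(any(flipped),
                 info = paste(biome, add, paste(picked, collapse = ",")))
  }
})

test_that("complete sites are additive and non-negative through the totals", {
  recs <- dplyr::bind_rows(
    forest_records(),
    make_record("T1", "herbivory", 12, "AG7"),
    make_record("T1", "reproductive", 8, "AG4")
  )
  lv <- compute_levels(recs, "forest")
  stopifnot(all(lv$status %in% c("complete", "not_applicable")))
  t1 <- level_row(lv, "total_npp_1")$value
  t2 <- level_row(lv, "total_npp_2")$value
  expect_gte(t2, t1)
  constituents <- lv$value[lv$status == "complete" &
                             !lv$level %in% c("total_npp_1", "total_npp_2")]
  expect_true(all(t1 >= constituents))
  expect_true(all(lv$value[lv$status == "complete"] >= 0))
})

test_that("completeness audit reports missing main vs minor components", {
  # boreal forest without understory: understory is a main component there
  boreal <- forest_records()[!forest_records()$component %in%
                               c("herb", "shrub"), ]
  a <- completeness_audit(boreal, "forest", climate_region = "cold")
  expect_equal(a$ecosystem_type, "boreal_forest")
  expect_true("understory" %in% a$missing_main)

  # fruit plantation without reproductive material
  b <- completeness_audit(forest_records(), "forest",
                          climate_region = "temperate",
                          fruit_plantation = TRUE)
  expect_equal(b$ecosystem_type, "fruit_plantation")
  expect_true("reproductive" %in% b$missing_main)

  # temperate forest without coarse roots: minor, not main
  temperate <- forest_records()[forest_records()$component != "coarse_root", ]
  d <- completeness_audit(temperate, "forest", climate_region = "temperate")
  expect_equal(d$missing_main, character(0))
  expect_true("coarse_root" %in% d$missing_minor)
})

test_that("expectation table covers every ecosystem type with disjoint classes", {
  exp <- component_expectations()
  for (et in unique(exp$ecosystem_type)) {
    main <- exp$component[exp$ecosystem_type == et & exp$class == "main"]
    minor <- exp$component[exp$ecosystem_type == et & exp$class == "minor"]
    expect_length(intersect(main, minor), 0)
    expect_gte(length(main), 2)
  }
  expect_setequal(
    unique(exp$ecosystem_type),
    c("boreal_forest", "tropical_forest", "other_forest", "fruit_plantation",
      "grassland", "cropland", "peatland_tundra",
      "peatland_tundra_nonvascular", "woodland_savanna_shrubland")
  )
})
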