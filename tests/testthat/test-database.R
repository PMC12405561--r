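test_that("packaged 12-site fixture reads with all tables and no issues", {
  path <- system.file("extdata", "synthdb12", package = "nppdb")
  db <- read_npp_database(path)
  expect_s3_class(db, "npp_database")
  expect_equal(nrow(db$site_information), 12)
  expect_equal(nrow(npp_validation(db)), 0)
  # all 12 canonical tables populated
  n_rows <- vapply(nppdb:::npp_tables(), function(tb) nrow(db[[tb]]), 1L)
  expect_true(all(n_rows > 0))
})

test_that("referential and bound violations are reported row by row", {
  sites <- make_site()
  npp <- make_record("T1", "stem", 400, method_id = "NO-SUCH-METHOD")
  db <- tiny_db(sites, npp)
  v <- npp_validation(db)
  expect_equal(nrow(v), 1)
  expect_equal(v$id, "T1-stem")
  expect_match(v$message, "unresolvable method_id")

  db2 <- tiny_db(make_site(latitude = 95.0), make_record("T1", "stem", 1, "AG3"))
  v2 <- npp_validation(db2)
  expect_match(v2$message, "coordinate out of bounds", all = FALSE)

  # scope incompatibility: a belowground method may not tag foliage
  db3 <- tiny_db(sites, make_record("T1", "foliage_litter", 300, "BG2"))
  expect_match(npp_validation(db3)$message, "scope incompatible", all = FALSE)

  # croplands are always managed
  db4 <- tiny_db(make_site(biome = "cropland", management = "unmanaged"),
                 make_record("T1", "herb", 500, "AG4"))
  expect_match(npp_validation(db4)$message, "always managed", all = FALSE)
})

test_that("validation is total: every row is accepted or reported, never dropped", {
  sites <- dplyr::bind_rows(make_site("A"), make_site("B", latitude = 95))
  npp <- dplyr::bind_rows(
    make_record("A", "stem", 400, "AG3"),
    make_record("A", "fine_root", -5, "BG2"),   # negative value
    make_record("C", "herb", 100, "AG4")        # unknown site
  )
  db <- tiny_db(sites, npp)
  expect_equal(nrow(db$npp_estimates), 3)      # nothing dropped
  v <- npp_validation(db)
  flagged <- unique(v$id[v$table == "npp_estimates"])
  expect_setequal(flagged, c("A-fine_root", "C-herb"))
})

test_that("databases round-trip through CSV and SQLite field by field", {
  db <- generate_database(synth_config(n_sites = 8, seed = 5))
  for (fmt in c("csv", "sqlite")) {
    path <- file.path(
      withr::local_tempdir(),
      if (fmt == "csv") "dbdir" else "db.sqlite"
    )
    write_npp_database(db, path, format = fmt)
    back <- read_npp_database(path)
    for (tb in nppdb:::npp_tables()) {
      if (nrow(db[[tb]]) == 0) next
      expect_equal(as.data.frame(back[[tb]]), as.data.frame(db[[tb]]),
                   tolerance = 1e-12, ignore_attr = TRUE,
                   label = paste(fmt, tb))
    }
  }
})

test_that("carbon-unit records convert to dry mass at load; missing factor is an error", {
  dir <- withr::local_tempdir()
  db <- tiny_db(
    make_site(),
    dplyr::bind_rows(
      make_record("T1", "stem", 250, "AG3", unit = "g_C", carbon_content = 0.5),
      make_record("T1", "branch", 100, "AG3", unit = "g_C") # no factor
    )
  )
  write_npp_database(db, file.path(dir, "db"), format = "csv")
  back <- read_npp_database(file.path(dir, "db"))
  stem <- back$npp_estimates[back$npp_estimates$component == "stem", ]
  expect_equal(stem$value, 500)
  expect_equal(stem$unit, "g_dry_mass")
  branch <- back$npp_estimates[back$npp_estimates$component == "branch", ]
  expect_equal(branch$value, 100) # untouched
  expect_match(npp_validation(back)$message, "requires an explicit carbon",
               all = FALSE)
})

test_that("to_dry_mass divides by the carbon fraction and rejects bad fractions", {
  expect_equal(to_dry_mass(250, 0.5), 500)
  expect_equal(to_dry_mass(7.3, 1.0), 7.3)
  expect_equal(to_dry_mass(450, 0.45), 1000)
  expect_error(to_dry_mass(100, 0), "carbon_content")
  expect_error(to_dry_mass(100, 1.2), "carbon_content")
})

test_that("a table/column mapping adapts externally named deposits", {
  dir <- withr::local_tempdir()
  db <- tiny_db(make_site(), make_record("T1", "stem", 400, "AG3"))
  write_npp_database(db, file.path(dir, "db"), format = "csv")
  # rename a table and a column as a foreign deposit might
  file.rename(file.path(dir, "db", "site_information.csv"),
              file.path(dir, "db", "sites.csv"))
  si <- readr::read_csv(file.path(dir, "db", "sites.csv"),
                        show_col_types = FALSE)
  names(si)[names(si) == "latitude"] <- "lat_dd"
  readr::write_csv(si, file.path(dir, "db", "sites.csv"), na = "")
  mapping <- list(
    tables = list(site_information = "sites"),
    columns = list(site_information = list(latitude = "lat_dd"))
  )
  back <- read_npp_database(file.path(dir, "db"), mapping = mapping)
  expect_equal(back$site_information$latitude, 48.0)
  expect_equal(nrow(npp_validation(back)), 0)
})

test_that("site_mean_npp averages per component and is order-invariant", {
  recs <- dplyr::bind_rows(
    make_record("T1", "foliage_litter", 300, "AG2", record_id = "r1"),
    make_record("T1", "foliage_litter", 500, "AG2", record_id = "r2"),
    make_record("T1", "stem", 400, "AG3")
  )
  m <- site_mean_npp(recs)
  expect_equal(m$mean_value[m$component == "foliage_litter"], 400)
  expect_equal(m$mean_value[m$component == "total"], 800)
  expect_false(m$incomplete[m$component == "total"])

  shuffled <- site_mean_npp(recs[c(3, 1, 2), ])
  expect_equal(dplyr::arrange(m, component), dplyr::arrange(shuffled, component))

  # absent components contribute zero
  recs2 <- dplyr::bind_rows(
    make_record("T1", "herb", 600, "AG4"),
    make_record("T1", c("shrub", "non_vascular"), 0, absent = TRUE)
  )
  m2 <- site_mean_npp(recs2)
  expect_equal(m2$mean_value[m2$component == "total"], 600)

  # unmeasured, unflagged components propagate a missingness flag
  recs3 <- dplyr::bind_rows(
    make_record("T1", "herb", 600, "AG4"),
    make_record("T1", "fine_root", NA_real_, "BG2")
  )
  m3 <- site_mean_npp(recs3)
  expect_true(m3$incomplete[m3$component == "total"])
})
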