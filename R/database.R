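#' @keywords internal
npp_tables <- function() {
  c(
    # core
    "site_information", "npp_estimates",
    "methods_aboveground", "methods_belowground", "methods_total",
    "reported_levels",
    # ancillary
    "climate_normals", "soil_properties", "site_history",
    "climate_short_term", "bioclim", "data_sources"
  )
}

#' @keywords internal
npp_required_tables <- function() c("site_information", "npp_estimates")

npp_schema <- function() {
  list(
    site_information = c(
      "site_id", "latitude", "longitude", "elevation", "biome", "management",
      "climate_region", "study_type", "species_info", "fertility"
    ),
    npp_estimates = c(
      "record_id", "site_id", "component", "original_label", "value", "unit",
      "carbon_content", "year_start", "year_end", "series_length",
      "method_id", "component_absent", "in_litterfall"
    ),
    methods_aboveground = c("method_id", "name", "scope", "rf"),
    methods_belowground = c("method_id", "name", "scope", "rf"),
    methods_total = c("method_id", "name", "scope", "rf"),
    reported_levels = c("site_id", "level", "value"),
    climate_normals = c("site_id", "month", "temperature", "precipitation", "pet"),
    soil_properties = c("site_id", "soil_texture", "ph", "fertility_class"),
    site_history = c(
      "site_id", "years_since_disturbance", "years_since_thinning_or_harvest",
      "years_since_fertilization", "years_since_planting", "years_protected",
      "grazing_intensity", "irrigated", "annual_burning", "crop",
      "fruit_plantation", "above_treeline"
    ),
    climate_short_term = c("site_id", "year", "temperature", "precipitation"),
    bioclim = c("site_id", "variable", "value"),
    data_sources = c("site_id", "source_type", "reference")
  )
}

#' Construct a multi-table NPP database object
#'
#' Bundles the table set into a single `npp_database` object (a named list of
#' tibbles). `site_information` and `npp_estimates` are required; the three
#' methodology tables, the reported summation levels and the six ancillary
#' tables are optional. Missing optional tables are stored as zero-row tibbles
#' with the canonical columns.
#'
#' @param tables Named list of data frames keyed by canonical table name.
#' @param validate If `TRUE` (default) run [validate_npp_database()] and attach
#'   the report.
#' @return An `npp_database` object.
#' @export
npp_database <- function(tables, validate = TRUE) {
  unknown <- setdiff(names(tables), npp_tables())
  if (length(unknown)) {
    stop("unknown table(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing_req <- setdiff(npp_required_tables(), names(tables))
  if (length(missing_req)) {
    stop("missing required table(s): ", paste(missing_req, collapse = ", "),
         call. = FALSE)
  }
  if (!any(c("methods_aboveground", "methods_belowground", "methods_total") %in%
           names(tables))) {
    stop("at least one methodology table is required", call. = FALSE)
  }
  schema <- npp_schema()
  db <- purrr::map(rlang::set_names(npp_tables()), function(tb) {
    if (tb %in% names(tables)) {
      x <- tibble::as_tibble(tables[[tb]])
      miss <- setdiff(schema[[tb]], names(x))
      for (m in miss) x[[m]] <- NA
      x[union(schema[[tb]], names(x))]
    } else {
      empty_table(tb)
    }
  })
  db <- coerce_types(db)
  structure(db, class = "npp_database",
            validation = if (validate) validate_npp_database(db) else NULL)
}

# canonical column types: numeric / logical / character (default)
schema_numeric_cols <- function() c(
  "latitude", "longitude", "elevation", "value", "carbon_content",
  "year_start", "year_end", "series_length", "rf", "month", "temperature",
  "precipitation", "pet", "ph", "year", "years_since_disturbance",
  "years_since_thinning_or_harvest", "years_since_fertilization",
  "years_since_planting", "years_protected"
)

schema_logical_cols <- function() c(
  "component_absent", "in_litterfall", "irrigated", "annual_burning", "crop",
  "fruit_plantation", "above_treeline"
)

empty_table <- function(tb) {
  cols <- npp_schema()[[tb]]
  proto <- function(col) {
    if (col %in% schema_numeric_cols()) numeric(0)
    else if (col %in% schema_logical_cols()) logical(0)
    else character(0)
  }
  tibble::as_tibble(rlang::set_names(purrr::map(cols, proto), cols))
}

coerce_types <- function(db) {
  num <- function(x) suppressWarnings(as.numeric(x))
  chr <- as.character
  schema <- npp_schema()
  for (tb in names(schema)) {
    canon <- schema[[tb]]
    db[[tb]] <- dplyr::mutate(
      db[[tb]],
      dplyr::across(dplyr::any_of(intersect(canon, schema_numeric_cols())), num),
      dplyr::across(dplyr::any_of(intersect(canon, schema_logical_cols())),
                    as.logical),
      dplyr::across(
        dplyr::any_of(setdiff(canon, c(schema_numeric_cols(),
                                       schema_logical_cols()))), chr)
    )
  }
  db
}

#' @export
print.npp_database <- function(x, ...) {
  cat("<npp_database>\n")
  for (tb in npp_tables()) {
    n <- nrow(x[[tb]])
    if (n > 0) cat(sprintf("  %-20s %5d rows\n", tb, n))
  }
  v <- attr(x, "validation")
  if (!is.null(v)) {
    cat(sprintf("  validation: %d issue(s)\n", nrow(v)))
  }
  invisible(x)
}

#' Combined method table of a database
#'
#' @param db An `npp_database`.
#' @return Tibble with `method_id`, `name`, `scope`, `rf` across the three
#'   methodology tables.
#' @export
npp_methods <- function(db) {
  dplyr::bind_rows(
    db$methods_aboveground, db$methods_belowground, db$methods_total
  ) |>
    dplyr::distinct(.data$method_id, .keep_all = TRUE)
}

issue <- function(table, row, id, field, message) {
  tibble::tibble(table = table, row = as.integer(row), id = as.character(id),
                 field = field, message = message)
}

no_issues <- function() issue(character(0), integer(0), character(0),
                              character(0), character(0))

#' Validate an NPP database
#'
#' Checks referential integrity, enumerated fields, coordinate bounds and the
#' record-level invariants of the NPP estimates table. Every failing row is
#' reported (never silently dropped); the return value is a structured issue
#' report with one row per violation.
#'
#' Checks include: unique site and record ids; latitude/longitude within
#' bounds; biome/management/study-type/fertility vocabulary; croplands must be
#' managed; non-negative NPP values; `year_end >= year_start`;
#' `series_length >= 1`; `method_id` resolving to a methodology table with a
#' scope compatible with the component; carbon content in (0, 1] and present
#' whenever the reported unit is grams of carbon; exactly 12 monthly rows per
#' site in the climate normals.
#'
#' @param db An `npp_database` or a named list of tables.
#' @return Tibble with columns `table`, `row`, `id`, `field`, `message`.
#' @export
validate_npp_database <- function(db) {
  out <- list(no_issues())
  si <- db$site_information
  if (nrow(si)) {
    dup <- duplicated(si$site_id)
    if (any(dup)) {
      out <- c(out, list(issue("site_information", which(dup), si$site_id[dup],
                               "site_id", "duplicate site_id")))
    }
    bad_lat <- !is.na(si$latitude) & (si$latitude < -90 | si$latitude > 90)
    bad_lat <- bad_lat | is.na(si$latitude)
    bad_lon <- is.na(si$longitude) | si$longitude < -180 | si$longitude > 180
    if (any(bad_lat)) {
      out <- c(out, list(issue("site_information", which(bad_lat),
                               si$site_id[bad_lat], "latitude",
                               "coordinate out of bounds")))
    }
    if (any(bad_lon)) {
      out <- c(out, list(issue("site_information", which(bad_lon),
                               si$site_id[bad_lon], "longitude",
                               "coordinate out of bounds")))
    }
    enum_check <- function(field, allowed, optional = TRUE) {
      v <- si[[field]]
      bad <- !is.na(v) & !v %in% allowed
      if (!optional) bad <- bad | is.na(v)
      if (any(bad)) {
        issue("site_information", which(bad), si$site_id[bad], field,
              paste0("invalid ", field))
      } else no_issues()
    }
    out <- c(out, list(
      enum_check("biome", npp_biomes(), optional = FALSE),
      enum_check("management", c("managed", "unmanaged")),
      enum_check("climate_region", npp_climate_regions()),
      enum_check("study_type", c("field_assessment", "manipulation_control",
                                 "manipulation_treatment")),
      enum_check("fertility", c("L", "M", "H", "unknown"))
    ))
    crop_bad <- !is.na(si$biome) & si$biome == "cropland" &
      !is.na(si$management) & si$management != "managed"
    if (any(crop_bad)) {
      out <- c(out, list(issue("site_information", which(crop_bad),
                               si$site_id[crop_bad], "management",
                               "croplands are always managed")))
    }
  }

  npp <- db$npp_estimates
  if (nrow(npp)) {
    methods <- npp_methods(db)
    scope_tab <- component_scope_table()
    dup <- duplicated(npp$record_id)
    if (any(dup)) {
      out <- c(out, list(issue("npp_estimates", which(dup), npp$record_id[dup],
                               "record_id", "duplicate record_id")))
    }
    fk <- !npp$site_id %in% si$site_id
    if (any(fk)) {
      out <- c(out, list(issue("npp_estimates", which(fk), npp$record_id[fk],
                               "site_id", "unresolvable site_id")))
    }
    bad_comp <- !npp$component %in% npp_components()
    if (any(bad_comp)) {
      out <- c(out, list(issue("npp_estimates", which(bad_comp),
                               npp$record_id[bad_comp], "component",
                               "unknown component")))
    }
    bad_val <- !is.na(npp$value) & npp$value < 0
    if (any(bad_val)) {
      out <- c(out, list(issue("npp_estimates", which(bad_val),
                               npp$record_id[bad_val], "value",
                               "negative NPP value")))
    }
    bad_yr <- !is.na(npp$year_start) & !is.na(npp$year_end) &
      npp$year_end < npp$year_start
    if (any(bad_yr)) {
      out <- c(out, list(issue("npp_estimates", which(bad_yr),
                               npp$record_id[bad_yr], "year_end",
                               "year_end before year_start")))
    }
    bad_l <- is.na(npp$series_length) | npp$series_length < 1
    if (any(bad_l)) {
      out <- c(out, list(issue("npp_estimates", which(bad_l),
                               npp$record_id[bad_l], "series_length",
                               "series length must be >= 1 year")))
    }
    bad_m <- !is.na(npp$method_id) & !npp$method_id %in% methods$method_id
    if (any(bad_m)) {
      out <- c(out, list(issue("npp_estimates", which(bad_m),
                               npp$record_id[bad_m], "method_id",
                               "unresolvable method_id")))
    }
    # scope compatibility, only where both sides resolve
    j <- dplyr::left_join(
      dplyr::mutate(npp, .row = dplyr::row_number()),
      methods[, c("method_id", "scope")], by = "method_id"
    )
    j <- dplyr::left_join(j, scope_tab, by = "component",
                          suffix = c("_method", "_component"))
    incompat <- !is.na(j$scope_method) & !is.na(j$scope_component) &
      j$scope_component != "any" & j$scope_method != j$scope_component
    if (any(incompat)) {
      out <- c(out, list(issue("npp_estimates", j$.row[incompat],
                               j$record_id[incompat], "method_id",
                               "method scope incompatible with component")))
    }
    bad_cc <- !is.na(npp$carbon_content) &
      (npp$carbon_content <= 0 | npp$carbon_content > 1)
    if (any(bad_cc)) {
      out <- c(out, list(issue("npp_estimates", which(bad_cc),
                               npp$record_id[bad_cc], "carbon_content",
                               "carbon content outside (0, 1]")))
    }
    need_cc <- !is.na(npp$unit) & npp$unit == "g_C" & is.na(npp$carbon_content)
    if (any(need_cc)) {
      out <- c(out, list(issue("npp_estimates", which(need_cc),
                               npp$record_id[need_cc], "carbon_content",
                               "unit g_C requires an explicit carbon content")))
    }
  }

  cn <- db$climate_normals
  if (nrow(cn)) {
    cnt <- dplyr::count(cn, .data$site_id)
    bad <- cnt$n != 12
    if (any(bad)) {
      out <- c(out, list(issue("climate_normals", NA_integer_,
                               cnt$site_id[bad], "month",
                               "expected exactly 12 monthly rows")))
    }
    neg <- (!is.na(cn$precipitation) & cn$precipitation < 0) |
      (!is.na(cn$pet) & cn$pet < 0)
    if (any(neg)) {
      out <- c(out, list(issue("climate_normals", which(neg), cn$site_id[neg],
                               "precipitation", "negative precipitation or PET")))
    }
  }

  dplyr::bind_rows(out)
}

#' Issue report attached to a database
#'
#' @param db An `npp_database`.
#' @return The validation tibble recorded when the database was built or read.
#' @export
npp_validation <- function(db) {
  v <- attr(db, "validation")
  if (is.null(v)) validate_npp_database(db) else v
}

apply_mapping <- function(tables, mapping) {
  if (is.null(mapping)) return(tables)
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- yaml::read_yaml(mapping)
  }
  if (!is.null(mapping$tables)) {
    # mapping$tables: canonical -> external name
    ext <- unlist(mapping$tables)
    for (canon in names(ext)) {
      if (ext[[canon]] %in% names(tables) && !canon %in% names(tables)) {
        names(tables)[names(tables) == ext[[canon]]] <- canon
      }
    }
  }
  if (!is.null(mapping$columns)) {
    for (tb in names(mapping$columns)) {
      if (!tb %in% names(tables)) next
      cols <- unlist(mapping$columns[[tb]]) # canonical -> external
      nm <- names(tables[[tb]])
      for (canon in names(cols)) {
        nm[nm == cols[[canon]]] <- canon
      }
      names(tables[[tb]]) <- nm
    }
  }
  tables
}

#' Read an NPP database from CSV tables or SQLite
#'
#' `path` may be a directory containing one CSV file per table
#' (`<table>.csv`, UTF-8, header row) or a single SQLite file with one table
#' per CSV counterpart. A column/table-name mapping (named list, or path to a
#' YAML file with `tables:` and `columns:` entries mapping canonical to
#' external names) adapts externally named deposits to the canonical schema.
#'
#' Records reported in grams of carbon (`unit == "g_C"`) are converted to
#' grams of dry mass at load time via [to_dry_mass()] using the row's
#' `carbon_content`; rows lacking the factor are reported as validation
#' errors and left unconverted.
#'
#' @param path Directory of CSV tables or path to an SQLite file.
#' @param mapping Optional mapping (list or YAML file path).
#' @return A validated `npp_database`; inspect issues with [npp_validation()].
#' @export
read_npp_database <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    tables <- purrr::map(
      rlang::set_names(files, sub("\\.csv$", "", basename(files))),
      function(f) readr::read_csv(f, show_col_types = FALSE,
                                  progress = FALSE, guess_max = 10000)
    )
  } else {
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    on.exit(DBI::dbDisconnect(con), add = TRUE)
    tbs <- DBI::dbListTables(con)
    tables <- purrr::map(rlang::set_names(tbs),
                         function(tb) tibble::as_tibble(DBI::dbReadTable(con, tb)))
  }
  tables <- apply_mapping(tables, mapping)
  tables <- tables[intersect(names(tables), npp_tables())]
  db <- npp_database(tables, validate = FALSE)
  db <- convert_carbon_units(db)
  attr(db, "validation") <- validate_npp_database(db)
  db
}

convert_carbon_units <- function(db) {
  npp <- db$npp_estimates
  if (!nrow(npp)) return(db)
  conv <- !is.na(npp$unit) & npp$unit == "g_C" & !is.na(npp$carbon_content) &
    npp$carbon_content > 0 & npp$carbon_content <= 1
  npp$value[conv] <- to_dry_mass(npp$value[conv], npp$carbon_content[conv])
  npp$unit[conv] <- "g_dry_mass"
  db$npp_estimates <- npp
  db
}

#' Write an NPP database
#'
#' Writes the canonical table set either as a directory of CSV files (one per
#' non-empty table, RFC 4180, missing values as empty fields) or as a single
#' SQLite database with identical table and column names. A write followed by
#' [read_npp_database()] reproduces the database field-by-field.
#'
#' @param db An `npp_database`.
#' @param path Output directory (csv) or file path (sqlite).
#' @param format `"csv"` or `"sqlite"`.
#' @return `path`, invisibly.
#' @export
write_npp_database <- function(db, path, format = c("csv", "sqlite")) {
  format <- match.arg(format)
  keep <- npp_tables()[purrr::map_int(npp_tables(), ~ nrow(db[[.x]])) > 0]
  if (format == "csv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (tb in keep) {
      readr::write_csv(db[[tb]], file.path(path, paste0(tb, ".csv")), na = "")
    }
  } else {
    if (file.exists(path)) unlink(path)
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    on.exit(DBI::dbDisconnect(con), add = TRUE)
    for (tb in keep) {
      DBI::dbWriteTable(con, tb, as.data.frame(db[[tb]]))
    }
  }
  invisible(path)
}

#' Convert grams of carbon to grams of dry mass
#'
#' Production reported in g C m^-2 yr^-1 is divided by the study's carbon
#' content (fraction of dry mass that is carbon) to put it on the database's
#' common dry-mass scale.
#'
#' @param value Numeric, g C m^-2 yr^-1.
#' @param carbon_content Fraction in (0, 1].
#' @return Numeric, g dry mass m^-2 yr^-1.
#' @export
#' @examples
#' to_dry_mass(250, 0.5) # 500
to_dry_mass <- function(value, carbon_content) {
  if (any(is.na(carbon_content)) ||
      any(carbon_content <= 0 | carbon_content > 1)) {
    stop("carbon_content must be in (0, 1]", call. = FALSE)
  }
  value / carbon_content
}

#' Per-component site means and their total
#'
#' Aggregates one site's component-level records to the site level: the mean
#' of the available entries per component, with components verified absent
#' contributing zero, and a `total` row equal to the sum of the component
#' means. If any supplied component is neither measured nor flagged absent
#' (value missing), the total carries `incomplete = TRUE`.
#'
#' @param records Tibble of one site's NPP records with at least `component`
#'   and `value`; optional logical `component_absent`.
#' @return Tibble with columns `component`, `n`, `mean_value`, `incomplete`;
#'   the last row is the `total`.
#' @export
site_mean_npp <- function(records) {
  stopifnot(nrow(records) >= 1)
  if (!"component_absent" %in% names(records)) records$component_absent <- FALSE
  records$component_absent[is.na(records$component_absent)] <- FALSE
  per <- records |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_value = dplyr::if_else(
        all(.data$component_absent), 0,
        mean(.data$value[!.data$component_absent])
      ),
      incomplete = any(is.na(.data$value) & !.data$component_absent),
      .groups = "drop"
    )
  total <- tibble::tibble(
    component = "total",
    n = sum(per$n),
    mean_value = sum(per$mean_value, na.rm = FALSE),
    incomplete = any(per$incomplete)
  )
  dplyr::bind_rows(per, total)
}
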