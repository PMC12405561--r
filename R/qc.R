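#' Coordinate sanity check
#'
#' Flags sites with out-of-range coordinates and, when a land mask is
#' supplied, sites whose nearest mask cell is ocean. QC never mutates the
#' data; the return value is a report.
#'
#' @param sites Tibble with `site_id`, `latitude`, `longitude`.
#' @param land_mask Optional gridded boolean mask: a tibble with `longitude`,
#'   `latitude` (cell centers on a regular grid) and logical `land`.
#' @return Tibble `site_id`, `reason`.
#' @export
check_coordinates <- function(sites, land_mask = NULL) {
  bad <- is.na(sites$latitude) | is.na(sites$longitude) |
    abs(sites$latitude) > 90 | abs(sites$longitude) > 180
  out <- tibble::tibble(site_id = sites$site_id[bad],
                        reason = "coordinate out of bounds")
  if (!is.null(land_mask)) {
    need <- c("longitude", "latitude", "land")
    if (!all(need %in% names(land_mask)) || !is.logical(land_mask$land)) {
      stop("land mask needs longitude, latitude and logical land columns",
           call. = FALSE)
    }
    ok <- sites[!bad, , drop = FALSE]
    if (nrow(ok)) {
      on_land <- purrr::map_lgl(seq_len(nrow(ok)), function(i) {
        d <- (land_mask$longitude - ok$longitude[i])^2 +
          (land_mask$latitude - ok$latitude[i])^2
        land_mask$land[which.min(d)]
      })
      out <- dplyr::bind_rows(out, tibble::tibble(
        site_id = ok$site_id[!on_land], reason = "site not on land"
      ))
    }
  }
  out
}

#' Summation-consistency check
#'
#' Recomputes every summation level from the component records (via
#' [compute_levels()]) and compares it with the aggregate value reported in
#' the database's `reported_levels` table, flagging absolute differences above
#' the tolerance. The default tolerance of 1 g m^-2 yr^-1 absorbs rounding in
#' source tables.
#'
#' @param db An `npp_database` with a non-empty `reported_levels` table.
#' @param tolerance Allowed absolute difference, g m^-2 yr^-1.
#' @return Tibble `site_id`, `level`, `stored_value`, `recomputed_value`,
#'   `abs_diff`.
#' @export
check_summation <- function(db, tolerance = 1) {
  stored <- db$reported_levels
  if (!nrow(stored)) {
    stop("database has no reported aggregate levels to check", call. = FALSE)
  }
  recomputed <- summarize_levels(db) |>
    dplyr::filter(.data$status == "complete") |>
    dplyr::select("site_id", "level", recomputed_value = "value")
  dplyr::inner_join(
    dplyr::select(stored, "site_id", "level", stored_value = "value"),
    recomputed,
    by = c("site_id", "level")
  ) |>
    dplyr::mutate(abs_diff = abs(.data$stored_value - .data$recomputed_value)) |>
    dplyr::filter(.data$abs_diff > tolerance)
}

#' Stratified boxplot outlier flagging
#'
#' Flags site-level ANPP and BNPP values outside the standard boxplot fences
#' `[Q1 - k IQR, Q3 + k IQR]` computed within each biome or climate-region
#' stratum. Strata with fewer than `min_stratum` sites are skipped with a
#' warning; flagged sites were double-checked, not removed, in the
#' harmonization this mirrors.
#'
#' @param site_means Tibble as from [site_npp_means()] (`site_id`, `biome`,
#'   `climate_region`, `anpp`, `bnpp`).
#' @param stratify_by `"biome"` or `"climate_region"`.
#' @param k IQR multiplier (1.5 = conventional whiskers).
#' @param min_stratum Minimum stratum size for fences.
#' @return Tibble `site_id`, `stratum`, `variable`, `value`, `fence_low`,
#'   `fence_high`.
#' @export
flag_outliers <- function(site_means, stratify_by = c("biome", "climate_region"),
                          k = 1.5, min_stratum = 5) {
  stratify_by <- match.arg(stratify_by)
  long <- site_means |>
    tidyr::pivot_longer(dplyr::any_of(c("anpp", "bnpp")),
                        names_to = "variable", values_to = "value") |>
    dplyr::mutate(variable = toupper(.data$variable),
                  stratum = .data[[stratify_by]]) |>
    dplyr::filter(!is.na(.data$value), !is.na(.data$stratum))
  sizes <- dplyr::count(long, .data$stratum, .data$variable)
  small <- unique(sizes$stratum[sizes$n < min_stratum])
  if (length(small)) {
    warning("stratum/strata skipped (fewer than ", min_stratum, " sites): ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  long |>
    dplyr::group_by(.data$stratum, .data$variable) |>
    dplyr::filter(dplyr::n() >= min_stratum) |>
    dplyr::mutate(
      q1 = stats::quantile(.data$value, 0.25, type = 7, names = FALSE),
      q3 = stats::quantile(.data$value, 0.75, type = 7, names = FALSE),
      fence_low = .data$q1 - k * (.data$q3 - .data$q1),
      fence_high = .data$q3 + k * (.data$q3 - .data$q1)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$value < .data$fence_low |
                    .data$value > .data$fence_high) |>
    dplyr::select("site_id", "stratum", "variable", "value",
                  "fence_low", "fence_high")
}

#' Full quality-control report
#'
#' Bundles the three technical-validation checks — coordinate sanity,
#' summation consistency and stratified outlier flagging — into one report
#' object. Advisory only: nothing is corrected or dropped.
#'
#' @param db An `npp_database`.
#' @param land_mask Optional land mask for [check_coordinates()].
#' @param tolerance Summation tolerance, g m^-2 yr^-1.
#' @param k IQR multiplier for [flag_outliers()].
#' @param stratify_by Stratification for outliers.
#' @return A list of class `npp_qc_report` with elements `coordinate_issues`,
#'   `summation_issues`, `outliers`.
#' @export
qc_report <- function(db, land_mask = NULL, tolerance = 1, k = 1.5,
                      stratify_by = "biome") {
  summation <- if (nrow(db$reported_levels)) {
    check_summation(db, tolerance)
  } else {
    tibble::tibble(site_id = character(0), level = character(0),
                   stored_value = numeric(0), recomputed_value = numeric(0),
                   abs_diff = numeric(0))
  }
  structure(
    list(
      coordinate_issues = check_coordinates(db$site_information, land_mask),
      summation_issues = summation,
      outliers = flag_outliers(site_npp_means(db), stratify_by, k = k)
    ),
    class = "npp_qc_report"
  )
}

#' @export
print.npp_qc_report <- function(x, ...) {
  cat("<npp_qc_report>\n")
  cat("  coordinate issues:", nrow(x$coordinate_issues), "\n")
  cat("  summation issues: ", nrow(x$summation_issues), "\n")
  cat("  outliers flagged: ", nrow(x$outliers), "\n")
  invisible(x)
}
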