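#' Biome-specific spread of a component class
#'
#' Half the 90th-10th interpercentile range of the site-level values of one
#' component class (ANPP, BNPP or TNPP) within one biome. This spread is the
#' biome-level scale P that the method reduction factors shrink into
#' per-measurement uncertainties.
#'
#' @param values Numeric vector of site-level NPP values (g m^-2 yr^-1), at
#'   least two.
#' @param percentile_method `"linear"` (interpolation between order
#'   statistics, the default) or `"nearest"` (nearest-rank percentiles).
#' @return Half interpercentile range, g m^-2 yr^-1.
#' @export
#' @examples
#' biome_variance(0:10) # (9 - 1) / 2 = 4
biome_variance <- function(values, percentile_method = c("linear", "nearest")) {
  percentile_method <- match.arg(percentile_method)
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    stop("need at least 2 values to estimate a biome spread", call. = FALSE)
  }
  type <- if (percentile_method == "linear") 7L else 1L
  q <- stats::quantile(values, c(0.1, 0.9), type = type, names = FALSE)
  (q[2] - q[1]) / 2
}

#' Per-measurement uncertainty
#'
#' The uncertainty attached to a single measurement: the biome spread P of the
#' component class, shrunk by the method's reduction factor and by the square
#' root of the measurement-series length (multiyear averages are less
#' uncertain): `S = P * rf / sqrt(l)`.
#'
#' @param p Biome spread, g m^-2 yr^-1 (non-negative).
#' @param rf Method reduction factor in (0, 1].
#' @param l Series length in years (>= 1).
#' @return Uncertainty S, g m^-2 yr^-1. Vectorized over all arguments.
#' @export
#' @examples
#' measurement_uncertainty(100, 0.4, 4) # 20
measurement_uncertainty <- function(p, rf, l) {
  if (any(is.na(l)) || any(l < 1)) {
    stop("series length l must be >= 1 year", call. = FALSE)
  }
  if (any(p < 0, na.rm = TRUE)) stop("P must be non-negative", call. = FALSE)
  if (any(rf <= 0 | rf > 1, na.rm = TRUE)) {
    stop("rf must be in (0, 1]", call. = FALSE)
  }
  p * rf / sqrt(l)
}

#' Average reduction factor over the methods of one estimate
#'
#' When several methods (one per component) underlie a single above- or
#' belowground estimate, the reported reduction factor is their arithmetic
#' mean rounded to one decimal place. An exact midpoint (mean ending in .x5)
#' is rounded toward the reduction factor of the dominant component — fine
#' roots for belowground estimates, the largest-flux component for
#' aboveground ones — since that component carries most of the flux and hence
#' most of the uncertainty. With unknown dominance midpoints round down
#' (toward the more accurate method).
#'
#' @param rf Numeric vector of method reduction factors (tenths in (0, 1]).
#' @param component Optional character vector naming the component each method
#'   measured (same length as `rf`).
#' @param dominant Optional name of the dominant component; must occur in
#'   `component`.
#' @param scope Optional character vector of the methods' scopes; mixing
#'   aboveground and belowground methods is an error.
#' @return Single reduction factor, rounded to one decimal.
#' @export
#' @examples
#' average_rf(c(0.3, 0.6), component = c("fine_root", "coarse_root"),
#'            dominant = "fine_root") # 0.4
average_rf <- function(rf, component = NULL, dominant = NULL, scope = NULL) {
  if (length(rf) < 1) stop("need at least one method", call. = FALSE)
  if (any(rf <= 0 | rf > 1)) stop("rf must be in (0, 1]", call. = FALSE)
  if (!is.null(scope) && length(unique(scope)) > 1) {
    stop("cannot average reduction factors across above/belowground scopes",
         call. = FALSE)
  }
  tenths <- round(rf * 10)
  m <- mean(tenths) # mean in units of 0.1
  lo <- floor(m)
  hi <- ceiling(m)
  if (abs(m - lo - 0.5) < 1e-9) {
    dom_rf <- NULL
    if (!is.null(dominant) && !is.null(component) && dominant %in% component) {
      dom_rf <- tenths[match(dominant, component)]
    }
    r <- if (!is.null(dom_rf)) {
      if (dom_rf <= lo) lo else hi
    } else {
      lo # unknown dominance: round half down
    }
  } else {
    r <- round(m)
  }
  r / 10
}

#' Propagate above- and belowground uncertainties to total NPP
#'
#' Euclidean (root-sum-square) combination of the uncertainties of the two
#' independent parts of a total NPP estimate.
#'
#' @param s_anpp,s_bnpp Non-negative uncertainties, g m^-2 yr^-1.
#' @return Total-NPP uncertainty. Vectorized.
#' @export
#' @examples
#' propagate_total(3, 4) # 5
propagate_total <- function(s_anpp, s_bnpp) {
  if (any(s_anpp < 0 | s_bnpp < 0, na.rm = TRUE)) {
    stop("uncertainties must be non-negative", call. = FALSE)
  }
  sqrt(s_anpp^2 + s_bnpp^2)
}

#' Site-level uncertainty from repeated measurements
#'
#' Aggregates the per-measurement uncertainties of one component class at one
#' site: the root-sum-square divided by the number of measurements N, so that
#' N equal measurements yield `s / sqrt(N)`.
#'
#' @param s Numeric vector of per-measurement uncertainties (>= 1 value).
#' @return Site-level uncertainty.
#' @export
#' @examples
#' site_uncertainty(c(10, 10, 10, 10)) # 5
site_uncertainty <- function(s) {
  s <- s[!is.na(s)]
  if (length(s) < 1) stop("need at least one measurement", call. = FALSE)
  sqrt(sum(s^2)) / length(s)
}

# scope classification of a record's component class
component_class_of_scope <- function(scope) {
  c(aboveground = "ANPP", belowground = "BNPP", total = "TNPP")[scope]
}

#' Site-level NPP means by component class
#'
#' Per-site aboveground (ANPP), belowground (BNPP) and total (TNPP) values
#' from the component means: ANPP sums the aboveground component means, BNPP
#' the root components, and TNPP their sum — or the mean of direct total-NPP
#' records for sites measured only by a total-scope method.
#'
#' @param db An `npp_database`.
#' @return Tibble `site_id`, `biome`, `climate_region`, `anpp`, `bnpp`,
#'   `tnpp`.
#' @export
site_npp_means <- function(db) {
  scope_tab <- component_scope_table()
  npp <- db$npp_estimates |>
    dplyr::filter(!is.na(.data$value) | .data$component_absent) |>
    dplyr::left_join(scope_tab, by = "component") |>
    dplyr::mutate(scope = dplyr::if_else(.data$scope == "any", "belowground",
                                         .data$scope))
  per <- npp |>
    dplyr::group_by(.data$site_id, .data$component, .data$scope) |>
    dplyr::summarise(
      mean_value = dplyr::if_else(
        all(.data$component_absent), 0,
        mean(.data$value[!.data$component_absent])
      ),
      .groups = "drop"
    )
  wide <- per |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      anpp = sum(.data$mean_value[.data$scope == "aboveground"]),
      bnpp = sum(.data$mean_value[.data$scope == "belowground"]),
      total_direct = mean(.data$mean_value[.data$component == "total_npp"]),
      has_parts = any(.data$scope != "total"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      anpp = dplyr::if_else(.data$has_parts, .data$anpp, NA_real_),
      bnpp = dplyr::if_else(.data$has_parts, .data$bnpp, NA_real_),
      tnpp = dplyr::if_else(.data$has_parts, .data$anpp + .data$bnpp,
                            .data$total_direct)
    ) |>
    dplyr::select("site_id", "anpp", "bnpp", "tnpp")
  dplyr::left_join(
    wide,
    db$site_information[, c("site_id", "biome", "climate_region")],
    by = "site_id"
  ) |>
    dplyr::relocate("biome", "climate_region", .after = "site_id")
}

#' Biome-by-component-class spread table
#'
#' Computes the P table (one spread per biome and component class) from the
#' site-level values of a database. Cells with fewer than two sites fall back
#' to the spread pooled across all biomes, with a warning.
#'
#' @param db An `npp_database`.
#' @inheritParams biome_variance
#' @return Tibble `biome`, `component_class`, `p`, `n_sites`, `pooled`
#'   (logical: fallback used).
#' @export
biome_variance_table <- function(db, percentile_method = c("linear", "nearest")) {
  percentile_method <- match.arg(percentile_method)
  sm <- site_npp_means(db)
  long <- sm |>
    tidyr::pivot_longer(c("anpp", "bnpp", "tnpp"),
                        names_to = "component_class", values_to = "value") |>
    dplyr::mutate(component_class = toupper(.data$component_class)) |>
    dplyr::filter(!is.na(.data$value), !is.na(.data$biome))
  pooled <- long |>
    dplyr::group_by(.data$component_class) |>
    dplyr::summarise(p_pooled = biome_variance(.data$value, percentile_method),
                     .groups = "drop")
  out <- long |>
    dplyr::group_by(.data$biome, .data$component_class) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      p = if (dplyr::n() >= 2) biome_variance(.data$value, percentile_method)
      else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::left_join(pooled, by = "component_class") |>
    dplyr::mutate(
      pooled = is.na(.data$p),
      p = dplyr::coalesce(.data$p, .data$p_pooled)
    ) |>
    dplyr::select("biome", "component_class", "p", "n_sites", "pooled")
  if (any(out$pooled)) {
    warning(sum(out$pooled),
            " biome/component cell(s) had < 2 sites; pooled spread used",
            call. = FALSE)
  }
  out
}

#' Method-specific uncertainty estimates for every site
#'
#' Runs the full uncertainty chain over a validated database: derives the
#' biome-by-component-class spread table from the data themselves (or accepts
#' a precomputed one), computes a per-measurement uncertainty
#' `S = P * rf / sqrt(l)` for every measurement campaign (records grouped by
#' site, scope and measurement years; the campaign reduction factor is the
#' rounded mean of its per-component method factors, midpoints resolved
#' toward fine roots for BNPP and the largest-flux component for ANPP),
#' aggregates campaigns to site level by root-sum-square over N, and
#' propagates the above- and belowground parts to a total-NPP uncertainty.
#' Sites measured only with total-scope methods (e.g. eddy covariance) get
#' their `s_tnpp` directly from the TNPP spread, bypassing the propagation.
#'
#' @param db An `npp_database`.
#' @param p_table Optional precomputed spread table (as from
#'   [biome_variance_table()], columns `biome`, `component_class`, `p`) to use
#'   instead of recomputing, e.g. for exact replication of published spreads.
#' @inheritParams biome_variance
#' @return Tibble with one row per site: `site_id`, `biome`, `s_anpp`,
#'   `s_bnpp`, `s_tnpp`, `rf_anpp`, `rf_bnpp`, `n_anpp`, `n_bnpp`.
#' @export
database_uncertainty <- function(db, p_table = NULL,
                                 percentile_method = c("linear", "nearest")) {
  percentile_method <- match.arg(percentile_method)
  if (is.null(p_table)) {
    p_table <- biome_variance_table(db, percentile_method)
  }
  methods <- npp_methods(db)
  si <- db$site_information[, c("site_id", "biome")]

  recs <- db$npp_estimates |>
    dplyr::filter(!.data$component_absent | is.na(.data$component_absent)) |>
    dplyr::inner_join(methods[, c("method_id", "scope", "rf")],
                      by = "method_id") |>
    dplyr::inner_join(si, by = "site_id") |>
    dplyr::mutate(component_class = component_class_of_scope(.data$scope))

  # one row per measurement campaign: site x class x measurement years
  campaigns <- recs |>
    dplyr::group_by(.data$site_id, .data$biome, .data$component_class,
                    .data$year_start, .data$year_end) |>
    dplyr::summarise(
      rf = {
        dom <- if (.data$component_class[[1]] == "BNPP" &&
                   "fine_root" %in% .data$component) {
          "fine_root"
        } else if (all(is.na(.data$value))) NULL
        else .data$component[which.max(.data$value)]
        average_rf(.data$rf, component = .data$component, dominant = dom)
      },
      l = max(.data$series_length),
      .groups = "drop"
    ) |>
    dplyr::left_join(p_table[, c("biome", "component_class", "p")],
                     by = c("biome", "component_class")) |>
    dplyr::mutate(s = measurement_uncertainty(.data$p, .data$rf, .data$l))

  per_site <- campaigns |>
    dplyr::group_by(.data$site_id, .data$biome, .data$component_class) |>
    dplyr::summarise(
      s = site_uncertainty(.data$s),
      rf = average_rf(.data$rf),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "component_class",
                       values_from = c("s", "rf", "n"))
  for (col in c("s_ANPP", "s_BNPP", "s_TNPP", "rf_ANPP", "rf_BNPP",
                "n_ANPP", "n_BNPP")) {
    if (!col %in% names(per_site)) per_site[[col]] <- NA_real_
  }
  per_site |>
    dplyr::mutate(
      s_tnpp = dplyr::case_when(
        !is.na(.data$s_ANPP) & !is.na(.data$s_BNPP) ~
          propagate_total(.data$s_ANPP, .data$s_BNPP),
        !is.na(.data$s_TNPP) ~ .data$s_TNPP,
        TRUE ~ NA_real_
      )
    ) |>
    dplyr::transmute(
      site_id = .data$site_id, biome = .data$biome,
      s_anpp = .data$s_ANPP, s_bnpp = .data$s_BNPP, s_tnpp = .data$s_tnpp,
      rf_anpp = .data$rf_ANPP, rf_bnpp = .data$rf_BNPP,
      n_anpp = .data$n_ANPP, n_bnpp = .data$n_BNPP
    )
}
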