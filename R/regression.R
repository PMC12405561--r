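#' Classic Miami-model parameters
#'
#' The empirical coefficients of the classic Miami formulation: asymptote
#' A = 3000 g m^-2 yr^-1, temperature intercept b = 1.315 and slope
#' c = 0.119 degC^-1 of the logistic temperature branch, and precipitation
#' rate d = 0.000664 mm^-1 of the saturating precipitation branch.
#'
#' @return Named numeric vector `c(A, b, c, d)`.
#' @export
miami_params_classic <- function() {
  c(A = 3000, b = 1.315, c = 0.119, d = 0.000664)
}

#' Miami-model NPP prediction
#'
#' NPP as the minimum of a temperature-limited logistic branch and a
#' precipitation-limited saturating branch:
#' `NPP = min(A / (1 + exp(b - c T)), A (1 - exp(-d P)))`
#' with T the mean annual temperature (degC) and P the annual precipitation
#' (mm). Zero precipitation forces zero NPP; both branches saturate at the
#' asymptote A.
#'
#' @param mat Mean annual temperature, degC.
#' @param map Annual precipitation, mm.
#' @param params Named vector with `A`, `b`, `c`, `d`; defaults to the
#'   classic coefficients.
#' @return Predicted NPP, g dry mass m^-2 yr^-1. Vectorized.
#' @export
#' @examples
#' miami_predict(27, 2000)
miami_predict <- function(mat, map, params = miami_params_classic()) {
  npp_t <- params[["A"]] / (1 + exp(params[["b"]] - params[["c"]] * mat))
  npp_p <- params[["A"]] * (1 - exp(-params[["d"]] * map))
  pmin(npp_t, npp_p)
}

miami_objective <- function(theta, mat, map, npp, w) {
  # theta on an unconstrained scale: log A, b, log c, log d
  params <- c(A = exp(theta[1]), b = theta[2], c = exp(theta[3]),
              d = exp(theta[4]))
  r <- npp - miami_predict(mat, map, params)
  sum(w * r^2)
}

#' Fit the Miami model to site climate and NPP
#'
#' Weighted nonlinear least squares on
#' `sum_i w_i (NPP_i - Miami(T_i, P_i))^2` with `w_i = 1 / S_i^2` when
#' `weighted = TRUE` (S the site-level NPP uncertainty) and `w_i = 1`
#' otherwise, so noisy high-uncertainty sites are down-weighted. Because the
#' `min()` of the two branches makes the objective non-smooth, fitting uses
#' derivative-free Nelder-Mead restarts (`n_starts` jittered initializations
#' around the classic coefficients, positive parameters on the log scale)
#' with a fixed seed, keeping the best converged start.
#'
#' Sites with `S = 0` cannot enter a 1/S^2 weight; they are floored at the
#' smallest positive S in the data, with a message.
#'
#' @param data Tibble with columns `mat` (degC), `map` (mm), `npp`
#'   (g m^-2 yr^-1), and `s` (uncertainty, required when `weighted`).
#' @param weighted Use 1/S^2 weights?
#' @param start Named starting vector (`A`, `b`, `c`, `d`).
#' @param n_starts Number of multi-start initializations.
#' @param seed Seed for the start jitter (fit is deterministic given it).
#' @return A `miami_fit` object; see [tidy.miami_fit()], [glance.miami_fit()],
#'   [autoplot.miami_fit()].
#' @export
fit_miami <- function(data, weighted = FALSE,
                      start = miami_params_classic(), n_starts = 8,
                      seed = 17) {
  stopifnot(all(c("mat", "map", "npp") %in% names(data)))
  data <- tibble::as_tibble(data)
  if (nrow(data) < 10) stop("need at least 10 sites to fit", call. = FALSE)
  if (weighted) {
    if (!"s" %in% names(data) || any(is.na(data$s))) {
      stop("weighted fit needs a complete uncertainty column `s`",
           call. = FALSE)
    }
    s <- data$s
    if (any(s < 0)) stop("uncertainties must be non-negative", call. = FALSE)
    if (any(s == 0)) {
      floor_s <- min(s[s > 0])
      if (!is.finite(floor_s)) stop("all uncertainties are zero", call. = FALSE)
      message(sum(s == 0), " site(s) with S = 0 floored at the smallest ",
              "positive S (", signif(floor_s, 3), ")")
      s[s == 0] <- floor_s
    }
    w <- 1 / s^2
  } else {
    w <- rep(1, nrow(data))
  }

  theta0 <- c(log(start[["A"]]), start[["b"]], log(start[["c"]]),
              log(start[["d"]]))
  starts <- local({
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    rbind(theta0,
          t(replicate(max(0, n_starts - 1),
                      theta0 + stats::rnorm(4, sd = c(0.3, 0.5, 0.3, 0.3)))))
  })

  fits <- apply(starts, 1, function(th) {
    stats::optim(th, miami_objective, mat = data$mat, map = data$map,
                 npp = data$npp, w = w, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
  })
  objective_values <- purrr::map_dbl(fits, "value")
  converged <- purrr::map_int(fits, "convergence") == 0L
  if (!any(is.finite(objective_values))) {
    stop("Miami fit failed to converge from any start; objectives: ",
         paste(signif(objective_values, 3), collapse = ", "), call. = FALSE)
  }
  best <- fits[[which.min(objective_values)]]
  params <- c(A = exp(best$par[1]), b = best$par[2], c = exp(best$par[3]),
              d = exp(best$par[4]))
  structure(
    list(
      params = params,
      weighted = weighted,
      fitted = miami_predict(data$mat, data$map, params),
      objective = best$value,
      converged = converged[[which.min(objective_values)]],
      n_starts = nrow(starts),
      start_objectives = unname(objective_values),
      data = data,
      weights = w
    ),
    class = "miami_fit"
  )
}

#' @export
print.miami_fit <- function(x, ...) {
  cat("<miami_fit>", if (x$weighted) "(uncertainty-weighted)" else "(unweighted)", "\n")
  cat("  A =", signif(x$params[["A"]], 5), "g m-2 yr-1;",
      "b =", signif(x$params[["b"]], 4), ";",
      "c =", signif(x$params[["c"]], 4), "degC-1;",
      "d =", signif(x$params[["d"]], 4), "mm-1\n")
  cat("  objective:", signif(x$objective, 6), "over", nrow(x$data), "sites\n")
  invisible(x)
}

#' Tidy a Miami fit
#'
#' @param x A `miami_fit`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`.
#' @export
tidy.miami_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' One-row summary of a Miami fit
#'
#' @param x A `miami_fit`.
#' @param ... Unused.
#' @return Tibble with `objective`, `nobs`, `weighted`, `converged`,
#'   `n_starts`.
#' @export
glance.miami_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    nobs = nrow(x$data),
    weighted = x$weighted,
    converged = x$converged,
    n_starts = x$n_starts
  )
}

#' Predict from a Miami fit
#'
#' @param object A `miami_fit`.
#' @param newdata Tibble with `mat` and `map`; defaults to the training data.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.miami_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  miami_predict(newdata$mat, newdata$map, object$params)
}

#' Observed-versus-fitted plot for a Miami fit
#'
#' @param object A `miami_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.miami_fit <- function(object, ...) {
  df <- tibble::tibble(observed = object$data$npp, fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "fitted NPP (g m⁻² yr⁻¹)",
      y = "observed NPP (g m⁻² yr⁻¹)",
      title = if (object$weighted) "Miami fit (uncertainty-weighted)"
      else "Miami fit (unweighted)"
    )
}

#' Compare weighted and unweighted Miami fits
#'
#' Relative difference in mean predicted NPP between an unweighted and a
#' weighted fit over a common evaluation set:
#' `(mean_unweighted - mean_weighted) / mean_unweighted`. Positive values mean
#' the uncertainty-weighted fit predicts lower NPP — the expected direction
#' when measurement noise grows with NPP, since weighting down-weights the
#' noisy high values.
#'
#' @param weighted_fit,unweighted_fit `miami_fit` objects.
#' @param newdata Evaluation set with `mat`, `map`; defaults to the weighted
#'   fit's training data.
#' @return List with `relative_difference`, `mean_weighted`,
#'   `mean_unweighted`.
#' @export
compare_fits <- function(weighted_fit, unweighted_fit, newdata = NULL) {
  stopifnot(inherits(weighted_fit, "miami_fit"),
            inherits(unweighted_fit, "miami_fit"))
  if (is.null(newdata)) newdata <- weighted_fit$data
  mw <- mean(predict(weighted_fit, newdata))
  mu <- mean(predict(unweighted_fit, newdata))
  list(
    relative_difference = (mu - mw) / mu,
    mean_weighted = mw,
    mean_unweighted = mu
  )
}
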