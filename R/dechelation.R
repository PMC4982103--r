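#' Initial rate from a progress curve
#'
#' Extracts the initial rate of a reaction by ordinary least squares over an
#' early time window, the standard treatment of a slow first-order decay
#' observed over a short interval (here, magnesium porphyrin dechelation
#' followed for five minutes while its half-time is about six hours, so the
#' curvature bias is ~0.5%).
#'
#' @param curve A data frame whose first column is `time_s` (strictly
#'   increasing, starting at or after 0) and whose second column is the
#'   concentration series (e.g. `conc_M` or `MgD_M`).
#' @param window_s Length of the fitting window in seconds, starting at
#'   t = 0; default 300 (a 5-min time course).
#' @return A list with `rate_M_per_s` (slope magnitude; dechelation rates are
#'   reported positive), `se_M_per_s` (standard error of the slope) and
#'   `n_points`.
#' @examples
#' tt <- seq(0, 300, 10)
#' cv <- data.frame(time_s = tt, conc_M = 2.5e-6 - 7.925e-11 * tt)
#' initial_rate(cv)$rate_M_per_s
#' @export
initial_rate <- function(curve, window_s = 300) {
  curve <- as.data.frame(curve)
  if (ncol(curve) < 2L) stop("curve needs a time column and a value column",
                             call. = FALSE)
  t <- curve[[1L]]
  y <- curve[[2L]]
  if (any(!is.finite(t)) || any(!is.finite(y))) {
    stop("curve contains non-finite values", call. = FALSE)
  }
  if (any(diff(t) <= 0)) {
    stop("time grid must be strictly increasing", call. = FALSE)
  }
  keep <- t >= 0 & t <= window_s
  if (sum(keep) < 3L) {
    stop("need at least 3 points inside the initial-rate window", call. = FALSE)
  }
  tw <- t[keep]
  yw <- y[keep]
  n <- length(tw)
  sxx <- sum((tw - mean(tw))^2)
  slope <- sum((tw - mean(tw)) * (yw - mean(yw))) / sxx
  rss <- sum((yw - mean(yw) - slope * (tw - mean(tw)))^2)
  se <- sqrt(rss / (n - 2) / sxx)
  list(rate_M_per_s = abs(slope),
       se_M_per_s = se,
       n_points = n)
}

#' Fit the first-order dechelation rate constant
#'
#' Through-origin least squares of initial dechelation rate against
#' concentration: for a first-order process the rate is k*c with zero rate
#' forced at zero concentration, so a single slope is fitted,
#' k = sum(c_i r_i) / sum(c_i^2), with standard error
#' sqrt(sum((r_i - k c_i)^2) / ((n - 1) * sum(c_i^2))) for n >= 2 (0 for
#' n = 1).
#'
#' Note the SE assumes homoscedastic rate errors; when the measurement error
#' is multiplicative (constant CV) it underestimates the sampling error of k
#' because the residual variance grows with concentration (see the methods
#' vignette).
#'
#' @param data A data frame with columns `conc_M` (> 0) and `rate_M_per_s`
#'   (>= 0, positive-magnitude convention); an optional `rate_se_M_per_s`
#'   column is carried through but not used as weights.
#' @return An object of class `first_order_fit`: a list with `k_dechel_per_s`,
#'   `k_se_per_s`, `n_points` and `residuals_M_per_s`.
#' @examples
#' d <- data.frame(conc_M = c(1, 2, 4) * 1e-6,
#'                 rate_M_per_s = c(3.17e-11, 6.34e-11, 1.268e-10))
#' fit_first_order_constant(d)$k_dechel_per_s
#' @export
fit_first_order_constant <- function(data) {
  data <- as.data.frame(data)
  if (!all(c("conc_M", "rate_M_per_s") %in% names(data))) {
    stop("data must have columns 'conc_M' and 'rate_M_per_s'", call. = FALSE)
  }
  conc <- data$conc_M
  rate <- data$rate_M_per_s
  n <- length(conc)
  if (n < 1L) stop("need at least one measurement", call. = FALSE)
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("all concentrations must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop("all rates must be finite and >= 0", call. = FALSE)
  }
  k <- sum(conc * rate) / sum(conc^2)
  resid <- rate - k * conc
  se <- if (n >= 2L) sqrt(sum(resid^2) / ((n - 1) * sum(conc^2))) else 0
  structure(list(k_dechel_per_s = k, k_se_per_s = se, n_points = n,
                 residuals_M_per_s = resid),
            class = "first_order_fit")
}

#' @export
print.first_order_fit <- function(x, ...) {
  cat(sprintf("First-order dechelation fit (n = %d)\n", x$n_points))
  cat(sprintf("  k_dechel = %.4g +/- %.2g s^-1\n",
              x$k_dechel_per_s, x$k_se_per_s))
  invisible(x)
}

#' Second-order uncatalyzed chelation constant
#'
#' By microscopic reversibility the association equilibrium constant is the
#' ratio of forward to reverse rate constants, K_eq = k_on / k_off, so the
#' second-order rate constant for uncatalyzed metal-ion chelation is
#' k_uncat = K_eq * k_dechel.
#'
#' @param K_eq_per_M Association equilibrium constant (M^-1, >= 0).
#' @param k_dechel_per_s First-order dechelation constant (s^-1, >= 0).
#' @return k_uncat in M^-1 s^-1.
#' @examples
#' chelation_second_order_constant(1e-6, 3.17e-5)  # ~3.17e-11
#' @export
chelation_second_order_constant <- function(K_eq_per_M, k_dechel_per_s) {
  if (!is.numeric(K_eq_per_M) || K_eq_per_M < 0 || is.na(K_eq_per_M) ||
      !is.numeric(k_dechel_per_s) || k_dechel_per_s < 0 ||
      is.na(k_dechel_per_s)) {
    stop("K_eq_per_M and k_dechel_per_s must be >= 0", call. = FALSE)
  }
  K_eq_per_M * k_dechel_per_s
}

#' Pseudo-first-order half-life of uncatalyzed chelation
#'
#' At a fixed free-metal concentration the bimolecular chelation step is
#' pseudo-first-order with rate constant k_uncat * [Mg2+], giving a half-life
#' of ln(2) / (k_uncat * [Mg2+]). At the package defaults and 1 mM Mg2+ this
#' is about 0.7 million years.
#'
#' @param k_uncat_per_M_s Second-order chelation constant (M^-1 s^-1, > 0).
#' @param mg_conc_M Free Mg2+ concentration (M, > 0).
#' @return Half-life in seconds; convert with [seconds_to_years()].
#' @examples
#' seconds_to_years(pseudo_first_order_halflife(3.17e-11, 1e-3))
#' @export
pseudo_first_order_halflife <- function(k_uncat_per_M_s, mg_conc_M) {
  if (!is.numeric(k_uncat_per_M_s) || is.na(k_uncat_per_M_s) ||
      k_uncat_per_M_s <= 0 || !is.numeric(mg_conc_M) || is.na(mg_conc_M) ||
      mg_conc_M <= 0) {
    stop("half-life undefined: k_uncat and mg_conc must be > 0", call. = FALSE)
  }
  log(2) / (k_uncat_per_M_s * mg_conc_M)
}

#' Convert seconds to Julian years
#'
#' Uses the Julian year of 3.15576e7 s, so rounding of geological half-times
#' is reproducible.
#'
#' @param s Duration in seconds.
#' @return Duration in years.
#' @export
seconds_to_years <- function(s) {
  s / 3.15576e7
}
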