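# Michaelis-Menten kinetics ----------------------------------------------
#
# Unit contract: substrate concentrations and KM in mM; enzyme
# concentration E0 in uM; rates in uM product per second, so that
# kcat = Vmax / E0 is in s^-1 and kcat/KM in mM^-1 s^-1.

#' Initial rate from a reaction progress curve
#'
#' Least-squares slope of signal vs time over the stated linear window.
#'
#' @param time_points Numeric times.
#' @param signal Numeric signal (e.g. product peak area) at each time.
#' @param window Length-2 numeric `c(t0, t1)`; points with
#'   `t0 <= t <= t1` are used (default: all points).
#' @return The fitted slope (signal units per time unit).
#' @export
initial_rate <- function(time_points, signal, window = range(time_points)) {
  stopifnot(length(time_points) == length(signal), length(window) == 2L)
  keep <- time_points >= window[1] & time_points <= window[2]
  if (sum(keep) < 3L) stop("fewer than 3 points in the linear window")
  unname(stats::coef(stats::lm(signal[keep] ~ time_points[keep]))[2L])
}

#' Read a kinetics CSV
#'
#' @param path CSV with header columns `substrate_mM`, `rate`, and
#'   optionally `replicate`.
#' @return Data frame suitable for [fit_michaelis_menten()].
#' @export
read_kinetics_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("substrate_mM", "rate")
  if (!all(need %in% names(df)))
    stop("kinetics CSV must have columns: ", paste(need, collapse = ", "))
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  df
}

#' Fit Michaelis-Menten kinetics
#'
#' Nonlinear least squares on `v = Vmax * S / (KM + S)` with starting values
#' from a Hanes-Woolf linearisation (`S/v` vs `S`).  Derived constants:
#' `kcat = Vmax / E0` (rates in uM/s, E0 in uM, so kcat is in 1/s) and the
#' catalytic efficiency `kcat / KM` (mM^-1 s^-1).  Standard errors of the
#' derived constants come from the fit covariance by the delta method.
#'
#' @param data Data frame with columns `substrate_mM` (> 0) and `rate`
#'   (>= 0); at least 4 distinct substrate concentrations.
#' @param E0 Enzyme concentration in uM (may also travel as
#'   `attr(data, "E0")`).
#' @param substrate Optional substrate label (e.g. `"NADH"`).
#' @return Object of class `mm_fit` with components `KM`, `Vmax`, `kcat`,
#'   `efficiency`, matching `*_se` standard errors, `E0`, `substrate`,
#'   `n_obs`, and the underlying `nls` fit.  Methods: `print`, `summary`,
#'   `coef`, `vcov`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' d <- make_mm_data(KM = 0.31, kcat = 2.9, E0 = 0.11, cv = 0, seed = 1)
#' fit <- fit_michaelis_menten(d)
#' coef(fit)
#' @export
fit_michaelis_menten <- function(data, E0 = attr(data, "E0"), substrate = NULL) {
  stopifnot(is.data.frame(data), all(c("substrate_mM", "rate") %in% names(data)))
  S <- data$substrate_mM
  v <- data$rate
  if (any(!is.finite(S)) || any(S <= 0)) stop("substrate concentrations must be > 0")
  if (any(!is.finite(v)) || any(v < 0)) stop("rates must be >= 0")
  if (length(unique(S)) < 4L)
    stop("at least 4 distinct substrate concentrations are required")
  if (all(v == 0)) stop("all rates are zero; nothing to fit")
  if (is.null(E0)) stop("enzyme concentration E0 (uM) is required")
  # Hanes-Woolf start: S/v = S/Vmax + KM/Vmax
  ok <- v > 0
  h <- stats::coef(stats::lm(I(S[ok] / v[ok]) ~ S[ok]))
  start <- if (is.finite(h[2L]) && h[2L] > 0 && h[1L] > 0)
    list(Vmax = unname(1 / h[2L]), KM = unname(h[1L] / h[2L]))
  else
    list(Vmax = max(v) * 1.2, KM = stats::median(S))
  fit <- minpack.lm::nlsLM(v ~ Vmax * S / (KM + S), start = start,
                           lower = c(Vmax = 0, KM = 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  if (!is.finite(est["KM"]) || est["KM"] <= 0) stop("KM estimate is not positive")
  V <- stats::vcov(fit)
  KM <- unname(est["KM"]); Vmax <- unname(est["Vmax"])
  KM_se <- sqrt(V["KM", "KM"]); Vmax_se <- sqrt(V["Vmax", "Vmax"])
  kcat <- Vmax / E0
  kcat_se <- Vmax_se / E0
  eff <- kcat / KM
  # delta method on (Vmax, KM)
  g <- c(Vmax = 1 / (E0 * KM), KM = -Vmax / (E0 * KM^2))
  eff_se <- sqrt(drop(t(g[colnames(V)]) %*% V %*% g[colnames(V)]))
  structure(list(KM = KM, KM_se = KM_se,
                 Vmax = Vmax, Vmax_se = Vmax_se,
                 kcat = kcat, kcat_se = kcat_se,
                 efficiency = eff, efficiency_se = eff_se,
                 E0 = E0, substrate = substrate,
                 n_obs = length(v), fit = fit, data = data),
            class = "mm_fit")
}

#' @export
coef.mm_fit <- function(object, ...) {
  c(KM = object$KM, Vmax = object$Vmax, kcat = object$kcat,
    efficiency = object$efficiency)
}

#' @export
vcov.mm_fit <- function(object, ...) stats::vcov(object$fit)

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) object$data$substrate_mM else newdata$substrate_mM
  object$Vmax * S / (object$KM + S)
}

#' @export
fitted.mm_fit <- function(object, ...) stats::fitted(object$fit)

#' @export
residuals.mm_fit <- function(object, ...) stats::residuals(object$fit)

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit",
      if (!is.null(x$substrate)) paste0(" (", x$substrate, ")"), "\n", sep = "")
  cat(sprintf("  KM   = %.4g +/- %.2g mM\n", x$KM, x$KM_se))
  cat(sprintf("  Vmax = %.4g +/- %.2g uM/s\n", x$Vmax, x$Vmax_se))
  cat(sprintf("  kcat = %.4g +/- %.2g 1/s   (E0 = %g uM)\n", x$kcat, x$kcat_se, x$E0))
  cat(sprintf("  kcat/KM = %.4g +/- %.2g mM^-1 s^-1\n", x$efficiency, x$efficiency_se))
  invisible(x)
}

#' @export
summary.mm_fit <- function(object, ...) {
  out <- data.frame(parameter = c("KM", "Vmax", "kcat", "efficiency"),
                    estimate = c(object$KM, object$Vmax, object$kcat,
                                 object$efficiency),
                    se = c(object$KM_se, object$Vmax_se, object$kcat_se,
                           object$efficiency_se),
                    unit = c("mM", "uM/s", "1/s", "mM^-1 s^-1"))
  structure(list(table = out, n_obs = object$n_obs, substrate = object$substrate),
            class = "summary.mm_fit")
}

#' @export
print.summary.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit on", x$n_obs, "observations\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
plot.mm_fit <- function(x, ...) {
  S <- x$data$substrate_mM
  graphics::plot(S, x$data$rate, xlab = "[S] (mM)", ylab = "v (uM/s)",
                 main = "Michaelis-Menten fit", ...)
  grid_S <- seq(min(S), max(S), length.out = 200)
  graphics::lines(grid_S, x$Vmax * grid_S / (x$KM + grid_S))
  invisible(x)
}

#' Catalytic efficiency and substrate-preference ratio
#'
#' `catalytic_efficiency()` returns `kcat / KM` (mM^-1 s^-1) from a fitted
#' `mm_fit` or from bare `kcat` and `KM` numbers, rounded to 3 significant
#' figures for reporting (set `signif_digits = NULL` for the raw value).
#' `efficiency_ratio()` is the NAD+/NADH preference:
#' `efficiency(NAD+) / efficiency(NADH)`, reported to 2 decimals.
#'
#' @param kcat An `mm_fit` object, or the turnover number (1/s).
#' @param KM Michaelis constant (mM); ignored when `kcat` is an `mm_fit`.
#' @param signif_digits Significant figures for reporting (default 3).
#' @examples
#' catalytic_efficiency(8.9, 1.6)     # 5.56
#' catalytic_efficiency(11.0, 0.011)  # 1000
#' efficiency_ratio(9.3, 89.2)        # 0.10
#' @export
catalytic_efficiency <- function(kcat, KM = NULL, signif_digits = 3L) {
  if (inherits(kcat, "mm_fit")) {
    val <- kcat$efficiency
  } else {
    if (is.null(KM)) stop("KM required when kcat is given as a number")
    if (any(KM <= 0)) stop("KM must be positive")
    val <- kcat / KM
  }
  if (is.null(signif_digits)) val else signif(val, signif_digits)
}

#' @rdname catalytic_efficiency
#' @param eff_nad,eff_nadh Efficiencies (mM^-1 s^-1) or `mm_fit` objects for
#'   the NAD+ and NADH datasets.
#' @param digits Decimals for the reported ratio (default 2).
#' @export
efficiency_ratio <- function(eff_nad, eff_nadh, digits = 2L) {
  val_of <- function(x) if (inherits(x, "mm_fit")) x$efficiency else x
  a <- val_of(eff_nad); b <- val_of(eff_nadh)
  if (any(b == 0)) stop("zero denominator efficiency")
  r <- a / b
  if (is.null(digits)) r else round_half_away(r, digits)
}

#' Serialise a fit to JSON
#'
#' @param fit An `mm_fit`.
#' @param path Optional output path; with `NULL` the JSON string is
#'   returned.
#' @export
mm_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "mm_fit"))
  x <- list(substrate = fit$substrate,
            E0_uM = fit$E0,
            n_obs = fit$n_obs,
            KM_mM = fit$KM, KM_se = fit$KM_se,
            Vmax_uM_s = fit$Vmax, Vmax_se = fit$Vmax_se,
            kcat_s = fit$kcat, kcat_se = fit$kcat_se,
            efficiency_mM_s = fit$efficiency, efficiency_se = fit$efficiency_se)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) js else { writeLines(js, path); invisible(path) }
}
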