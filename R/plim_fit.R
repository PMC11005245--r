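#' Fit a mono-exponential lifetime to a mean decay
#'
#' Nonlinear least-squares fit of `y(t) = A * exp(-t / tau) + C` to the
#' averaged decay, after discarding the first `window_start_us` microseconds
#' of the collection window (default 5 us, leaving 285 us of a standard
#' 290 us collection). Initial values are derived from the data: `C` from the
#' mean of the last 10% of bins, `tau` from the slope of
#' `log(counts - C0)` over the first half of the window, `A` from the first
#' window bin. Optionally Poisson-weighted (weights `1 / max(counts, 1)`).
#'
#' @param mean_decay A [decay_histogram()] (typically from
#'   [average_decays()]), or a numeric vector of bin values with `t` supplied.
#' @param t Bin-start times if `mean_decay` is a bare vector.
#' @param window_start_us Time (us) before which bins are discarded.
#' @param weighting `"none"` (default) or `"poisson"`.
#' @return A list with `A`, `tau`, `C`, `residual_norm` (root-mean-square
#'   residual over the fit window), `converged`, and `fit_window` (the bin
#'   index range used).
#' @export
fit_lifetime <- function(mean_decay, t = NULL, window_start_us = 5,
                         weighting = c("none", "poisson")) {
  weighting <- match.arg(weighting)
  if (inherits(mean_decay, "decay_histogram")) {
    y <- mean_decay$counts
    t <- mean_decay$t
  } else {
    y <- as.numeric(mean_decay)
    if (is.null(t)) stop("`t` required when `mean_decay` is a bare vector",
                         call. = FALSE)
  }
  stopifnot(length(y) == length(t))
  if (window_start_us >= max(t))
    stop("`window_start_us` leaves no bins to fit", call. = FALSE)
  keep <- t >= window_start_us
  tw <- t[keep]
  yw <- y[keep]
  if (max(yw) - min(yw) <= 0)
    stop("decay has zero dynamic range in the fit window", call. = FALSE)

  # data-driven start values (robust, derivative-free)
  ntail <- max(1L, floor(0.1 * length(yw)))
  C0 <- mean(utils::tail(yw, ntail))
  half <- seq_len(max(2L, floor(length(yw) / 2)))
  pos <- yw[half] - C0
  ok <- pos > 0
  if (sum(ok) >= 2) {
    sl <- unname(stats::coef(stats::lm(log(pos[ok]) ~ tw[half][ok]))[2])
    tau0_init <- if (is.finite(sl) && sl < 0) -1 / sl else diff(range(tw)) / 3
  } else tau0_init <- diff(range(tw)) / 3
  A0 <- max(yw[1] - C0, max(yw) * 1e-3)

  w <- if (weighting == "poisson") 1 / pmax(yw, 1) else rep(1, length(yw))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yw ~ A * exp(-tw / tau) + C,
      start = list(A = A0, tau = tau0_init, C = C0),
      weights = w,
      lower = c(A = 0, tau = 1e-9, C = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(list(A = NA_real_, tau = NA_real_, C = NA_real_,
                residual_norm = NA_real_, converged = FALSE,
                message = conditionMessage(fit),
                fit_window = range(which(keep))))
  }
  cf <- stats::coef(fit)
  res <- yw - (cf[["A"]] * exp(-tw / cf[["tau"]]) + cf[["C"]])
  list(A = cf[["A"]], tau = cf[["tau"]], C = cf[["C"]],
       residual_norm = sqrt(mean(res^2)), converged = TRUE,
       message = NULL, fit_window = range(which(keep)))
}

#' Fit pO2 at one intravascular location from repeated PLIM decays
#'
#' The central model fit of the package. Takes the repetitions acquired at
#' one intravascular point and performs, in order: (1) rejection of
#' motion-corrupted repetitions by iterated two-sided Grubbs test on
#' per-repetition total photons ([reject_outlier_decays()]); (2) per-bin
#' averaging of the surviving repetitions ([average_decays()]); (3) windowed
#' mono-exponential fit `y(t) = A exp(-t/tau) + C` to the mean decay
#' ([fit_lifetime()]), the first `window_start_us` microseconds discarded;
#' (4) Stern-Volmer conversion of the lifetime to pO2
#' ([lifetime_to_po2()]) and Hill conversion to SO2 ([po2_to_so2()]).
#'
#' The lifetime is fitted on the averaged decay, not averaged over
#' per-repetition fits.
#'
#' @param decays List of [decay_histogram()] repetitions, or a
#'   repetitions-by-bins count matrix (with optional attributes `t`,
#'   `protocol`).
#' @param calib A [plim_calibration()].
#' @param window_start_us Initial portion of the decay to discard (us).
#' @param alpha Grubbs significance level for repetition rejection; set to
#'   `NULL` to skip rejection.
#' @param weighting Passed to [fit_lifetime()].
#' @param clamp_po2 If `TRUE`, lifetimes above `tau0` clamp to pO2 = 0.
#' @return An object of class `plim_fit` with components `coefficients`
#'   (named `A`, `tau`, `C`), `po2`, `so2`, `n_kept`, `kept`, `rejections`,
#'   `mean_decay`, `residual_norm`, `converged`, `calib`,
#'   `window_start_us`, `call`. Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot`, `simulate`.
#' @examples
#' cal <- plim_calibration()
#' decays <- replicate(20, simulate_decay(40, cal, photon_budget = 5e4),
#'                     simplify = FALSE)
#' fit <- plim_fit(decays, cal)
#' coef(fit)["tau"]
#' fit$po2
#' @export
plim_fit <- function(decays, calib = plim_calibration(), window_start_us = 5,
                     alpha = 0.05, weighting = c("none", "poisson"),
                     clamp_po2 = FALSE) {
  weighting <- match.arg(weighting)
  m <- as_decay_matrix(decays)
  protocol <- attr(m, "protocol")

  if (!is.null(alpha) && nrow(m) >= 3) {
    rej <- reject_outlier_decays(m, alpha = alpha)
  } else {
    rej <- list(kept = rep(TRUE, nrow(m)), totals = rowSums(m),
                rejections = data.frame())
  }
  mk <- m[rej$kept, , drop = FALSE]
  attr(mk, "t") <- attr(m, "t")
  attr(mk, "protocol") <- protocol
  mean_decay <- average_decays(mk)

  lf <- fit_lifetime(mean_decay, window_start_us = window_start_us,
                     weighting = weighting)
  po2 <- so2 <- NA_real_
  if (lf$converged) {
    po2 <- lifetime_to_po2(lf$tau, calib, clamp = clamp_po2)
    so2 <- po2_to_so2(po2, calib)
  }
  out <- list(
    coefficients = c(A = lf$A, tau = lf$tau, C = lf$C),
    po2 = po2, so2 = so2,
    n_kept = sum(rej$kept), kept = rej$kept, rejections = rej$rejections,
    totals = rej$totals,
    mean_decay = mean_decay,
    residual_norm = lf$residual_norm, converged = lf$converged,
    fit_message = lf$message,
    calib = calib, window_start_us = window_start_us,
    weighting = weighting, protocol = protocol,
    call = match.call()
  )
  class(out) <- "plim_fit"
  out
}

#' @export
print.plim_fit <- function(x, digits = 4, ...) {
  cat("Pointwise PLIM lifetime fit\n")
  if (!x$converged) {
    cat("  FIT DID NOT CONVERGE:", x$fit_message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  tau = %.*g us  ->  pO2 = %.*g mmHg, SO2 = %.*g%%\n",
              digits, x$coefficients[["tau"]], digits, x$po2, digits, x$so2))
  cat(sprintf("  repetitions kept: %d/%d\n", x$n_kept, length(x$kept)))
  invisible(x)
}

#' @export
summary.plim_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.plim_fit")
}

#' @export
print.summary.plim_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  if (f$converged) {
    cat("\nCoefficients of y(t) = A exp(-t/tau) + C:\n")
    print(signif(f$coefficients, digits))
    cat(sprintf("\nRMS residual over fit window: %.*g counts\n",
                digits, f$residual_norm))
    cat(sprintf("Fit window start: %g us; weighting: %s\n",
                f$window_start_us, f$weighting))
  }
  if (nrow(f$rejections))
    cat(sprintf("Rejected repetitions (Grubbs on total photons): %s\n",
                paste(f$rejections$index, collapse = ", ")))
  invisible(x)
}

#' @export
coef.plim_fit <- function(object, ...) object$coefficients

#' @export
predict.plim_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$mean_decay$t else newdata$t
  cf <- object$coefficients
  cf[["A"]] * exp(-t / cf[["tau"]]) + cf[["C"]]
}

#' @export
fitted.plim_fit <- function(object, ...) predict(object)

#' @export
residuals.plim_fit <- function(object, ...) {
  object$mean_decay$counts - predict(object)
}

#' @export
plot.plim_fit <- function(x, log = "y", ...) {
  md <- x$mean_decay
  graphics::plot(md$t, pmax(md$counts, .Machine$double.eps),
                 log = log, xlab = "time after excitation (us)",
                 ylab = "mean photons / bin", pch = 16, cex = 0.4,
                 col = "grey40", ...)
  if (x$converged)
    graphics::lines(md$t, pmax(predict(x), .Machine$double.eps),
                    col = "red3", lwd = 2)
  graphics::abline(v = x$window_start_us, lty = 3)
  invisible(x)
}

#' Simulate new repetitions from a fitted decay model
#'
#' Draws Poisson decay histograms whose expected bin contents are the fitted
#' curve, useful for parametric-bootstrap uncertainty on tau and pO2.
#'
#' @param object A converged [plim_fit()].
#' @param nsim Number of repetitions to draw.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A list of `nsim` [decay_histogram()] objects.
#' @export
simulate.plim_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop("cannot simulate from a non-converged fit",
                              call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  md <- object$mean_decay
  mu <- pmax(predict(object), 0)
  lapply(seq_len(nsim), function(i)
    decay_histogram(md$t, stats::rpois(length(mu), mu),
                    protocol = md$protocol))
}
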