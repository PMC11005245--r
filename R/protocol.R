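#' Pointwise PLIM acquisition protocol
#'
#' Describes one pointwise phosphorescence-lifetime acquisition: each cycle is
#' a short excitation gate followed by a photon-collection window in which the
#' TCSPC hardware accumulates a time-binned histogram of emitted photons.
#' Cycles are repeated within a repetition, and several repetitions are
#' acquired per intravascular location. The defaults describe a 10 us
#' excitation + 290 us collection cycle repeated 2000 times (0.6 s) with 20
#' repetitions per location and 1 us histogram bins.
#'
#' @param excitation_us Duration of the excitation gate (microseconds).
#' @param collection_us Duration of the photon-collection window (microseconds).
#' @param n_cycles Number of excitation/collection cycles per repetition.
#' @param n_repetitions Number of repetitions (decay histograms) per location.
#' @param bin_width_us TCSPC histogram bin width (microseconds). Must divide
#'   `collection_us` exactly.
#'
#' @return An object of class `plim_protocol`: a list with the fields above
#'   plus `cycle_us` (cycle period) and `duration_s` (trace duration).
#' @examples
#' p <- plim_protocol()
#' p$cycle_us     # 300
#' p$duration_s   # 0.6
#' @export
plim_protocol <- function(excitation_us = 10, collection_us = 290,
                          n_cycles = 2000, n_repetitions = 20,
                          bin_width_us = 1) {
  stopifnot(excitation_us > 0, collection_us > 0,
            n_cycles >= 1, n_repetitions >= 1, bin_width_us > 0)
  if (abs(collection_us / bin_width_us - round(collection_us / bin_width_us)) > 1e-9)
    stop("`collection_us` must be an integer multiple of `bin_width_us`",
         call. = FALSE)
  p <- list(
    excitation_us = excitation_us,
    collection_us = collection_us,
    n_cycles = as.integer(n_cycles),
    n_repetitions = as.integer(n_repetitions),
    bin_width_us = bin_width_us,
    cycle_us = excitation_us + collection_us,
    duration_s = n_cycles * (excitation_us + collection_us) * 1e-6
  )
  class(p) <- "plim_protocol"
  p
}

#' @export
print.plim_protocol <- function(x, ...) {
  cat("PLIM acquisition protocol\n")
  cat(sprintf("  cycle: %g us excitation + %g us collection (%g us)\n",
              x$excitation_us, x$collection_us, x$cycle_us))
  cat(sprintf("  %d cycles/repetition (%g s trace), %d repetitions/location\n",
              x$n_cycles, x$duration_s, x$n_repetitions))
  cat(sprintf("  TCSPC bin width: %g us (%d bins)\n",
              x$bin_width_us, n_bins(x)))
  invisible(x)
}

n_bins <- function(protocol) as.integer(round(protocol$collection_us / protocol$bin_width_us))

#' Bin-start times of the TCSPC histogram
#'
#' Times are relative to the end of the excitation gate, in microseconds.
#'
#' @param protocol A [plim_protocol()].
#' @return Numeric vector of bin-start times, length `collection_us / bin_width_us`.
#' @export
bin_times <- function(protocol) {
  seq(0, protocol$collection_us - protocol$bin_width_us,
      by = protocol$bin_width_us)
}

#' Probe calibration and hemoglobin-dissociation parameters
#'
#' Bundles the constants that convert a fitted phosphorescence lifetime into
#' oxygen partial pressure and hemoglobin saturation. Lifetime-to-pO2 uses a
#' Stern-Volmer relation, `1/tau = 1/tau0 + kq * pO2`: collisional quenching by
#' oxygen shortens the lifetime from its zero-oxygen value `tau0` at rate `kq`.
#' pO2-to-SO2 uses the Hill equation with coefficients for C57BL/6 mouse blood
#' (`h = 2.59`, `P50 = 40.2` mmHg). The probe constants depend on the probe
#' batch and temperature (objective heated to ~36.6 degC); the defaults span
#' lifetimes of roughly 15-40 us over 0-150 mmHg.
#'
#' @param tau0 Phosphorescence lifetime at zero oxygen (microseconds).
#' @param kq Oxygen quenching rate constant (1 / (us * mmHg)).
#' @param hill_h Hill exponent (dimensionless).
#' @param hill_p50 Half-saturation oxygen pressure (mmHg).
#' @return An object of class `plim_calibration`.
#' @examples
#' cal <- plim_calibration()
#' po2_to_lifetime(0, cal)    # tau0
#' po2_to_so2(cal$hill_p50, cal)  # 50 by definition of P50
#' @export
plim_calibration <- function(tau0 = 40, kq = 2.8e-4,
                             hill_h = 2.59, hill_p50 = 40.2) {
  stopifnot(tau0 > 0, kq > 0, hill_h > 0, hill_p50 > 0)
  cal <- list(tau0 = tau0, kq = kq, hill_h = hill_h, hill_p50 = hill_p50)
  class(cal) <- "plim_calibration"
  cal
}

#' @export
print.plim_calibration <- function(x, ...) {
  cat("PLIM probe calibration\n")
  cat(sprintf("  Stern-Volmer: tau0 = %g us, kq = %g /(us*mmHg)\n", x$tau0, x$kq))
  cat(sprintf("  Hill: h = %g, P50 = %g mmHg\n", x$hill_h, x$hill_p50))
  invisible(x)
}

#' Convert phosphorescence lifetime to pO2 (and back)
#'
#' `lifetime_to_po2()` inverts the Stern-Volmer quenching relation
#' `1/tau = 1/tau0 + kq * pO2` to give `pO2 = (1/tau - 1/tau0) / kq`;
#' `po2_to_lifetime()` is its exact algebraic inverse. A lifetime longer than
#' `tau0` has no physical pO2; beyond a small relative tolerance it is an
#' error unless `clamp = TRUE`, in which case it maps to 0 mmHg.
#'
#' @param tau Lifetime(s) in microseconds.
#' @param po2 Oxygen partial pressure(s) in mmHg.
#' @param calib A [plim_calibration()].
#' @param clamp If `TRUE`, lifetimes above `tau0` clamp to pO2 = 0 rather than
#'   erroring.
#' @param tol Relative tolerance on `tau <= tau0` before the calibration
#'   violation is raised.
#' @return Numeric vector of pO2 values (mmHg) or lifetimes (us).
#' @export
lifetime_to_po2 <- function(tau, calib = plim_calibration(),
                            clamp = FALSE, tol = 1e-6) {
  stopifnot(is.numeric(tau), all(is.finite(tau)), all(tau > 0))
  over <- tau > calib$tau0 * (1 + tol)
  if (any(over) && !clamp)
    stop(sprintf("lifetime %.4g us exceeds tau0 = %g us: calibration violation",
                 max(tau), calib$tau0), call. = FALSE)
  po2 <- (1 / tau - 1 / calib$tau0) / calib$kq
  pmax(po2, 0)
}

#' @rdname lifetime_to_po2
#' @export
po2_to_lifetime <- function(po2, calib = plim_calibration()) {
  stopifnot(is.numeric(po2), all(is.finite(po2)), all(po2 >= 0))
  1 / (1 / calib$tau0 + calib$kq * po2)
}

#' Hemoglobin oxygen saturation from pO2 (Hill equation)
#'
#' `SO2 = 100 * pO2^h / (pO2^h + P50^h)` with the calibration's Hill
#' coefficients. Strictly increasing in pO2 with `SO2(P50) = 50%`.
#'
#' @param po2 Oxygen partial pressure(s), mmHg; must be non-negative.
#' @param calib A [plim_calibration()].
#' @return Saturation in percent (0-100).
#' @export
po2_to_so2 <- function(po2, calib = plim_calibration()) {
  if (!is.numeric(po2) || any(!is.finite(po2)) || any(po2 < 0))
    stop("`po2` must be finite and non-negative", call. = FALSE)
  ph <- po2^calib$hill_h
  100 * ph / (ph + calib$hill_p50^calib$hill_h)
}

#' Cortical layer definitions and depth binning
#'
#' Subpial depth bands: layer I 0-100 um, layer II/III 100-320 um, layer IV
#' 320-450 um. Bands are half-open on the low side (`[0,100)`, `[100,320)`)
#' with the deepest band closed (`[320,450]`), so a measurement at exactly
#' 100 um falls in layer II/III and each of the standard measurement depths
#' 50/100/200/300/400 um maps to a layer.
#'
#' @return `cortical_layers()`: a data.frame with columns `layer`, `lower_um`,
#'   `upper_um`.
#' @export
cortical_layers <- function() {
  data.frame(layer = c("I", "II/III", "IV"),
             lower_um = c(0, 100, 320),
             upper_um = c(100, 320, 450),
             stringsAsFactors = FALSE)
}

#' @rdname cortical_layers
#' @param depth_um Subpial depth(s) in micrometers; must lie in [0, 450].
#' @return `assign_layer()`: a character vector of layer labels
#'   (`"I"`, `"II/III"`, `"IV"`).
#' @examples
#' assign_layer(c(50, 100, 200, 300, 400))
#' @export
assign_layer <- function(depth_um) {
  stopifnot(is.numeric(depth_um), all(is.finite(depth_um)))
  if (any(depth_um < 0 | depth_um > 450))
    stop("depth outside the 0-450 um cortical range", call. = FALSE)
  layers <- cortical_layers()
  idx <- findInterval(depth_um, c(layers$lower_um, 450), rightmost.closed = TRUE)
  layers$layer[idx]
}

#' Classify a penetrating vessel as arteriole or venule
#'
#' Diving arterioles and ascending venules are separated by their baseline
#' (day 0) pO2 measured at 50 um below the pial surface: strictly above
#' 66 mmHg is an arteriole, otherwise a venule. The classification is frozen
#' at baseline and propagated to later timepoints of the same vessel.
#'
#' @param surface_po2 Baseline pO2 at 50 um subpial depth (mmHg). `NA` values
#'   return `NA` (unclassified) with a warning.
#' @param threshold_mmHg Classification boundary, default 66 mmHg.
#' @return Character vector: `"arteriole"` or `"venule"` (or `NA`).
#' @export
classify_vessel <- function(surface_po2, threshold_mmHg = 66) {
  out <- ifelse(surface_po2 > threshold_mmHg, "arteriole", "venule")
  if (anyNA(surface_po2)) {
    warning("vessels with missing baseline surface pO2 left unclassified",
            call. = FALSE)
  }
  out
}
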