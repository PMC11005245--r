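#' TCSPC decay histogram
#'
#' One repetition's time-binned photon counts at one intravascular point.
#' Bin-start times are relative to the end of the excitation gate and must be
#' uniformly spaced at the protocol's bin width.
#'
#' @param t Bin-start times (microseconds), strictly increasing, uniform.
#' @param counts Photons per bin (non-negative; real-valued bins are allowed
#'   so that averaged and expected-value decays share the class).
#' @param protocol A [plim_protocol()].
#' @param truth Optional list of generative ground truth (kept by the
#'   simulator; `NULL` for measured data).
#' @return An object of class `decay_histogram`.
#' @export
decay_histogram <- function(t, counts, protocol = plim_protocol(), truth = NULL) {
  stopifnot(is.numeric(t), is.numeric(counts), length(t) == length(counts))
  if (length(t) == 0) stop("empty histogram", call. = FALSE)
  if (any(counts < 0)) stop("negative bin counts", call. = FALSE)
  dt <- diff(t)
  if (length(dt) && (any(dt <= 0) || max(abs(dt - protocol$bin_width_us)) > 1e-9))
    stop("bin times must be strictly increasing with spacing = bin_width_us",
         call. = FALSE)
  if (length(t) != n_bins(protocol))
    stop("histogram length must equal collection_us / bin_width_us", call. = FALSE)
  structure(list(t = t, counts = counts, protocol = protocol, truth = truth),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("TCSPC decay histogram: %d bins of %g us, %.0f photons\n",
              length(x$t), x$protocol$bin_width_us, sum(x$counts)))
  if (!is.null(x$truth))
    cat(sprintf("  simulated truth: tau = %.3f us, pO2 = %.2f mmHg\n",
                x$truth$tau, x$truth$po2))
  invisible(x)
}

#' Total photon count of a decay
#'
#' The per-repetition total photon count is the statistic used to reject
#' motion-corrupted repetitions (see [reject_outlier_decays()]).
#'
#' @param decay A [decay_histogram()], or a numeric vector of bin counts.
#' @return The sum of all bin counts.
#' @export
total_photons <- function(decay) {
  counts <- if (inherits(decay, "decay_histogram")) decay$counts else decay
  if (length(counts) == 0) stop("empty histogram", call. = FALSE)
  sum(counts)
}

#' Average repetitions into a mean decay
#'
#' Per-bin arithmetic mean of the surviving repetitions; all histograms must
#' share the same bin grid.
#'
#' @param decays A list of [decay_histogram()] objects (or a numeric matrix
#'   with one repetition per row).
#' @return A `decay_histogram` with real-valued mean bin counts.
#' @export
average_decays <- function(decays) {
  m <- as_decay_matrix(decays)
  decay_histogram(attr(m, "t"), colMeans(m), protocol = attr(m, "protocol"))
}

# Normalize a list of decay_histogram objects / numeric matrix to a
# repetitions-by-bins matrix carrying the common bin grid.
as_decay_matrix <- function(decays, t = NULL, protocol = NULL) {
  if (is.matrix(decays)) {
    if (is.null(t)) t <- attr(decays, "t")
    if (is.null(protocol)) protocol <- attr(decays, "protocol")
    if (is.null(protocol)) protocol <- plim_protocol()
    if (is.null(t)) {
      t <- bin_times(protocol)
      # bare matrices on a nonstandard grid: fall back to the bin index
      if (length(t) != ncol(decays))
        t <- (seq_len(ncol(decays)) - 1) * protocol$bin_width_us
    }
    stopifnot(ncol(decays) == length(t))
    m <- decays
  } else {
    if (inherits(decays, "decay_histogram")) decays <- list(decays)
    stopifnot(is.list(decays), length(decays) >= 1)
    t0 <- decays[[1]]$t
    for (d in decays) {
      if (!inherits(d, "decay_histogram")) stop("expected decay_histogram objects",
                                                call. = FALSE)
      if (length(d$t) != length(t0) || max(abs(d$t - t0)) > 1e-9)
        stop("mismatched bin grids across repetitions", call. = FALSE)
    }
    m <- do.call(rbind, lapply(decays, `[[`, "counts"))
    t <- t0
    protocol <- decays[[1]]$protocol
  }
  attr(m, "t") <- t
  attr(m, "protocol") <- protocol
  m
}

#' Two-sided Grubbs critical value
#'
#' Closed-form critical value for the single-outlier Grubbs statistic
#' `G = max|x - mean| / sd` at two-sided significance `alpha`:
#' `G_crit = (n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n - 2)`.
#'
#' @param n Sample size (>= 3).
#' @param alpha Two-sided significance level.
#' @return The critical value.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  stopifnot(n >= 3, alpha > 0, alpha < 1)
  tc <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(tc^2 / (n - 2 + tc^2))
}

#' Reject motion-corrupted repetitions by total photons (iterated Grubbs)
#'
#' Animal motion produces repetitions whose total photon count is an outlier
#' relative to the other repetitions at the same location. Those are removed
#' by an iterated two-sided Grubbs test on the vector of per-repetition total
#' photons: at each iteration the single most extreme total is tested and
#' removed if its statistic exceeds the critical value; iteration stops when
#' nothing is rejected or fewer than 3 repetitions remain. Rejection happens
#' before averaging.
#'
#' @param decays List of [decay_histogram()] objects, or a repetitions-by-bins
#'   count matrix.
#' @param alpha Two-sided significance level per iteration (default 0.05).
#' @return A list with `kept` (logical vector in input order), `totals`
#'   (per-repetition total photons), and `rejections` (data.frame logging each
#'   removed repetition: index, total, Grubbs statistic, critical value).
#' @export
reject_outlier_decays <- function(decays, alpha = 0.05) {
  m <- as_decay_matrix(decays)
  totals <- rowSums(m)
  n <- length(totals)
  kept <- rep(TRUE, n)
  log <- data.frame(index = integer(), total = numeric(),
                    G = numeric(), G_crit = numeric())
  if (n < 3) {
    warning("fewer than 3 repetitions: Grubbs test undefined, all kept",
            call. = FALSE)
    return(list(kept = kept, totals = totals, rejections = log))
  }
  repeat {
    idx <- which(kept)
    if (length(idx) < 3) break
    x <- totals[idx]
    s <- stats::sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    G <- max(dev) / s
    gc <- grubbs_critical(length(x), alpha)
    if (G <= gc) break
    worst <- idx[which.max(dev)]
    kept[worst] <- FALSE
    log <- rbind(log, data.frame(index = worst, total = totals[worst],
                                 G = G, G_crit = gc))
  }
  list(kept = kept, totals = totals, rejections = log)
}
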