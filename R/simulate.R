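#' Simulate a TCSPC phosphorescence decay histogram
#'
#' Forward model for one PLIM repetition: oxygen sets the probe lifetime via
#' the Stern-Volmer relation, the expected histogram over the collection
#' window follows `A * exp(-t/tau) + C`, and photon noise is Poisson per bin.
#' The amplitude is scaled so the expected total photon count equals
#' `photon_budget` exactly; the generative `A`, `tau`, `C` and pO2 are
#' recorded in the returned histogram's `truth`.
#'
#' @param po2 True oxygen partial pressure (mmHg), finite and non-negative.
#' @param calib A [plim_calibration()].
#' @param protocol A [plim_protocol()].
#' @param photon_budget Expected total photons in the histogram (> 0).
#' @param background_frac Constant offset `C` as a fraction of the peak
#'   amplitude `A` (default 0.5%).
#' @param noise If `FALSE`, returns the expected-value (real-valued) histogram.
#' @param seed Optional RNG seed.
#' @return A [decay_histogram()] with `truth = list(A, tau, C, po2,
#'   photon_budget)`.
#' @examples
#' d <- simulate_decay(40, photon_budget = 1e5, seed = 1)
#' total_photons(d)
#' @export
simulate_decay <- function(po2, calib = plim_calibration(),
                           protocol = plim_protocol(),
                           photon_budget = 1e5, background_frac = 0.005,
                           noise = TRUE, seed = NULL) {
  if (!is.numeric(po2) || length(po2) != 1 || !is.finite(po2) || po2 < 0)
    stop("`po2` must be a single finite non-negative value", call. = FALSE)
  if (!is.finite(photon_budget) || photon_budget <= 0)
    stop("`photon_budget` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t <- bin_times(protocol)
  tau <- po2_to_lifetime(po2, calib)
  shape <- exp(-t / tau)
  # A solves A * (sum(shape) + n_bins * background_frac) = photon_budget
  A <- photon_budget / (sum(shape) + length(t) * background_frac)
  C <- background_frac * A
  mu <- A * shape + C
  counts <- if (noise) stats::rpois(length(mu), mu) else mu
  decay_histogram(t, counts, protocol = protocol,
                  truth = list(A = A, tau = tau, C = C, po2 = po2,
                               photon_budget = photon_budget))
}

#' Simulate a capillary intensity trace with RBC-passage valleys
#'
#' RBC arrivals follow a Poisson process at `flux_rate`; each arrival
#' depresses the expected per-cycle photon count from `baseline_counts`
#' toward `(1 - valley_depth_fraction) * baseline_counts` for
#' `transit_time_us`. Arrivals whose transit windows overlap merge into one
#' wider valley (the ground-truth arrival list still holds every arrival).
#' Per-sample photon noise is Poisson.
#'
#' @param flux_rate True RBC flux (RBC/s, >= 0).
#' @param transit_time_us Duration each RBC occludes the focal volume (us).
#' @param valley_depth_fraction Fractional intensity loss inside a valley,
#'   in (0, 1].
#' @param baseline_counts Expected photons per cycle outside valleys.
#' @param protocol A [plim_protocol()].
#' @param noise If `FALSE`, the trace is the expected value (no Poisson noise).
#' @param arrival_times_s Optional fixed arrival times (seconds) overriding
#'   the Poisson draw, for constructing deterministic traces.
#' @param seed Optional RNG seed.
#' @return An [intensity_trace()] whose `truth` holds `arrival_times_s`,
#'   the per-sample `occupancy` mask, `n_merged_valleys` (count of distinct
#'   occupancy runs, `<=` number of arrivals), and the generative parameters.
#'   Warns when more than 95% of samples are inside valleys.
#' @export
simulate_flux_trace <- function(flux_rate, transit_time_us = 3000,
                                valley_depth_fraction = 0.9,
                                baseline_counts = 100,
                                protocol = plim_protocol(),
                                noise = TRUE, arrival_times_s = NULL,
                                seed = NULL) {
  stopifnot(flux_rate >= 0, valley_depth_fraction > 0,
            valley_depth_fraction <= 1, baseline_counts > 0,
            transit_time_us > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- protocol$n_cycles
  dt_s <- protocol$cycle_us * 1e-6
  duration_s <- n * dt_s
  if (is.null(arrival_times_s)) {
    k <- stats::rpois(1, flux_rate * duration_s)
    arrival_times_s <- sort(stats::runif(k, 0, duration_s))
  } else {
    arrival_times_s <- sort(arrival_times_s)
  }
  occupancy <- rep(FALSE, n)
  transit_s <- transit_time_us * 1e-6
  ts <- (seq_len(n) - 1) * dt_s
  for (a in arrival_times_s)
    occupancy <- occupancy | (ts >= a & ts < a + transit_s)
  n_merged <- sum(rle(occupancy)$values)
  if (mean(occupancy) > 0.95)
    warning("flux unresolvable: > 95% of samples are inside valleys",
            call. = FALSE)
  mu <- ifelse(occupancy,
               baseline_counts * (1 - valley_depth_fraction),
               baseline_counts)
  counts <- if (noise) stats::rpois(n, mu) else mu
  intensity_trace(counts, protocol = protocol,
                  truth = list(arrival_times_s = arrival_times_s,
                               occupancy = occupancy,
                               n_merged_valleys = n_merged,
                               flux_rate = flux_rate,
                               transit_time_us = transit_time_us,
                               valley_depth_fraction = valley_depth_fraction,
                               baseline_counts = baseline_counts))
}

#' Ground-truth configuration for a synthetic AD/WT cohort
#'
#' Generative parameters for a longitudinal two-cohort study: per-cohort,
#' per-vessel-class, per-layer mean pO2 with between-vessel SD; per-day pO2
#' offsets emulating a systemic-inflammation challenge (days 0/7/14);
#' capillary flux distribution; photon budget per decay; and study sizes.
#' Default means are seeded from published cohort-level values for
#' 8-month-old APP/PS1 (AD) mice and wild-type littermates (e.g. layer-IV
#' arteriolar pO2 of 69.33 mmHg in WT vs 80.79 mmHg in AD; capillary pO2
#' near 48.6 mmHg in WT), with day-7 offsets sized so the layer-IV capillary
#' saturation drop is near -13% (WT) and -23% (AD); they are configuration
#' inputs, not assertions.
#'
#' @param cohorts Cohort labels.
#' @param n_animals Animals per cohort (>= 1).
#' @param days Measurement days.
#' @param depths_um Measurement depths (subpial, um).
#' @param n_penetrating Named counts of diving arterioles and ascending
#'   venules per animal; each is measured at every depth.
#' @param n_capillaries_per_depth Distinct capillary segments per depth.
#' @param n_primary_branches_per_depth Primary branches of penetrating
#'   vessels per depth; these carry a metadata flag and are excluded from
#'   capillary pools during analysis.
#' @param po2_mean Named list `cohort -> class -> numeric(3)` of layer means
#'   (mmHg, layers I, II/III, IV), each in [0, 160].
#' @param po2_sd Named per-class between-vessel SD (mmHg, >= 0).
#' @param day_offsets_mmHg Named list `cohort -> numeric(length(days))` of
#'   additive pO2 offsets per day.
#' @param flux_mean,flux_sd Capillary flux distribution (RBC/s), truncated
#'   at 5 RBC/s.
#' @param photon_budget Expected photons per decay repetition.
#' @param background_frac Decay offset fraction (see [simulate_decay()]).
#' @param n_flux_repetitions Intensity-trace repetitions per capillary point.
#' @param transit_time_us,valley_depth_fraction,baseline_counts Flux-trace
#'   parameters (see [simulate_flux_trace()]).
#' @param noise `TRUE` for the full stochastic model; `FALSE` zeroes all
#'   between-vessel SDs and disables photon noise (every measurement then
#'   equals its generative mean exactly).
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(cohorts = c("WT", "AD"),
                          n_animals = 5,
                          days = c(0, 7, 14),
                          depths_um = c(50, 100, 200, 300, 400),
                          n_penetrating = c(arteriole = 3, venule = 3),
                          n_capillaries_per_depth = 4,
                          n_primary_branches_per_depth = 1,
                          po2_mean = list(
                            WT = list(arteriole = c(85, 78, 69.33),
                                      venule = c(55, 52, 50),
                                      capillary = c(50, 48.59, 47)),
                            AD = list(arteriole = c(90, 84, 80.79),
                                      venule = c(60, 57, 55),
                                      capillary = c(52, 51, 50))),
                          po2_sd = c(arteriole = 5, venule = 4,
                                     capillary = 6),
                          day_offsets_mmHg = list(WT = c(0, -9, -5),
                                                  AD = c(0, -15, -8)),
                          flux_mean = 60, flux_sd = 15,
                          photon_budget = 1e5, background_frac = 0.005,
                          n_flux_repetitions = 4,
                          transit_time_us = 3000,
                          valley_depth_fraction = 0.9,
                          baseline_counts = 100,
                          noise = TRUE) {
  if (n_animals < 1) stop("`n_animals` must be >= 1", call. = FALSE)
  if (n_capillaries_per_depth < 1 && sum(n_penetrating) < 1)
    stop("config must include at least one vessel", call. = FALSE)
  stopifnot(all(cohorts %in% names(po2_mean)),
            all(cohorts %in% names(day_offsets_mmHg)),
            all(c("arteriole", "venule") %in% names(n_penetrating)),
            all(po2_sd >= 0), flux_mean >= 0, flux_sd >= 0,
            photon_budget > 0)
  for (co in cohorts) {
    vals <- unlist(po2_mean[[co]])
    if (any(vals < 0 | vals > 160))
      stop("pO2 means must lie in [0, 160] mmHg", call. = FALSE)
    if (length(day_offsets_mmHg[[co]]) != length(days))
      stop("`day_offsets_mmHg` must supply one offset per day", call. = FALSE)
  }
  cfg <- mget(names(formals()))
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %s; %d animals/cohort; days %s\n",
              paste(x$cohorts, collapse = "/"), x$n_animals,
              paste(x$days, collapse = "/")))
  cat(sprintf("  depths: %s um; %s penetrating + %d capillaries/depth; noise: %s\n",
              paste(x$depths_um, collapse = "/"),
              paste(x$n_penetrating, collapse = "+"),
              x$n_capillaries_per_depth, x$noise))
  invisible(x)
}

#' Simulate a full longitudinal AD/WT cohort with known ground truth
#'
#' Generates, for every animal, day, depth and vessel, the raw measurements
#' the pipeline consumes — repetition decay histograms for every vessel
#' point and intensity traces for capillaries — from the generative
#' parameters in a [cohort_config()]. Diving arterioles and ascending
#' venules are traced along depth (one vessel, all depths) and their
#' surface (50 um) baseline pO2 is drawn strictly on the correct side of the
#' 66 mmHg classification boundary by construction. Ground truth for every
#' record is retained for recovery tests.
#'
#' @param config A [cohort_config()].
#' @param protocol A [plim_protocol()].
#' @param calib A [plim_calibration()].
#' @param seed RNG seed; identical (config, seed) give bitwise-identical
#'   datasets.
#' @return An object of class `plim_cohort`: list with `records` (data frame
#'   of per-point ground truth: ids, class, depth, layer, day, true pO2 /
#'   tau / SO2 / flux), `measurements` (named list per record: `decays`
#'   repetition-by-bin count matrix; `traces` list of [intensity_trace()]
#'   for capillaries), `config`, `protocol`, `calib`, `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            protocol = plim_protocol(),
                            calib = plim_calibration(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  noise <- isTRUE(config$noise)
  sd_of <- function(cls) if (noise) config$po2_sd[[cls]] else 0
  layers <- cortical_layers()$layer
  depth_layer <- assign_layer(config$depths_um)

  rec <- list(); meas <- list(); rid <- 0L
  day_idx <- seq_along(config$days)

  for (co in config$cohorts) {
    offsets <- config$day_offsets_mmHg[[co]]
    for (an in seq_len(config$n_animals)) {
      animal_id <- sprintf("%s_m%02d", co, an)

      # penetrating vessels: one vessel measured at every depth
      pen <- list()
      for (cls in c("arteriole", "venule")) {
        for (v in seq_len(config$n_penetrating[[cls]])) {
          means <- config$po2_mean[[co]][[cls]][match(depth_layer, layers)]
          repeat {
            offset_v <- stats::rnorm(1, 0, sd_of(cls))
            p50um <- means[config$depths_um == 50] + offset_v
            ok <- if (cls == "arteriole") p50um > 66 else p50um < 66
            if (length(p50um) == 0 || ok) break
          }
          pen[[length(pen) + 1]] <- list(cls = cls, offset = offset_v,
                                         means = means,
                                         vessel_id = sprintf("%s_%s%02d",
                                                             animal_id,
                                                             substr(cls, 1, 3), v))
        }
      }

      # capillaries and primary branches: distinct segments per depth
      seg <- list()
      for (di in seq_along(config$depths_um)) {
        cap_mean <- config$po2_mean[[co]][["capillary"]][match(depth_layer[di], layers)]
        for (v in seq_len(config$n_capillaries_per_depth)) {
          seg[[length(seg) + 1]] <- list(
            cls = "capillary", depth_i = di,
            po2_0 = cap_mean + stats::rnorm(1, 0, sd_of("capillary")),
            flux = if (noise) max(5, stats::rnorm(1, config$flux_mean,
                                                  config$flux_sd))
                   else config$flux_mean,
            vessel_id = sprintf("%s_cap_d%03d_%02d", animal_id,
                                config$depths_um[di], v))
        }
        if (config$n_primary_branches_per_depth > 0) {
          for (v in seq_len(config$n_primary_branches_per_depth)) {
            seg[[length(seg) + 1]] <- list(
              cls = "primary_branch", depth_i = di,
              po2_0 = cap_mean + 5 + stats::rnorm(1, 0, sd_of("capillary")),
              flux = NA_real_,
              vessel_id = sprintf("%s_pb_d%03d_%02d", animal_id,
                                  config$depths_um[di], v))
          }
        }
      }

      for (d in day_idx) {
        day <- config$days[d]
        emit <- function(vessel_id, cls, depth_um, layer, po2_day, flux) {
          rid <<- rid + 1L
          record_id <- sprintf("r%06d", rid)
          tau <- po2_to_lifetime(po2_day, calib)
          decays <- matrix(0, protocol$n_repetitions, n_bins(protocol))
          for (r in seq_len(protocol$n_repetitions)) {
            dh <- simulate_decay(po2_day, calib, protocol,
                                 photon_budget = config$photon_budget,
                                 background_frac = config$background_frac,
                                 noise = noise)
            decays[r, ] <- dh$counts
          }
          m <- list(decays = decays)
          if (cls == "capillary") {
            m$traces <- lapply(seq_len(config$n_flux_repetitions), function(i)
              simulate_flux_trace(flux,
                                  transit_time_us = config$transit_time_us,
                                  valley_depth_fraction = config$valley_depth_fraction,
                                  baseline_counts = config$baseline_counts,
                                  protocol = protocol, noise = noise))
          }
          meas[[record_id]] <<- m
          rec[[rid]] <<- data.frame(
            record_id = record_id, cohort = co, animal_id = animal_id,
            vessel_id = vessel_id, vessel_type = cls, depth_um = depth_um,
            layer = layer, day = day, po2_true = po2_day, tau_true = tau,
            so2_true = po2_to_so2(po2_day, calib), flux_true = flux,
            stringsAsFactors = FALSE)
        }
        for (p in pen) {
          for (di in seq_along(config$depths_um)) {
            po2_day <- max(1, p$means[di] + p$offset + offsets[d])
            emit(p$vessel_id, p$cls, config$depths_um[di], depth_layer[di],
                 po2_day, NA_real_)
          }
        }
        for (s in seg) {
          po2_day <- max(1, s$po2_0 + offsets[d])
          emit(s$vessel_id, s$cls, config$depths_um[s$depth_i],
               depth_layer[s$depth_i], po2_day, s$flux)
        }
      }
    }
  }

  structure(list(records = do.call(rbind, rec), measurements = meas,
                 config = config, protocol = protocol, calib = calib,
                 seed = seed),
            class = "plim_cohort")
}

#' @export
print.plim_cohort <- function(x, ...) {
  r <- x$records
  cat(sprintf("Synthetic PLIM cohort: %d vessel-point-days (%s; %d animals/cohort; days %s)\n",
              nrow(r), paste(unique(r$cohort), collapse = "/"),
              x$config$n_animals, paste(unique(r$day), collapse = "/")))
  print(table(r$vessel_type) / length(unique(r$day)))
  invisible(x)
}

#' Ground truth for a synthetic immunofluorescence stack
#'
#' @param pa_percent Named per-channel true positive-area percentage of the
#'   maximum-intensity projection, each in [0, 100].
#' @param blob_radius_px Range (min, max) of blob radii in pixels.
#' @param thickness_um,z_step_um Stack geometry; the number of planes is
#'   `round(thickness_um / z_step_um) + 1` (defaults give an 11-plane,
#'   40-um stack at 3.96 um step).
#' @return A list of class `if_truth`.
#' @export
if_truth <- function(pa_percent = c(GFAP = 12, Iba1 = 8),
                     blob_radius_px = c(3, 8),
                     thickness_um = 40, z_step_um = 3.96) {
  stopifnot(all(pa_percent >= 0), all(pa_percent <= 100),
            length(blob_radius_px) == 2, blob_radius_px[1] > 0,
            thickness_um > 0, z_step_um > 0)
  structure(list(pa_percent = pa_percent, blob_radius_px = blob_radius_px,
                 thickness_um = thickness_um, z_step_um = z_step_um,
                 n_z = as.integer(round(thickness_um / z_step_um)) + 1L),
            class = "if_truth")
}

#' Simulate a two-channel immunofluorescence z-stack
#'
#' Bright blobs (out-of-plane-spread disks emulating stained somata and
#' processes) are placed at random positions and depths on a dark background
#' until the channel's maximum-intensity-projection positive-area fraction
#' reaches its target; the painted ground-truth mask and the achieved
#' percent area (which can overshoot the target by at most one blob's area)
#' are recorded. Intensities are in [0, 1]; foreground 0.8, background 0.05,
#' optional Gaussian speckle.
#'
#' @param truth An [if_truth()].
#' @param image_shape `c(ny, nx)` pixels.
#' @param pixel_size_um Lateral pixel size (um), mapping image rows to
#'   cortical depth (pial surface at the top row).
#' @param noise_sd Gaussian intensity noise SD (0 disables noise).
#' @param seed Optional RNG seed.
#' @return Object of class `if_stack`: `channels` (named list of
#'   `ny x nx x nz` arrays), `truth` (input truth plus per-channel `mask`
#'   and `pa_achieved`), `pixel_size_um`, `z_step_um`.
#' @export
simulate_if_stack <- function(truth = if_truth(), image_shape = c(300, 300),
                              pixel_size_um = 1.55, noise_sd = 0.02,
                              seed = NULL) {
  stopifnot(inherits(truth, "if_truth"), length(image_shape) == 2)
  if (max(truth$pa_percent) > 95)
    stop("blob area demand exceeds what random placement can cover",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ny <- image_shape[1]; nx <- image_shape[2]; nz <- truth$n_z
  masks <- list(); achieved <- numeric(0); channels <- list()
  for (ch in names(truth$pa_percent)) {
    target <- truth$pa_percent[[ch]] / 100
    mask <- matrix(FALSE, ny, nx)
    stack <- array(0, dim = c(ny, nx, nz))
    while (mean(mask) < target) {
      r <- stats::runif(1, truth$blob_radius_px[1], truth$blob_radius_px[2])
      cy <- stats::runif(1, 1, ny); cx <- stats::runif(1, 1, nx)
      zc <- sample.int(nz, 1)
      ylo <- max(1, floor(cy - r)); yhi <- min(ny, ceiling(cy + r))
      xlo <- max(1, floor(cx - r)); xhi <- min(nx, ceiling(cx + r))
      ys <- ylo:yhi; xs <- xlo:xhi
      disk <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= r^2
      if (!any(disk)) next
      mask[ys, xs] <- mask[ys, xs] | disk
      for (z in max(1, zc - 1):min(nz, zc + 1)) {
        amp <- if (z == zc) 0.8 else 0.4
        plane <- stack[ys, xs, z]
        plane[disk] <- pmax(plane[disk], amp)
        stack[ys, xs, z] <- plane
      }
    }
    stack <- stack + 0.05
    if (noise_sd > 0)
      stack <- stack + stats::rnorm(length(stack), 0, noise_sd)
    channels[[ch]] <- pmin(pmax(stack, 0), 1)
    masks[[ch]] <- mask
    achieved[ch] <- 100 * mean(mask)
  }
  truth$mask <- masks
  truth$pa_achieved <- achieved
  structure(list(channels = channels, truth = truth,
                 pixel_size_um = pixel_size_um, z_step_um = truth$z_step_um),
            class = "if_stack")
}

#' @export
print.if_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("Synthetic IF stack: %d channel(s) of %d x %d x %d (y,x,z), %.2f um/px\n",
              length(x$channels), d[1], d[2], d[3], x$pixel_size_um))
  cat(sprintf("  achieved positive area: %s\n",
              paste(sprintf("%s %.2f%%", names(x$truth$pa_achieved),
                            x$truth$pa_achieved), collapse = ", ")))
  invisible(x)
}
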