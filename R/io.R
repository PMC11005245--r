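#' Fit lifetimes and oxygenation for every point of a cohort
#'
#' Runs the full pointwise analysis over a cohort container: per record,
#' Grubbs rejection of repetitions, averaging, windowed mono-exponential
#' fit, Stern-Volmer pO2 and Hill SO2 ([plim_fit()]); then assigns the
#' analysis vessel class. Penetrating vessels are classified as arteriole or
#' venule from their fitted baseline (day 0) pO2 at 50 um subpial depth
#' ([classify_vessel()]), and the class is frozen and propagated to later
#' days; capillaries keep their morphological identification; primary
#' branches of penetrating vessels are flagged and excluded from capillary
#' pools downstream.
#'
#' @param cohort A [simulate_cohort()] result (or [read_cohort()] handle).
#' @param alpha Grubbs significance level (see [plim_fit()]).
#' @param window_start_us Fit window start (us).
#' @param weighting Fit weighting (see [fit_lifetime()]).
#' @return Data frame with one row per vessel point and day: ids, metadata,
#'   `vessel_class` (analysis class), `n_kept`, `tau_us`, `po2`, `so2`,
#'   `residual_norm`, `converged`.
#' @export
fit_cohort <- function(cohort, alpha = 0.05, window_start_us = 5,
                       weighting = c("none", "poisson")) {
  stopifnot(inherits(cohort, "plim_cohort"))
  weighting <- match.arg(weighting)
  rec <- cohort$records
  t <- bin_times(cohort$protocol)
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    m <- cohort$measurements[[rec$record_id[i]]]$decays
    attr(m, "t") <- t
    attr(m, "protocol") <- cohort$protocol
    f <- plim_fit(m, calib = cohort$calib, window_start_us = window_start_us,
                  alpha = alpha, weighting = weighting)
    data.frame(rec[i, c("record_id", "cohort", "animal_id", "vessel_id",
                        "vessel_type", "depth_um", "layer", "day")],
               n_kept = f$n_kept, tau_us = unname(f$coefficients["tau"]),
               po2 = f$po2, so2 = f$so2,
               residual_norm = f$residual_norm, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, rows)

  # analysis class: penetrating vessels by baseline 50-um pO2, frozen at day 0
  fits$vessel_class <- fits$vessel_type
  pen <- fits$vessel_type %in% c("arteriole", "venule")
  if (any(pen)) {
    base <- fits[pen & fits$day == min(fits$day) & fits$depth_um == 50, ]
    cls <- classify_vessel(base$po2)
    names(cls) <- base$vessel_id
    fits$vessel_class[pen] <- unname(cls[fits$vessel_id[pen]])
  }
  fits
}

#' Red-blood-cell flux for every capillary of a cohort
#'
#' Counts valleys in each repetition trace ([count_rbc()]) and averages the
#' per-repetition fluxes per capillary point ([flux_per_capillary()]).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param estimate Flux estimate carried into `flux`: `"corrected"`
#'   (default) or raw `"counted"` (see [count_rbc()]); both are reported.
#' @param ... Passed to [count_rbc()] (threshold, widths, baseline window).
#' @return Data frame with one row per capillary point and day: ids,
#'   `depth_um`, `layer`, `flux` (RBC/s, the chosen estimate),
#'   `flux_counted`, `flux_corrected`, `n_repetitions`, `n_unresolvable`.
#' @export
flux_cohort <- function(cohort, estimate = c("corrected", "counted"), ...) {
  stopifnot(inherits(cohort, "plim_cohort"))
  estimate <- match.arg(estimate)
  rec <- cohort$records[cohort$records$vessel_type == "capillary", ]
  if (nrow(rec) == 0) stop("cohort contains no capillary traces", call. = FALSE)
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    traces <- cohort$measurements[[rec$record_id[i]]]$traces
    frs <- lapply(traces, count_rbc, ...)
    counted <- flux_per_capillary(frs, estimate = "counted")
    corrected <- flux_per_capillary(frs, estimate = "corrected")
    data.frame(rec[i, c("record_id", "cohort", "animal_id", "vessel_id",
                        "depth_um", "layer", "day")],
               flux = if (estimate == "corrected") corrected else counted,
               flux_counted = counted, flux_corrected = corrected,
               n_repetitions = length(frs),
               n_unresolvable = sum(vapply(frs, `[[`, logical(1),
                                           "unresolvable")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

schema_version <- "1"

#' Write / read a cohort container
#'
#' The container is a directory holding the ground-truth record table as a
#' CSV sidecar (`records.csv`), the raw measurement arrays in native R
#' serialization (`measurements.rds`), and a JSON meta file with the schema
#' version, configuration hash and seed. Reading validates integrity: every
#' record must have its decay histograms; a vessel with missing measurements
#' raises an error naming it.
#'
#' @param cohort A `plim_cohort`.
#' @param path Container directory (created if needed).
#' @return `write_cohort()`: the path, invisibly. `read_cohort()`: the
#'   `plim_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "plim_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$records, file.path(path, "records.csv"),
                   row.names = FALSE)
  saveRDS(cohort$measurements, file.path(path, "measurements.rds"))
  saveRDS(list(config = cohort$config, protocol = cohort$protocol,
               calib = cohort$calib), file.path(path, "params.rds"))
  jsonlite::write_json(
    list(schema_version = schema_version,
         config_hash = config_hash(cohort$config),
         seed = cohort$seed, n_records = nrow(cohort$records)),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("not a cohort container: ", path,
                                    call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(as.character(meta$schema_version), schema_version))
    stop(sprintf("unsupported container schema version '%s' (supported: %s)",
                 meta$schema_version, schema_version), call. = FALSE)
  records <- utils::read.csv(file.path(path, "records.csv"),
                             stringsAsFactors = FALSE)
  measurements <- if (file.exists(file.path(path, "measurements.rds")))
    readRDS(file.path(path, "measurements.rds")) else list()
  params <- readRDS(file.path(path, "params.rds"))
  if (nrow(records)) {
    missing <- setdiff(records$record_id, names(measurements))
    if (length(missing)) {
      v <- records$vessel_id[match(missing[1], records$record_id)]
      stop(sprintf("container integrity error: vessel %s (record %s) has no measurements",
                   v, missing[1]), call. = FALSE)
    }
    no_decay <- records$record_id[!vapply(records$record_id, function(id)
      !is.null(measurements[[id]]$decays), logical(1))]
    if (length(no_decay)) {
      v <- records$vessel_id[match(no_decay[1], records$record_id)]
      stop(sprintf("container integrity error: vessel %s (record %s) is missing its decays",
                   v, no_decay[1]), call. = FALSE)
    }
  }
  structure(list(records = records, measurements = measurements,
                 config = params$config, protocol = params$protocol,
                 calib = params$calib, seed = meta$seed),
            class = "plim_cohort")
}

# Stable hash of a configuration: md5 of its canonical YAML rendering.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config), precision = 15), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [cohort_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A [cohort_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), names(formals(cohort_config)))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(y$n_penetrating)) y$n_penetrating <- unlist(y$n_penetrating)
  if (!is.null(y$po2_sd)) y$po2_sd <- unlist(y$po2_sd)
  do.call(cohort_config, y)
}

#' Run the full synthetic-to-summary pipeline
#'
#' Executes every stage in order — simulate the cohort, fit pO2/SO2 at every
#' vessel point, count capillary RBC flux, and compute the cohort summary
#' tables (per-layer means and CVs with the animal as unit of averaging,
#' depth-dependent oxygen extraction, and longitudinal SO2 changes) — and
#' writes them as CSVs under `out_dir`. Every table carries the
#' configuration hash and seed, so identical (config, seed) runs are
#' bit-identical.
#'
#' @param config A [cohort_config()] or path to a YAML file for
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created).
#' @param seed RNG seed for the simulation.
#' @param keep_cohort If `TRUE`, also writes the cohort container under
#'   `out_dir/cohort/`.
#' @return Invisibly, a list with the tables (`fits`, `flux`,
#'   `layer_summaries`, `doe`, `deltas`) and `paths`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir, seed = 1,
                         keep_cohort = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)

  cohort <- simulate_cohort(config, seed = seed)
  if (keep_cohort) write_cohort(cohort, file.path(out_dir, "cohort"))

  fits <- fit_cohort(cohort)
  flux <- flux_cohort(cohort)
  fits_flux <- merge(fits, flux[, c("record_id", "flux", "n_repetitions")],
                     by = "record_id", all.x = TRUE, sort = FALSE)
  fits_flux <- fits_flux[order(match(fits_flux$record_id, fits$record_id)), ]

  # per-layer cohort summaries (animal = unit of averaging)
  caps <- fits_flux[fits_flux$vessel_class == "capillary", ]
  summaries <- list()
  for (v in c("po2", "so2")) {
    for (s in c("mean", "cv")) {
      for (set in list(list(d = caps, pool = "capillary"),
                       list(d = fits_flux[fits_flux$vessel_class == "arteriole", ],
                            pool = "arteriole"),
                       list(d = fits_flux[fits_flux$vessel_class == "venule", ],
                            pool = "venule"))) {
        if (nrow(set$d) == 0) next
        a <- suppressWarnings(cohort_aggregate(set$d, value = v, stat = s))
        a <- cbind(data.frame(pool = set$pool, value = v, stat = s,
                              stringsAsFactors = FALSE), a)
        summaries[[length(summaries) + 1]] <- a
      }
    }
  }
  if (nrow(caps) && any(!is.na(caps$flux))) {
    for (s in c("mean", "cv")) {
      a <- suppressWarnings(cohort_aggregate(caps, value = "flux", stat = s))
      summaries[[length(summaries) + 1]] <-
        cbind(data.frame(pool = "capillary", value = "flux", stat = s,
                         stringsAsFactors = FALSE), a)
    }
  }
  layer_summaries <- do.call(rbind, summaries)

  # DOE: per-animal SaO2 - SvO2, then averaged over animals
  doe_animal <- compute_doe(fits_flux, by = c("cohort", "day", "animal_id"))
  doe <- cohort_aggregate(
    data.frame(cohort = doe_animal$cohort, day = doe_animal$day,
               animal_id = doe_animal$animal_id, layer = doe_animal$layer,
               doe = doe_animal$doe),
    value = "doe", stat = "mean")
  names(doe)[names(doe) == "mean"] <- "doe_mean"
  names(doe)[names(doe) == "se"] <- "doe_se"

  deltas <- if (length(unique(fits_flux$day)) > 1) so2_deltas(caps) else NULL

  tables <- list(fits = fits_flux, layer_summaries = layer_summaries,
                 doe = doe, deltas = deltas)
  paths <- character(0)
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    tb <- tables[[nm]]
    tb$config_hash <- hash
    tb$seed <- seed
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tb, p, row.names = FALSE)
    paths[nm] <- p
  }
  invisible(c(tables, list(flux = flux, paths = paths, config_hash = hash)))
}
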