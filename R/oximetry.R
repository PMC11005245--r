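#' Per-layer summary statistics of vessel measurements
#'
#' Groups vessel-point records into cortical layers by subpial depth and
#' computes, for a chosen value column: n, mean, sd, standard error
#' (`sd/sqrt(n)`), and the coefficient of variation (`sd/mean`, sample sd
#' with n-1 denominator). The CV is the package's heterogeneity metric.
#'
#' @param records Data frame with at least `depth_um` (or `layer`) and the
#'   `value` column; typically the fit table from [fit_cohort()] with one row
#'   per vessel point.
#' @param value Name of the column to summarize (e.g. `"po2"`, `"so2"`,
#'   `"flux"`).
#' @param by Optional extra grouping column names (e.g. `"vessel_class"`,
#'   `"animal_id"`, `"day"`).
#' @return Data frame with one row per group: grouping columns, `layer`, `n`,
#'   `mean`, `sd`, `se`, `cv`. CV is `NA` (with a warning) when the group
#'   mean is not positive.
#' @export
layer_summary <- function(records, value = "po2", by = character()) {
  stopifnot(is.data.frame(records), value %in% names(records))
  if (!"layer" %in% names(records)) {
    stopifnot("depth_um" %in% names(records))
    records$layer <- assign_layer(records$depth_um)
  }
  records <- records[!is.na(records[[value]]), , drop = FALSE]
  if (nrow(records) == 0) stop("no non-missing values to summarize", call. = FALSE)
  keys <- c(by, "layer")
  split_key <- interaction(records[keys], drop = TRUE, lex.order = TRUE)
  parts <- split(records, split_key)
  out <- do.call(rbind, lapply(parts, function(d) {
    x <- d[[value]]
    m <- mean(x)
    s <- if (length(x) > 1) stats::sd(x) else 0
    cv <- if (m > 0) s / m else NA_real_
    cbind(d[1, keys, drop = FALSE],
          data.frame(n = length(x), mean = m, sd = s,
                     se = s / sqrt(length(x)), cv = cv))
  }))
  rownames(out) <- NULL
  if (anyNA(out$cv))
    warning("CV undefined for groups with non-positive mean", call. = FALSE)
  out[order(match(out$layer, cortical_layers()$layer)), , drop = FALSE]
}

#' Depth-dependent oxygen extraction per cortical layer
#'
#' For each layer, the mean arteriolar saturation SaO2 and mean venular
#' saturation SvO2 are computed by averaging all measured arteriole and
#' venule SO2 values in that layer, and the extraction is their difference,
#' `DOE = SaO2 - SvO2` (percentage points). The SaO2-normalized extraction
#' fraction (OEF) is intentionally not applied.
#'
#' @param records Data frame with columns `vessel_class`
#'   (`"arteriole"`/`"venule"`; other classes are ignored), `so2`, and
#'   `depth_um` or `layer`. Optional extra grouping via `by`.
#' @param by Optional extra grouping column names (e.g. `"animal_id"`, `"day"`).
#' @return Data frame with columns `by...`, `layer`, `n_arteriole`,
#'   `n_venule`, `sao2`, `svo2`, `doe`. Layers missing one class are omitted
#'   with a warning.
#' @export
compute_doe <- function(records, by = character()) {
  stopifnot(is.data.frame(records),
            all(c("vessel_class", "so2") %in% names(records)))
  if (!"layer" %in% names(records)) {
    stopifnot("depth_um" %in% names(records))
    records$layer <- assign_layer(records$depth_um)
  }
  records <- records[records$vessel_class %in% c("arteriole", "venule") &
                       !is.na(records$so2), , drop = FALSE]
  keys <- c(by, "layer")
  parts <- split(records, interaction(records[keys], drop = TRUE,
                                      lex.order = TRUE))
  rows <- lapply(parts, function(d) {
    a <- d$so2[d$vessel_class == "arteriole"]
    v <- d$so2[d$vessel_class == "venule"]
    if (length(a) == 0 || length(v) == 0) return(NULL)
    cbind(d[1, keys, drop = FALSE],
          data.frame(n_arteriole = length(a), n_venule = length(v),
                     sao2 = mean(a), svo2 = mean(v),
                     doe = mean(a) - mean(v)))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(sprintf("%d layer group(s) omitted: missing arterioles or venules",
                    dropped), call. = FALSE)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no layer has both arterioles and venules", call. = FALSE)
  rownames(out) <- NULL
  out[order(match(out$layer, cortical_layers()$layer)), , drop = FALSE]
}

#' Cohort-level aggregation with the animal as unit of averaging
#'
#' Per-animal layer statistics are computed first, then averaged (unweighted)
#' across the animals of each cohort, so every animal counts once regardless
#' of how many vessels it contributed; the cohort standard error is taken
#' over animals.
#'
#' @param records Data frame of vessel-point measurements with columns
#'   `cohort`, `animal_id`, the `value` column, and `depth_um` or `layer`;
#'   optionally `day` (kept as a grouping variable if present).
#' @param value Column to aggregate (e.g. `"po2"`, `"so2"`, `"flux"`).
#' @param stat Which per-animal statistic to carry to the cohort level:
#'   `"mean"` or `"cv"`.
#' @return Data frame with one row per cohort (x day) x layer: `n_animals`,
#'   `mean` (cohort mean of per-animal statistics), `se` (over animals).
#' @export
cohort_aggregate <- function(records, value = "po2",
                             stat = c("mean", "cv")) {
  stat <- match.arg(stat)
  stopifnot(all(c("cohort", "animal_id") %in% names(records)))
  by <- c("cohort", intersect("day", names(records)), "animal_id")
  per_animal <- layer_summary(records, value = value, by = by)
  per_animal$stat <- per_animal[[stat]]
  keys <- c(setdiff(by, "animal_id"), "layer")
  parts <- split(per_animal, interaction(per_animal[keys], drop = TRUE,
                                         lex.order = TRUE))
  out <- do.call(rbind, lapply(parts, function(d) {
    x <- d$stat[!is.na(d$stat)]
    cbind(d[1, keys, drop = FALSE],
          data.frame(n_animals = length(x), mean = mean(x),
                     se = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0))
  }))
  rownames(out) <- NULL
  out[order(out$cohort, match(out$layer, cortical_layers()$layer)), ,
      drop = FALSE]
}

#' Longitudinal saturation changes relative to baseline
#'
#' For vessels measured on several days, computes the per-point change
#' `dSO2 = SO2(day d) - SO2(day 0)` by aligning measurements of the same
#' vessel point (`vessel_id` x `depth_um`) across days, then aggregates with
#' the animal as the unit of averaging (per-animal mean first, then cohort
#' mean and SE over animals).
#'
#' @param records Data frame with columns `cohort`, `animal_id`, `vessel_id`,
#'   `depth_um`, `day`, `so2`.
#' @param value Column to difference against baseline (default `"so2"`).
#' @return Data frame with one row per cohort x day (> 0) x layer:
#'   `n_animals`, `delta_mean`, `delta_se`.
#' @export
so2_deltas <- function(records, value = "so2") {
  need <- c("cohort", "animal_id", "vessel_id", "depth_um", "day", value)
  stopifnot(all(need %in% names(records)))
  base <- records[records$day == 0, c("vessel_id", "depth_um", value)]
  names(base)[3] <- "baseline"
  later <- records[records$day != 0, , drop = FALSE]
  mg <- merge(later, base, by = c("vessel_id", "depth_um"))
  if (nrow(mg) == 0) stop("no vessel points with a day-0 baseline", call. = FALSE)
  mg$delta <- mg[[value]] - mg$baseline
  # CV of a signed change is not requested here; silence the undefined-CV note
  agg <- suppressWarnings(cohort_aggregate(
    data.frame(cohort = mg$cohort, animal_id = mg$animal_id, day = mg$day,
               depth_um = mg$depth_um, delta = mg$delta),
    value = "delta", stat = "mean"))
  names(agg)[names(agg) == "mean"] <- "delta_mean"
  names(agg)[names(agg) == "se"] <- "delta_se"
  agg
}
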