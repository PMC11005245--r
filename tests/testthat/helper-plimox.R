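# Shared fixtures, built in code.

# A constructed trace with rectangular valleys at known positions: flat
# baseline with `widths[i]` consecutive samples dropped to `depth` starting
# at `starts[i]` (1-based sample indices).
rect_valley_trace <- function(starts, widths, n = 2000, baseline = 100,
                              depth = 10) {
  y <- rep(baseline, n)
  for (i in seq_along(starts))
    y[starts[i]:(starts[i] + widths[i] - 1)] <- depth
  intensity_trace(y)
}

# Brute-force run enumeration: counts maximal runs of samples strictly below
# `thr` after merging runs separated by <= debounce above-threshold samples,
# keeping runs of length >= min_width. Written as a naive loop, independent
# of the package's rle-based implementation.
brute_force_valleys <- function(y, thr, min_width = 2, debounce = 1) {
  below <- y < thr
  # merge short gaps
  i <- 1
  n <- length(below)
  while (i <= n) {
    if (!below[i]) {
      j <- i
      while (j <= n && !below[j]) j <- j + 1
      gap <- j - i
      if (i > 1 && j <= n && gap <= debounce) below[i:(j - 1)] <- TRUE
      i <- j
    } else i <- i + 1
  }
  count <- 0
  run <- 0
  for (i in seq_len(n)) {
    if (below[i]) run <- run + 1
    else {
      if (run >= min_width) count <- count + 1
      run <- 0
    }
  }
  if (run >= min_width) count <- count + 1
  count
}

# Draw k candidate rectangular valleys and keep a greedily non-overlapping
# subset separated by at least `gap` above-threshold samples.
random_valleys <- function(k, n = 2000, margin = 60, width_range = 2:20,
                           gap = 2) {
  if (k == 0) return(list(starts = integer(0), widths = integer(0)))
  starts <- sort(sample(seq(margin, n - margin, by = 2), k))
  widths <- sample(width_range, k, replace = TRUE)
  keep_s <- integer(0); keep_w <- integer(0); last_end <- -Inf
  for (i in seq_len(k)) {
    if (starts[i] > last_end + gap) {
      keep_s <- c(keep_s, starts[i]); keep_w <- c(keep_w, widths[i])
      last_end <- starts[i] + widths[i] - 1
    }
  }
  list(starts = keep_s, widths = keep_w)
}

# Small cohort configuration for fast end-to-end tests.
tiny_config <- function(noise = FALSE, n_animals = 2, ...) {
  cohort_config(n_animals = n_animals,
                n_penetrating = c(arteriole = 1, venule = 1),
                n_capillaries_per_depth = 2,
                n_primary_branches_per_depth = 1,
                n_flux_repetitions = 1,
                photon_budget = 2e4,
                noise = noise, ...)
}
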