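#' Maximum-intensity projection of a z-stack
#'
#' Per-pixel maximum over the z (third) dimension, computed over the full
#' stack thickness.
#'
#' @param stack A `ny x nx x nz` numeric array, a list of equally sized
#'   matrices (z-planes), or an [simulate_if_stack()] channel.
#' @return A `ny x nx` matrix.
#' @export
max_intensity_projection <- function(stack) {
  if (is.list(stack) && !is.array(stack)) {
    dims <- lapply(stack, dim)
    if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
      stop("mismatched z-plane shapes", call. = FALSE)
    return(Reduce(pmax, stack))
  }
  stopifnot(is.array(stack))
  if (length(dim(stack)) == 2) return(stack)
  stopifnot(length(dim(stack)) == 3)
  apply(stack, c(1, 2), max)
}

#' Shared intensity threshold for a densitometry batch
#'
#' Percent-area densitometry requires one threshold applied identically to
#' every projection in the batch. The threshold is determined from the
#' intensity histogram by Otsu's method computed on the brightest image of
#' the batch (the image with the highest mean intensity), then frozen
#' batch-wide — mirroring acquisition practice where gain is fixed on one of
#' the brightest slices.
#'
#' @param mips A matrix or list of matrices (the batch of projections),
#'   intensities in `[0, 1]`.
#' @return A single threshold value.
#' @export
batch_threshold <- function(mips) {
  if (is.matrix(mips)) mips <- list(mips)
  stopifnot(length(mips) >= 1)
  brightest <- mips[[which.max(vapply(mips, mean, numeric(1)))]]
  EBImage::otsu(brightest, range = c(0, 1))
}

#' Binarize a projection at a fixed threshold
#'
#' A pixel is positive iff its intensity is strictly above the threshold.
#' When given a batch (list of projections), a single scalar threshold is
#' required — requesting per-image thresholds is a contract violation, since
#' percent areas are only comparable under an identical threshold.
#'
#' @param mip Matrix, or list of matrices (batch mode).
#' @param threshold Single finite threshold shared by the whole batch.
#' @return A logical mask (or list of masks).
#' @export
binarize <- function(mip, threshold) {
  if (length(threshold) != 1 || !is.finite(threshold))
    stop("`threshold` must be a single finite value shared by the batch",
         call. = FALSE)
  if (is.list(mip) && !is.matrix(mip)) return(lapply(mip, function(m) m > threshold))
  mip > threshold
}

#' Percent area of positive pixels, globally and per cortical layer
#'
#' `PA = 100 * positive / total` pixels. When a pixel size is supplied, image
#' rows are mapped to cortical depth (pial surface at the top row, row `i`
#' centred at `(i - 1/2) * pixel_size_um`) and the PA is also reported within
#' each cortical layer band; bands that do not intersect the image are
#' omitted with a warning.
#'
#' @param mask Logical matrix from [binarize()].
#' @param pixel_size_um Optional lateral pixel size (um) enabling the
#'   per-layer split.
#' @param layers Layer definition table, default [cortical_layers()].
#' @param threshold Optional threshold value recorded in the output.
#' @return Data frame with columns `layer` (`"global"` plus layer labels),
#'   `n_pixels`, `n_positive`, `pa_percent`, `threshold`.
#' @export
percent_area <- function(mask, pixel_size_um = NULL,
                         layers = cortical_layers(), threshold = NA_real_) {
  stopifnot(is.matrix(mask), is.logical(mask))
  out <- data.frame(layer = "global", n_pixels = length(mask),
                    n_positive = sum(mask),
                    pa_percent = 100 * mean(mask), threshold = threshold,
                    stringsAsFactors = FALSE)
  if (!is.null(pixel_size_um)) {
    depth <- (seq_len(nrow(mask)) - 0.5) * pixel_size_um
    for (i in seq_len(nrow(layers))) {
      rows <- depth >= layers$lower_um[i] &
        (depth < layers$upper_um[i] |
           (i == nrow(layers) & depth <= layers$upper_um[i]))
      if (!any(rows)) {
        warning(sprintf("layer %s outside the imaged strip: omitted",
                        layers$layer[i]), call. = FALSE)
        next
      }
      band <- mask[rows, , drop = FALSE]
      out <- rbind(out, data.frame(layer = layers$layer[i],
                                   n_pixels = length(band),
                                   n_positive = sum(band),
                                   pa_percent = 100 * mean(band),
                                   threshold = threshold,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Percent-area densitometry of an immunofluorescence stack batch
#'
#' Full histology pipeline: per-channel maximum-intensity projection over
#' the stack thickness, one shared Otsu threshold per channel across the
#' whole batch, binarization, and global plus per-layer percent area.
#'
#' @param stacks A list of [simulate_if_stack()] objects (or one stack).
#' @param threshold Optional fixed threshold(s); default determined per
#'   channel by [batch_threshold()] across the batch.
#' @return Data frame with columns `image_id`, `channel`, `layer`,
#'   `n_pixels`, `n_positive`, `pa_percent`, `threshold`.
#' @export
densitometry <- function(stacks, threshold = NULL) {
  if (inherits(stacks, "if_stack")) stacks <- list(stacks)
  stopifnot(length(stacks) >= 1)
  channels <- names(stacks[[1]]$channels)
  out <- list()
  for (ch in channels) {
    mips <- lapply(stacks, function(s) max_intensity_projection(s$channels[[ch]]))
    thr <- if (is.null(threshold)) batch_threshold(mips)
           else if (is.numeric(threshold) && !is.null(names(threshold)))
             threshold[[ch]]
           else threshold
    masks <- binarize(mips, thr)
    for (i in seq_along(stacks)) {
      pa <- percent_area(masks[[i]], pixel_size_um = stacks[[i]]$pixel_size_um,
                         threshold = thr)
      pa <- cbind(data.frame(image_id = sprintf("img%02d", i), channel = ch,
                             stringsAsFactors = FALSE), pa)
      out[[length(out) + 1]] <- pa
    }
  }
  do.call(rbind, out)
}

#' Write / read an immunofluorescence stack as multi-page TIFF
#'
#' Pages are ordered channel-major (all z-planes of channel 1, then channel
#' 2, ...), intensities in `[0, 1]`; a JSON sidecar (`<path>.json`) records
#' the channel layout, pixel geometry and — for synthetic stacks — the
#' ground-truth percent areas.
#'
#' @param stack An `if_stack`.
#' @param path Output TIFF path.
#' @return `write_if_stack()`: the path, invisibly. `read_if_stack()`: an
#'   `if_stack` (without the pixelwise truth masks, which are not stored).
#' @export
write_if_stack <- function(stack, path) {
  stopifnot(inherits(stack, "if_stack"))
  pages <- list()
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    for (z in seq_len(dim(a)[3])) pages[[length(pages) + 1]] <- a[, , z]
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(channels = names(stack$channels),
               n_z = dim(stack$channels[[1]])[3],
               pixel_size_um = stack$pixel_size_um,
               z_step_um = stack$z_step_um,
               synthetic = TRUE,
               pa_achieved = as.list(stack$truth$pa_achieved))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_if_stack
#' @export
read_if_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- meta$n_z
  channels <- list()
  for (i in seq_along(meta$channels)) {
    planes <- pages[((i - 1) * nz + 1):(i * nz)]
    channels[[meta$channels[i]]] <-
      array(unlist(planes), dim = c(dim(planes[[1]]), nz))
  }
  truth <- list(pa_achieved = unlist(meta$pa_achieved))
  structure(list(channels = channels, truth = truth,
                 pixel_size_um = meta$pixel_size_um,
                 z_step_um = meta$z_step_um),
            class = "if_stack")
}
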