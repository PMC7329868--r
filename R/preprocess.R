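# Image preprocessing: percentile windowing, z-score normalisation from a
# cohort subset, foreground slice sampling to a fixed count, and in-plane
# downsampling. The chain maps any admissible case onto the fixed
# (n_slices, target, target) stack shape every model consumes.

#' Specify a percentile intensity window
#'
#' The default (0.6, 0.99) percentile range corresponds to the window a
#' radiologist would use for organ-focused decision-making in abdominal CT.
#' For other problems the percentiles should be adjusted to the intensity
#' distribution of the relevant body parts.
#'
#' @param lower_percentile,upper_percentile Fractions in `[0, 1]`,
#'   `lower < upper`.
#' @param scope `"per_volume"` (default: bounds computed from each volume) or
#'   `"cohort"` (bounds computed once from pooled voxels).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(lower_percentile = 0.6, upper_percentile = 0.99,
                        scope = c("per_volume", "cohort")) {
  scope <- match.arg(scope)
  if (!(lower_percentile >= 0 && lower_percentile < upper_percentile && upper_percentile <= 1)) {
    stop("need 0 <= lower_percentile < upper_percentile <= 1")
  }
  structure(list(lower_percentile = lower_percentile,
                 upper_percentile = upper_percentile,
                 scope = scope), class = "window_spec")
}

#' Compute window bounds as distribution percentiles
#'
#' Uses the linear-interpolation quantile definition (interpolation between
#' order statistics), so independent implementations agree exactly.
#'
#' @param values Numeric collection of intensities (array or vector).
#' @param spec A [window_spec()].
#' @return Numeric `c(lower, upper)` in the input units.
#' @export
compute_window_bounds <- function(values, spec = window_spec()) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("cannot compute window bounds of an empty collection")
  b <- stats::quantile(values, probs = c(spec$lower_percentile, spec$upper_percentile),
                       names = FALSE, type = 7)
  c(lower = b[1], upper = b[2])
}

#' Clip a volume to an intensity window
#'
#' Voxel-wise clamp to `[lower, upper]`; shape and spacing unchanged.
#' Idempotent.
#'
#' @param volume A [ct_volume()].
#' @param bounds Numeric `c(lower, upper)`, `lower <= upper`.
#' @return The windowed `ct_volume`.
#' @export
apply_window <- function(volume, bounds) {
  stopifnot(inherits(volume, "ct_volume"))
  if (bounds[1] > bounds[2]) stop("window lower bound exceeds upper bound")
  volume$intensities <- clamp(volume$intensities, bounds[1], bounds[2])
  volume
}

#' Pooled intensity statistics from a cohort subset
#'
#' Mean and standard deviation pooled over all voxels of the given (already
#' windowed) volumes. In a clinical environment only a subset of the data is
#' typically available before training starts, so normalisation statistics
#' are taken from a random subset rather than the full data set.
#'
#' @param volumes List of windowed [ct_volume()] objects.
#' @return An object of class `norm_stats` with fields `mean`, `std`,
#'   `n_cases_used`.
#' @export
compute_norm_stats <- function(volumes) {
  if (length(volumes) == 0L) stop("need at least one volume")
  v <- unlist(lapply(volumes, function(x) as.numeric(x$intensities)), use.names = FALSE)
  m <- mean(v)
  s <- stats::sd(v)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate intensity statistics: pooled standard deviation is zero")
  }
  structure(list(mean = m, std = s, n_cases_used = length(volumes)),
            class = "norm_stats")
}

#' Sample a random cohort subset and compute normalisation statistics
#'
#' @param volumes List of windowed volumes (the full available cohort).
#' @param n_subset Cases to draw; default `min(10, length(volumes))`.
#' @param rng An [rng_stream()].
#' @return A `norm_stats` object.
#' @export
norm_stats_from_subset <- function(volumes, n_subset = min(10L, length(volumes)),
                                   rng = rng_stream(1L)) {
  if (length(volumes) == 0L) stop("need at least one volume")
  idx <- rs_sample(rng, seq_along(volumes), min(n_subset, length(volumes)))
  compute_norm_stats(volumes[idx])
}

#' Z-score normalise a windowed volume
#'
#' Voxel-wise `(v - mean) / std`. The result is no longer on the HU scale;
#' the volume's `units` field is set to `"zscore"`.
#'
#' @param volume A [ct_volume()].
#' @param stats A `norm_stats` object (`std > 0`).
#' @return Normalised `ct_volume`.
#' @export
znormalize <- function(volume, stats) {
  stopifnot(inherits(volume, "ct_volume"))
  if (stats$std <= 0) stop("normalisation std must be > 0")
  volume$intensities <- (volume$intensities - stats$mean) / stats$std
  volume$units <- "zscore"
  volume
}

#' Construct a slice stack
#'
#' The unit of training data: an aligned set of 2D intensity and label
#' slices plus the (sorted, possibly fractional after interpolation) source
#' slice positions they came from.
#'
#' @param slices 3D array `(n_slices, rows, cols)` of intensities.
#' @param label_slices Optional aligned 3D integer array.
#' @param source_indices Numeric source positions, one per slice.
#' @param fill_value Intensity representing background/air after windowing;
#'   used by geometric operators to fill exposed regions.
#' @return An object of class `slice_stack`.
#' @export
slice_stack <- function(slices, label_slices = NULL, source_indices = NULL,
                        fill_value = min(slices)) {
  slices <- as.array(slices)
  stopifnot(length(dim(slices)) == 3L)
  if (!is.null(label_slices)) {
    label_slices <- as.array(label_slices)
    stopifnot(identical(dim(label_slices), dim(slices)))
    storage.mode(label_slices) <- "integer"
  }
  if (is.null(source_indices)) source_indices <- seq_len(dim(slices)[1])
  stopifnot(length(source_indices) == dim(slices)[1])
  structure(list(slices = slices, label_slices = label_slices,
                 source_indices = as.numeric(source_indices),
                 fill_value = fill_value),
            class = "slice_stack")
}

#' Sample slices from a case to a fixed count
#'
#' Selects `n` slice positions at random. With `exclude_background = TRUE`
#' (the training default) only slices containing at least one foreground
#' voxel are candidates, since pure background slices are not considered at
#' test time either. Sampling is without replacement when enough candidates
#' exist, with replacement otherwise (short volumes are never upsampled by
#' interpolation, they are re-sampled). Repeating the sampling per volume
#' gives a simultaneous augmentation effect across epochs.
#'
#' @param case A labelled [ct_case()] (labels required when excluding
#'   background).
#' @param n Target slice count (default 16).
#' @param exclude_background Restrict candidates to foreground slices.
#' @param rng An [rng_stream()].
#' @return A [slice_stack()] with `source_indices` sorted ascending.
#' @export
sample_slices <- function(case, n = 16L, exclude_background = TRUE,
                          rng = rng_stream(1L)) {
  stopifnot(inherits(case, "ct_case"))
  ns <- dim(case$image$intensities)[1]
  if (exclude_background) {
    if (is.null(case$labels)) stop("exclude_background requires labels")
    lab <- case$labels$classes
    fg <- which(apply(lab > 0L, 1L, any))
    if (length(fg) == 0L) {
      stop("case '", case$id, "' has no foreground slices to sample")
    }
    candidates <- fg
  } else {
    candidates <- seq_len(ns)
  }
  replace <- length(candidates) < n
  take <- if (length(candidates) == n && !replace) {
    candidates  # forced selection: each candidate exactly once
  } else {
    rs_sample(rng, candidates, n, replace = replace)
  }
  take <- sort(take)
  sl <- case$image$intensities[take, , , drop = FALSE]
  lb <- if (!is.null(case$labels)) case$labels$classes[take, , , drop = FALSE] else NULL
  slice_stack(sl, lb, source_indices = take,
              fill_value = min(case$image$intensities))
}

# Area-averaging weight matrix mapping `src` samples onto `target` samples.
# Row t holds the fractional overlap of target cell t with each source cell.
.area_weights <- function(src, target) {
  r <- src / target
  W <- matrix(0, target, src)
  for (t in seq_len(target)) {
    a <- (t - 1) * r; b <- t * r
    s0 <- floor(a) + 1; s1 <- ceiling(b)
    for (s in s0:min(s1, src)) {
      W[t, s] <- (min(b, s) - max(a, s - 1)) / r
    }
  }
  W
}

# Nearest-neighbour source index for each target cell centre.
.nn_index <- function(src, target) {
  pmin(src, floor((seq_len(target) - 0.5) * src / target) + 1L)
}

#' Downsample a slice stack in-plane
#'
#' Intensities are resized by area averaging (each target voxel is the
#' overlap-weighted mean of the source voxels it covers); labels by
#' nearest-neighbour, so no new label values can appear. Slice count is
#' unchanged. `target` equal to the source size is the identity.
#'
#' @param stack A [slice_stack()] with square slices.
#' @param target Side length (>= 8).
#' @return The resized `slice_stack`.
#' @export
downsample_stack <- function(stack, target = 128L) {
  stopifnot(inherits(stack, "slice_stack"))
  d <- dim(stack$slices)
  if (d[2] != d[3]) stop("downsample_stack requires square slices, got ",
                         d[2], "x", d[3])
  if (target < 8L) stop("target side must be >= 8")
  if (target == d[2]) return(stack)
  if (target > d[2]) stop("target side exceeds source size (downsampling only)")
  W <- .area_weights(d[2], target)
  tW <- t(W)
  out <- array(0, c(d[1], target, target))
  for (i in seq_len(d[1])) out[i, , ] <- W %*% stack$slices[i, , ] %*% tW
  lab <- NULL
  if (!is.null(stack$label_slices)) {
    idx <- .nn_index(d[2], target)
    lab <- stack$label_slices[, idx, idx, drop = FALSE]
  }
  slice_stack(out, lab, stack$source_indices, fill_value = stack$fill_value)
}

#' Full preprocessing chain for one case
#'
#' Applies, in order: percentile windowing (bounds from this volume under
#' `per_volume` scope, or the supplied cohort `bounds`), z-score
#' normalisation with the supplied statistics, random foreground slice
#' sampling to `n_slices`, and in-plane downsampling to
#' `target_size` x `target_size`. Deterministic given the rng state.
#'
#' @param case A [ct_case()].
#' @param window A [window_spec()].
#' @param stats A `norm_stats` object.
#' @param n_slices Slices per stack (default 16).
#' @param target_size In-plane side (default 128).
#' @param exclude_background Restrict sampling to foreground slices.
#' @param rng An [rng_stream()].
#' @param bounds Optional precomputed `c(lower, upper)` for cohort scope.
#' @return A [slice_stack()] of shape `(n_slices, target_size, target_size)`.
#' @export
preprocess_case <- function(case, window = window_spec(), stats,
                            n_slices = 16L, target_size = 128L,
                            exclude_background = TRUE,
                            rng = rng_stream(1L), bounds = NULL) {
  stopifnot(inherits(case, "ct_case"))
  if (is.null(bounds)) {
    if (window$scope == "cohort") {
      stop("cohort-scope windowing requires precomputed bounds")
    }
    bounds <- compute_window_bounds(case$image$intensities, window)
  }
  vol <- apply_window(case$image, bounds)
  vol <- znormalize(vol, stats)
  wcase <- ct_case(vol, case$labels, id = case$id)
  stack <- sample_slices(wcase, n = n_slices, exclude_background = exclude_background,
                         rng = rng)
  downsample_stack(stack, target_size)
}
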