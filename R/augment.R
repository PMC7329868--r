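# CT-specific image augmentation (CTIA): cluster-wise voxel intensity range
# shift (CWVRS), slice skipping, slice interpolation, Gaussian noise, bounded
# random rotation, random patch extraction, and the stochastic batch policy
# that applies them during training.
#
# Contracts shared by all operators: image/label pairing is preserved under
# identical geometry, no operator introduces label values absent from its
# input, and every operator reduces to the exact identity when its magnitude
# parameter is zero.

#' Tissue intensity window table
#'
#' Base intensity windows corresponding to ranges used in routine
#' radiological workflows, slightly extended to allow for uncertainty in the
#' exact ranges: soft tissue/organ, lung, and bone presets.
#'
#' @param windows Data frame with columns `name`, `lower`, `upper` (HU).
#' @return An object of class `window_table`.
#' @export
intensity_window_table <- function(windows = data.frame(
    name = c("soft_tissue", "lung", "bone"),
    lower = c(-150, -1000, 200),
    upper = c(250, -300, 2000))) {
  stopifnot(all(c("name", "lower", "upper") %in% names(windows)))
  if (any(windows$lower >= windows$upper)) stop("every window needs lower < upper")
  structure(windows, class = c("window_table", "data.frame"))
}

#' Express a HU window table in z-score units
#'
#' When augmentation runs after z-score normalisation, the window table and
#' shift magnitudes must be transformed through the same normalisation.
#'
#' @param table A [intensity_window_table()].
#' @param stats A `norm_stats` object.
#' @return The transformed `window_table`.
#' @export
transform_window_table <- function(table, stats) {
  table$lower <- (table$lower - stats$mean) / stats$std
  table$upper <- (table$upper - stats$mean) / stats$std
  table
}

#' Declarative augmentation policy
#'
#' Describes which CTIA operators fire during training, with what
#' probabilities and parameter ranges. Defaults follow the training
#' protocol: augmentation applied to 90% of training batches in 2D and 80%
#' in 3D, CWVRS to 20% of volumes, rotations bounded at 16 degrees.
#'
#' @param dims 2 or 3; selects the default `p_augment`.
#' @param p_augment Probability a batch is augmented.
#' @param p_cwvrs Probability CWVRS applies to a volume.
#' @param max_rotation_deg In-plane rotation bound, degrees.
#' @param noise_sigma Additive Gaussian noise std (intensity units of the
#'   stacks being augmented).
#' @param skip_max Maximum slices removable by slice skipping.
#' @param interp_max Maximum slices insertable by slice interpolation.
#' @param patch_size Optional in-plane crop side; `NULL` disables cropping.
#' @param cwvrs_max_shift_hu CWVRS window shift bound (HU).
#' @param cwvrs_max_scale_delta CWVRS bound perturbation as a fraction of the
#'   window width.
#' @param keep_slice_count Re-pad skipped stacks back to their input slice
#'   count (required when the consumer needs a fixed count).
#' @return An object of class `augment_policy`.
#' @export
augment_policy <- function(dims = 2L,
                           p_augment = if (dims == 2L) 0.9 else 0.8,
                           p_cwvrs = 0.2,
                           max_rotation_deg = 16,
                           noise_sigma = 0.05,
                           skip_max = 2L,
                           interp_max = 2L,
                           patch_size = NULL,
                           cwvrs_max_shift_hu = 20,
                           cwvrs_max_scale_delta = 0.1,
                           keep_slice_count = TRUE) {
  if (p_augment < 0 || p_augment > 1 || p_cwvrs < 0 || p_cwvrs > 1) {
    stop("probabilities must lie in [0, 1]")
  }
  if (max_rotation_deg < 0) stop("max_rotation_deg must be >= 0")
  structure(list(dims = dims, p_augment = p_augment, p_cwvrs = p_cwvrs,
                 max_rotation_deg = max_rotation_deg, noise_sigma = noise_sigma,
                 skip_max = as.integer(skip_max), interp_max = as.integer(interp_max),
                 patch_size = patch_size,
                 cwvrs_max_shift_hu = cwvrs_max_shift_hu,
                 cwvrs_max_scale_delta = cwvrs_max_scale_delta,
                 keep_slice_count = keep_slice_count),
            class = "augment_policy")
}

#' Cluster-wise voxel intensity range shift
#'
#' For each tissue window independently, draws a shift and small bound
#' perturbations, then linearly remaps voxels lying inside the original
#' window onto the perturbed window. Voxels outside all windows are left
#' bit-identical; labels are untouched. This simulates vendor- or
#' patient-specific variations in exact tissue intensities that lead to
#' different spatial patterns after windowing. Overlapping windows are
#' resolved in table order: the first window containing a voxel claims it.
#'
#' @param stack A [slice_stack()] whose intensities are on the same scale as
#'   `table` (see [transform_window_table()] for normalised stacks).
#' @param table A [intensity_window_table()].
#' @param max_shift_hu Shift bound (same units as the table).
#' @param max_scale_delta Bound perturbation as a fraction of window width.
#' @param rng An [rng_stream()].
#' @return The augmented `slice_stack`.
#' @export
cwvrs <- function(stack, table = intensity_window_table(),
                  max_shift_hu = 20, max_scale_delta = 0.1,
                  rng = rng_stream(1L)) {
  stopifnot(inherits(stack, "slice_stack"))
  if (max_shift_hu == 0 && max_scale_delta == 0) return(stack)
  v <- stack$slices
  remaining <- array(TRUE, dim(v))
  for (i in seq_len(nrow(table))) {
    lo <- table$lower[i]; hi <- table$upper[i]; wid <- hi - lo
    for (try in seq_len(20L)) {
      shift <- rs_unif(rng, 1L, -max_shift_hu, max_shift_hu)
      dlo <- rs_unif(rng, 1L, -max_scale_delta * wid, max_scale_delta * wid)
      dhi <- rs_unif(rng, 1L, -max_scale_delta * wid, max_scale_delta * wid)
      nlo <- lo + shift + dlo; nhi <- hi + shift + dhi
      if (nlo < nhi) break
      if (try == 20L) stop("CWVRS could not draw a non-degenerate window for '",
                           table$name[i], "'")
    }
    sel <- remaining & v >= lo & v <= hi
    if (any(sel)) {
      v[sel] <- nlo + (v[sel] - lo) / wid * (nhi - nlo)
      remaining[sel] <- FALSE
    }
  }
  stack$slices <- v
  stack
}

# Pick up to k pairwise non-adjacent interior slice positions.
.nonadjacent_interior <- function(n_slices, k, rng) {
  pool <- seq(2L, n_slices - 1L)
  chosen <- integer(0)
  while (length(chosen) < k && length(pool) > 0) {
    p <- if (length(pool) == 1L) pool else rs_sample(rng, pool, 1L)
    chosen <- c(chosen, p)
    pool <- setdiff(pool, c(p - 1L, p, p + 1L))
  }
  sort(chosen)
}

#' Slice skipping
#'
#' Removes between 1 and `max_removed` randomly chosen, pairwise
#' non-adjacent interior slices from image and labels jointly, simulating a
#' larger effective slice spacing. Survivor order is preserved. With
#' `keep_count = TRUE` the stack is re-padded to its input slice count by
#' re-sampling from the survivors. Stacks too short to skip are returned
#' unchanged with a notice.
#'
#' @param stack A [slice_stack()].
#' @param max_removed Maximum slices to remove (0 = identity).
#' @param rng An [rng_stream()].
#' @param keep_count Re-pad to the input slice count.
#' @return The augmented `slice_stack`.
#' @export
slice_skip <- function(stack, max_removed = 2L, rng = rng_stream(1L),
                       keep_count = FALSE) {
  stopifnot(inherits(stack, "slice_stack"))
  if (max_removed <= 0L) return(stack)
  n <- dim(stack$slices)[1]
  if (n <= max_removed + 1L) {
    message("slice_skip: stack of ", n, " slices too short; skipped")
    return(stack)
  }
  k <- as.integer(rs_int(rng, 1L, 1L, max_removed))
  drop_idx <- .nonadjacent_interior(n, k, rng)
  keep <- setdiff(seq_len(n), drop_idx)
  if (keep_count && length(keep) < n) {
    extra <- rs_sample(rng, keep, n - length(keep), replace = TRUE)
    keep <- sort(c(keep, extra))
  }
  slice_stack(stack$slices[keep, , , drop = FALSE],
              if (!is.null(stack$label_slices)) stack$label_slices[keep, , , drop = FALSE],
              stack$source_indices[keep], fill_value = stack$fill_value)
}

#' Slice interpolation
#'
#' Inserts between 1 and `max_inserted` new slices; each inserted intensity
#' slice is the voxel-wise linear midpoint of a randomly chosen adjacent
#' pair, while the inserted label slice is a copy of one parent (no
#' fractional labels can appear). Source indices gain fractional positions.
#'
#' @param stack A [slice_stack()] with at least 2 slices.
#' @param max_inserted Maximum slices to insert (0 = identity).
#' @param rng An [rng_stream()].
#' @return The augmented `slice_stack`.
#' @export
slice_interpolate <- function(stack, max_inserted = 2L, rng = rng_stream(1L)) {
  stopifnot(inherits(stack, "slice_stack"))
  if (max_inserted <= 0L) return(stack)
  if (dim(stack$slices)[1] < 2L) stop("slice_interpolate needs >= 2 slices")
  k <- as.integer(rs_int(rng, 1L, 1L, max_inserted))
  sl <- stack$slices; lb <- stack$label_slices; src <- stack$source_indices
  for (j in seq_len(k)) {
    n <- dim(sl)[1]
    at <- as.integer(rs_int(rng, 1L, 1L, n - 1L))
    mid <- (sl[at, , , drop = FALSE] + sl[at + 1L, , , drop = FALSE]) / 2
    parent <- at + (rs_unif(rng, 1L) < 0.5)  # nearest-neighbour label: one parent
    ord <- c(seq_len(at), n + 1L, seq(at + 1L, n))
    sl <- (abind3(sl, mid))[ord, , , drop = FALSE]
    if (!is.null(lb)) lb <- (abind3(lb, lb[parent, , , drop = FALSE]))[ord, , , drop = FALSE]
    src <- c(src, (src[at] + src[at + 1L]) / 2)[ord]
  }
  slice_stack(sl, lb, src, fill_value = stack$fill_value)
}

# Bind a slice (1,H,W) onto a stack (n,H,W) along the first axis.
abind3 <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1] + dim(b)[1], d[2], d[3]))
  out[seq_len(d[1]), , ] <- a
  out[d[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' Additive Gaussian image noise
#'
#' Adds an independent zero-mean normal draw per voxel to the intensities;
#' labels are untouched.
#'
#' @param stack A [slice_stack()].
#' @param sigma Noise standard deviation (>= 0; 0 = identity).
#' @param rng An [rng_stream()].
#' @return The augmented `slice_stack`.
#' @export
gaussian_noise <- function(stack, sigma, rng = rng_stream(1L)) {
  stopifnot(inherits(stack, "slice_stack"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(stack)
  stack$slices <- stack$slices + array(rs_norm(rng, length(stack$slices), 0, sigma),
                                       dim(stack$slices))
  stack
}

# Rotate one 2D matrix by `theta` radians about its centre.
# Bilinear interpolation for intensities, nearest-neighbour for labels.
.rotate_plane <- function(m, theta, fill, nearest = FALSE) {
  h <- nrow(m); w <- ncol(m)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  gr <- matrix(seq_len(h), h, w) - cy
  gc <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  ct <- cos(theta); st <- sin(theta)
  sy <- cy + ct * gr + st * gc
  sx <- cx - st * gr + ct * gc
  if (nearest) {
    iy <- round(sy); ix <- round(sx)
    ok <- iy >= 1 & iy <= h & ix >= 1 & ix <= w
    out <- matrix(fill, h, w)
    out[ok] <- m[cbind(iy[ok], ix[ok])]
    return(out)
  }
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  gather <- function(yy, xx) {
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    g <- matrix(fill, h, w)
    g[ok] <- m[cbind(yy[ok], xx[ok])]
    g
  }
  gather(y0, x0) * (1 - fy) * (1 - fx) +
    gather(y0, x0 + 1) * (1 - fy) * fx +
    gather(y0 + 1, x0) * fy * (1 - fx) +
    gather(y0 + 1, x0 + 1) * fy * fx
}

#' Bounded random in-plane rotation
#'
#' Draws one angle in `[-max_deg, +max_deg]` per stack (a patient rotates
#' rigidly, so all slices share the angle) and rotates every slice in-plane.
#' Intensities are bilinearly interpolated; labels use nearest-neighbour so
#' the label value set never grows. Regions rotated in from outside the
#' frame are filled with the stack's background fill value and label 0.
#'
#' @param stack A [slice_stack()].
#' @param max_deg Rotation bound in degrees (0 = identity).
#' @param rng An [rng_stream()].
#' @return The augmented `slice_stack`.
#' @export
random_rotate <- function(stack, max_deg = 16, rng = rng_stream(1L)) {
  stopifnot(inherits(stack, "slice_stack"))
  if (max_deg < 0) stop("max_deg must be >= 0")
  if (max_deg == 0) return(stack)
  theta <- rs_unif(rng, 1L, -max_deg, max_deg) * pi / 180
  n <- dim(stack$slices)[1]
  for (i in seq_len(n)) {
    stack$slices[i, , ] <- .rotate_plane(stack$slices[i, , ], theta,
                                         fill = stack$fill_value)
    if (!is.null(stack$label_slices)) {
      stack$label_slices[i, , ] <- .rotate_plane(stack$label_slices[i, , ], theta,
                                                 fill = 0L, nearest = TRUE)
    }
  }
  stack
}

#' Random patch extraction
#'
#' Draws a single in-plane offset per stack and applies the identical
#' `patch_size` x `patch_size` crop to every image and label slice.
#'
#' @param stack A [slice_stack()].
#' @param patch_size Crop side (<= slice side; equal side = identity).
#' @param rng An [rng_stream()].
#' @return The cropped `slice_stack`.
#' @export
random_patch <- function(stack, patch_size, rng = rng_stream(1L)) {
  stopifnot(inherits(stack, "slice_stack"))
  d <- dim(stack$slices)
  if (patch_size > d[2] || patch_size > d[3]) {
    stop("patch_size ", patch_size, " exceeds slice size ", d[2], "x", d[3])
  }
  if (patch_size == d[2] && patch_size == d[3]) return(stack)
  oy <- as.integer(rs_int(rng, 1L, 0L, d[2] - patch_size))
  ox <- as.integer(rs_int(rng, 1L, 0L, d[3] - patch_size))
  ry <- oy + seq_len(patch_size); rx <- ox + seq_len(patch_size)
  slice_stack(stack$slices[, ry, rx, drop = FALSE],
              if (!is.null(stack$label_slices)) stack$label_slices[, ry, rx, drop = FALSE],
              stack$source_indices, fill_value = stack$fill_value)
}

#' Apply the CTIA policy to a training batch
#'
#' With probability `p_augment` the whole batch passes through the operator
#' chain in the fixed order rotation -> patch -> slice skip/interpolate ->
#' CWVRS -> noise (spatial before intensity, so intensity statistics are
#' defined on the final geometry); otherwise the batch is returned
#' untouched. CWVRS is additionally gated per volume at `p_cwvrs`. Skip and
#' interpolation are mutually exclusive per volume (a fair coin picks one
#' when both are enabled). The realised decision sequence is a pure function
#' of the rng state; the return value carries an `augmented` attribute.
#'
#' @param batch List of [slice_stack()] objects.
#' @param policy An [augment_policy()].
#' @param rng An [rng_stream()].
#' @param window_table A [intensity_window_table()], already on the scale of
#'   the stacks (transform with [transform_window_table()] after z-score
#'   normalisation).
#' @return List of augmented `slice_stack`s with attribute `augmented`.
#' @export
augment_batch <- function(batch, policy = augment_policy(), rng = rng_stream(1L),
                          window_table = intensity_window_table()) {
  stopifnot(inherits(policy, "augment_policy"))
  gate <- rs_unif(rng, 1L) < policy$p_augment
  if (!gate) {
    attr(batch, "augmented") <- FALSE
    return(batch)
  }
  out <- lapply(batch, function(stack) {
    stack <- random_rotate(stack, policy$max_rotation_deg, rng)
    if (!is.null(policy$patch_size)) stack <- random_patch(stack, policy$patch_size, rng)
    do_skip <- policy$skip_max > 0L
    do_interp <- policy$interp_max > 0L
    if (do_skip && do_interp) {
      if (rs_unif(rng, 1L) < 0.5) do_interp <- FALSE else do_skip <- FALSE
    }
    if (do_skip) {
      stack <- slice_skip(stack, policy$skip_max, rng, keep_count = policy$keep_slice_count)
    } else if (do_interp && dim(stack$slices)[1] >= 2L) {
      stack <- slice_interpolate(stack, policy$interp_max, rng)
    }
    if (rs_unif(rng, 1L) < policy$p_cwvrs) {
      stack <- cwvrs(stack, window_table, policy$cwvrs_max_shift_hu,
                     policy$cwvrs_max_scale_delta, rng)
    }
    gaussian_noise(stack, policy$noise_sigma, rng)
  })
  attr(out, "augmented") <- TRUE
  out
}
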