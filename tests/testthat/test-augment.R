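test_that("every CTIA operator is the identity at zero magnitude", {
  st <- ramp_stack()
  expect_identical(cwvrs(st, max_shift_hu = 0, max_scale_delta = 0,
                         rng = rng_stream(1)), st)
  expect_identical(slice_skip(st, max_removed = 0L, rng = rng_stream(1)), st)
  expect_identical(slice_interpolate(st, max_inserted = 0L, rng = rng_stream(1)), st)
  expect_identical(gaussian_noise(st, 0, rng_stream(1)), st)
  expect_identical(random_rotate(st, 0, rng_stream(1)), st)
  expect_identical(random_patch(st, dim(st$slices)[2], rng_stream(1)), st)
})

test_that("CWVRS remaps in-window voxels linearly and leaves the rest bit-identical", {
  side <- 10L
  ramp <- slice_stack(array(seq(0, 100, length.out = side^2), c(1, side, side)))
  tab <- intensity_window_table(data.frame(name = "w", lower = 0, upper = 100))

  # oracle: replicate the rng draws and apply the closed-form remap
  out <- cwvrs(ramp, tab, max_shift_hu = 10, max_scale_delta = 0, rng = rng_stream(77))
  shift <- rs_unif(rng_stream(77), 1L, -10, 10)
  expect_equal(out$slices, ramp$slices + shift, tolerance = 1e-12)

  # voxels outside every window are untouched exactly
  v <- array(c(-500, 50, 150, 3000), c(1, 2, 2))
  stk <- slice_stack(v)
  tab2 <- intensity_window_table(data.frame(name = "w", lower = 0, upper = 100))
  out2 <- cwvrs(stk, tab2, max_shift_hu = 20, max_scale_delta = 0.1,
                rng = rng_stream(5))
  expect_identical(out2$slices[1, 1, 1], v[1, 1, 1])   # -500: outside
  expect_identical(out2$slices[1, 1, 2], v[1, 1, 2])   #  150: outside
  expect_identical(out2$slices[1, 2, 2], v[1, 2, 2])   # 3000: outside
  expect_false(identical(out2$slices[1, 2, 1], v[1, 2, 1]))  # 50: in-window

  # labels never touched
  st <- ramp_stack()
  outl <- cwvrs(st, intensity_window_table(), 20, 0.1, rng_stream(3))
  expect_identical(outl$label_slices, st$label_slices)
})

test_that("slice skipping removes non-adjacent interior slices jointly", {
  for (trial in 1:100) {
    st <- ramp_stack(n = 8L, side = 8L)
    out <- slice_skip(st, max_removed = 3L, rng = rng_stream(trial))
    kept <- out$source_indices
    dropped <- setdiff(st$source_indices, kept)
    expect_gte(length(dropped), 1L)
    expect_lte(length(dropped), 3L)
    # interior and pairwise non-adjacent
    expect_false(1 %in% dropped)
    expect_false(8 %in% dropped)
    if (length(dropped) > 1) expect_gt(min(diff(sort(dropped))), 1)
    # survivors keep order and image/label pairing
    expect_false(is.unsorted(kept))
    for (j in seq_along(kept)) {
      expect_identical(out$slices[j, , ], st$slices[kept[j], , ])
      expect_identical(out$label_slices[j, , ], st$label_slices[kept[j], , ])
    }
  }

  # re-padding restores the input count from survivors only
  st <- ramp_stack(n = 8L, side = 8L)
  rp <- slice_skip(st, 3L, rng_stream(9), keep_count = TRUE)
  expect_identical(dim(rp$slices)[1], 8L)

  short <- ramp_stack(n = 3L, side = 8L)
  expect_message(out <- slice_skip(short, 3L, rng_stream(1)), "too short")
  expect_identical(out, short)
})

test_that("slice interpolation inserts parent midpoints with parent labels", {
  a <- array(0, c(1, 6, 6)); b <- array(2, c(1, 6, 6))
  st <- slice_stack(abind_test(a, b), abind_test(array(0L, c(1, 6, 6)), array(1L, c(1, 6, 6))))
  out <- slice_interpolate(st, 1L, rng_stream(4))
  expect_identical(dim(out$slices)[1], 3L)
  expect_true(all(out$slices[2, , ] == 1))
  expect_true(all(out$label_slices[2, , ] == 0L) || all(out$label_slices[2, , ] == 1L))
  expect_equal(out$source_indices, c(1, 1.5, 2))

  st2 <- ramp_stack(n = 4L)
  out2 <- slice_interpolate(st2, 3L, rng_stream(8))
  k <- dim(out2$slices)[1] - 4L
  expect_gte(k, 1L); expect_lte(k, 3L)
  # inserted label slices equal one of their neighbours exactly
  ins <- which(!(out2$source_indices %in% st2$source_indices))
  for (j in ins) {
    expect_true(identical(out2$label_slices[j, , ], out2$label_slices[j - 1L, , ]) ||
                identical(out2$label_slices[j, , ], out2$label_slices[j + 1L, , ]))
  }
})

test_that("Gaussian noise has the configured moments and spares labels", {
  st <- slice_stack(array(0, c(1, 128, 128)), array(1L, c(1, 128, 128)))
  out <- gaussian_noise(st, 5, rng_stream(12))
  diffs <- out$slices - st$slices
  expect_lt(abs(stats::sd(diffs) - 5), 0.2)
  expect_lt(abs(mean(diffs)), 3 * 5 / sqrt(length(diffs)))
  expect_identical(out$label_slices, st$label_slices)
  expect_error(gaussian_noise(st, -1, rng_stream(1)), "sigma")
})

test_that("rotation shares one angle per stack, preserves labels and area", {
  side <- 64L
  disk <- array(0L, c(2, side, side))
  cc <- (side + 1) / 2
  for (r in 1:side) for (c in 1:side) {
    if ((r - cc)^2 + (c - cc)^2 <= 20^2) disk[, r, c] <- 1L
  }
  st <- slice_stack(array(disk, c(2, side, side)) * 100, disk, fill_value = 0)
  out <- random_rotate(st, 16, rng_stream(21))
  expect_true(all(unique(as.vector(out$label_slices)) %in% c(0L, 1L)))
  a0 <- sum(st$label_slices[1, , ]); a1 <- sum(out$label_slices[1, , ])
  expect_lt(abs(a1 - a0) / a0, 0.02)
  # both slices rotated by the same angle
  expect_identical(out$label_slices[1, , ], out$label_slices[2, , ])
})

test_that("random patches crop image and labels with one shared offset", {
  st <- ramp_stack(n = 3L, side = 16L)
  out <- random_patch(st, 8L, rng_stream(15))
  expect_identical(dim(out$slices), c(3L, 8L, 8L))
  # oracle: recover the offset from the ramp values and check the full crop
  oy <- as.integer(out$slices[1, 1, 1]) %/% 16 + 1L
  ox <- as.integer(out$slices[1, 1, 1]) %% 16 + 1L
  expect_equal(out$slices, st$slices[, oy:(oy + 7L), ox:(ox + 7L), drop = FALSE])
  expect_equal(out$label_slices, st$label_slices[, oy:(oy + 7L), ox:(ox + 7L), drop = FALSE])
  expect_error(random_patch(st, 32L, rng_stream(1)), "exceeds")
})

test_that("batch gating honours p_augment and composes identities", {
  st <- ramp_stack(n = 4L, side = 8L)
  pol0 <- augment_policy(2L, p_augment = 0)
  out <- augment_batch(list(st), pol0, rng_stream(3))
  expect_identical(out[[1]], st)
  expect_false(attr(out, "augmented"))

  # p_augment = 1 with all magnitudes zeroed returns voxel-identical stacks
  polid <- augment_policy(2L, p_augment = 1, p_cwvrs = 1, max_rotation_deg = 0,
                          noise_sigma = 0, skip_max = 0L, interp_max = 0L,
                          cwvrs_max_shift_hu = 0, cwvrs_max_scale_delta = 0)
  outid <- augment_batch(list(st, st), polid, rng_stream(7))
  expect_identical(outid[[1]]$slices, st$slices)
  expect_identical(outid[[2]]$label_slices, st$label_slices)
  expect_true(attr(outid, "augmented"))

  # observed gate frequency tracks p_augment (the full 10k-trial check runs
  # in the acceptance suite)
  pol <- augment_policy(2L, p_augment = 0.9, max_rotation_deg = 0,
                        noise_sigma = 0, skip_max = 0L, interp_max = 0L,
                        cwvrs_max_shift_hu = 0, cwvrs_max_scale_delta = 0)
  rng <- rng_stream(42)
  hits <- sum(vapply(1:1000, function(i)
    attr(augment_batch(list(), pol, rng), "augmented"), logical(1)))
  expect_lt(abs(hits / 1000 - 0.9), 0.03)
})

test_that("augmented stacks preserve image/label pairing through the chain", {
  pol <- augment_policy(2L, p_augment = 1, p_cwvrs = 0.5, patch_size = 12L)
  for (trial in 1:20) {
    st <- ramp_stack(n = 6L, side = 16L)
    out <- augment_batch(list(st), pol, rng_stream(trial))[[1]]
    expect_identical(dim(out$slices), dim(out$label_slices))
    # no new label values
    expect_true(all(unique(as.vector(out$label_slices)) %in%
                    unique(as.vector(st$label_slices))))
  }
})
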