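# Independent sort-based linear-interpolation quantile oracle.
quantile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

test_that("window bounds equal sort-based interpolated percentiles", {
  vals <- as.numeric(1:1000)
  b <- compute_window_bounds(vals, window_spec(0.6, 0.99))
  expect_equal(unname(b), c(quantile_oracle(vals, 0.6), quantile_oracle(vals, 0.99)))

  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(257, sd = 300)
    p <- sort(runif(2))
    if (p[1] == p[2]) p[2] <- p[1] + 0.1
    spec <- window_spec(p[1], min(p[2], 1))
    b <- compute_window_bounds(x, spec)
    expect_equal(unname(b),
                 c(quantile_oracle(x, spec$lower_percentile),
                   quantile_oracle(x, spec$upper_percentile)))
  }

  expect_equal(unname(compute_window_bounds(rep(7, 50), window_spec())), c(7, 7))
  full <- compute_window_bounds(c(3, 9, 1), window_spec(0, 1))
  expect_equal(unname(full), c(1, 9))
  expect_error(compute_window_bounds(numeric(0)), "empty")
  expect_error(window_spec(0.9, 0.5), "lower_percentile")
})

test_that("windowing clamps voxel-wise, never widens, and is idempotent", {
  vol <- ct_volume(array(seq(-1000, 1000, length.out = 4 * 8 * 8), c(4, 8, 8)))
  w <- apply_window(vol, c(-150, 250))
  expect_true(all(w$intensities >= -150 & w$intensities <= 250))
  inside <- vol$intensities > -150 & vol$intensities < 250
  expect_equal(w$intensities[inside], vol$intensities[inside])
  expect_equal(apply_window(w, c(-150, 250))$intensities, w$intensities)
  # full-range bounds are the identity
  idw <- apply_window(vol, range(vol$intensities))
  expect_equal(idw$intensities, vol$intensities)
  expect_error(apply_window(vol, c(10, -10)), "exceeds")
})

test_that("z-normalisation matches pooled moments and flags units", {
  vol <- ct_volume(array(rnorm(4 * 8 * 8, 100, 40), c(4, 8, 8)))
  ident <- znormalize(vol, structure(list(mean = 0, std = 1), class = "norm_stats"))
  expect_equal(ident$intensities, vol$intensities)
  expect_equal(ident$units, "zscore")

  const <- ct_volume(array(5, c(2, 4, 4)))
  z <- znormalize(const, structure(list(mean = 5, std = 2), class = "norm_stats"))
  expect_true(all(z$intensities == 0))

  # normalising a cohort with its own pooled stats recentres it exactly
  vols <- lapply(1:5, function(i) ct_volume(array(rnorm(200, i * 10, 20), c(2, 10, 10))))
  st <- compute_norm_stats(vols)
  pooled <- unlist(lapply(vols, function(v) znormalize(v, st)$intensities))
  expect_lt(abs(mean(pooled)), 1e-9)
  expect_lt(abs(stats::sd(pooled) - 1), 1e-9)
})

test_that("pooled statistics match a flatten-and-moment oracle", {
  a <- ct_volume(array(0, c(2, 4, 4)))
  b <- ct_volume(array(2, c(2, 4, 4)))
  st <- compute_norm_stats(list(a, b))
  expect_equal(st$mean, 1)
  expect_equal(st$std, stats::sd(c(rep(0, 32), rep(2, 32))))
  expect_equal(st$n_cases_used, 2L)

  vols <- generate_cohort(5, tiny_phantom_config(), 3)
  wv <- lapply(vols, function(cs) cs$image)
  st2 <- compute_norm_stats(wv)
  flat <- unlist(lapply(wv, function(v) as.numeric(v$intensities)))
  expect_equal(st2$mean, mean(flat), tolerance = 1e-9)
  expect_equal(st2$std, stats::sd(flat), tolerance = 1e-9)

  expect_error(compute_norm_stats(list()), "at least one")
  expect_error(compute_norm_stats(list(ct_volume(array(3, c(2, 4, 4))))),
               "degenerate")
})

test_that("slice sampling honours count, candidates and background exclusion", {
  case <- generate_phantom(tiny_phantom_config(in_plane = 24L, slices = c(20L, 20L)), 13)
  fg <- which(apply(case$labels$classes > 0L, 1, any))
  bg <- setdiff(seq_len(20L), fg)
  expect_gt(length(bg), 0)

  # background never sampled when excluded (200 stacks here; the exhaustive
  # 1000-stack sweep runs in the acceptance suite)
  for (i in 1:200) {
    st <- sample_slices(case, n = 8L, exclude_background = TRUE, rng = rng_stream(i))
    expect_true(all(st$source_indices %in% fg))
    expect_false(is.unsorted(st$source_indices))
  }

  # n equal to candidate count selects each exactly once
  st <- sample_slices(case, n = length(fg), exclude_background = TRUE,
                      rng = rng_stream(1))
  expect_identical(sort(unique(st$source_indices)), as.numeric(fg))

  # replacement only when candidates are scarce
  st2 <- sample_slices(case, n = length(fg) + 5L, exclude_background = TRUE,
                       rng = rng_stream(2))
  expect_length(st2$source_indices, length(fg) + 5L)

  # fresh rng states give different stacks (simultaneous augmentation effect)
  s1 <- sample_slices(case, 8L, rng = rng_stream(100))
  s2 <- sample_slices(case, 8L, rng = rng_stream(101))
  expect_false(identical(s1$source_indices, s2$source_indices))

  nofg <- ct_case(case$image, label_volume(array(0L, dim(case$labels$classes))))
  expect_error(sample_slices(nofg, 4L, exclude_background = TRUE), "foreground")
})

test_that("downsampling averages areas for intensities and never invents labels", {
  st <- ramp_stack(n = 3L, side = 16L)
  ident <- downsample_stack(st, 16L)
  expect_identical(ident$slices, st$slices)

  ds <- downsample_stack(st, 8L)
  expect_identical(dim(ds$slices), c(3L, 8L, 8L))
  # integer-factor area averaging equals 2x2 block means
  blk <- st$slices[1, , ]
  expected <- 0.25 * (blk[seq(1, 15, 2), seq(1, 15, 2)] + blk[seq(2, 16, 2), seq(1, 15, 2)] +
                      blk[seq(1, 15, 2), seq(2, 16, 2)] + blk[seq(2, 16, 2), seq(2, 16, 2)])
  expect_equal(ds$slices[1, , ], expected)
  expect_true(all(unique(as.vector(ds$label_slices)) %in%
                  unique(as.vector(st$label_slices))))

  cst <- slice_stack(array(7, c(2, 16, 16)))
  expect_true(all(downsample_stack(cst, 8L)$slices == 7))

  bad <- slice_stack(array(0, c(2, 16, 12)))
  expect_error(downsample_stack(bad, 8L), "square")
})

test_that("the full chain yields the configured stack shape deterministically", {
  case <- generate_phantom(tiny_phantom_config(in_plane = 32L), 21)
  stats <- compute_norm_stats(list(case$image))
  out <- preprocess_case(case, window_spec(), stats, n_slices = 6L,
                         target_size = 16L, rng = rng_stream(5))
  expect_identical(dim(out$slices), c(6L, 16L, 16L))
  expect_identical(dim(out$label_slices), c(6L, 16L, 16L))

  again <- preprocess_case(case, window_spec(), stats, n_slices = 6L,
                           target_size = 16L, rng = rng_stream(5))
  expect_identical(out$slices, again$slices)

  # identity window + identity stats + full slice count + native size:
  # the output is a (sorted) slice selection of the input
  idstats <- structure(list(mean = 0, std = 1), class = "norm_stats")
  ns <- dim(case$image$intensities)[1]
  full <- preprocess_case(case, window_spec(0, 1), idstats, n_slices = ns,
                          target_size = 32L, exclude_background = FALSE,
                          rng = rng_stream(1))
  expect_equal(full$slices[order(full$source_indices), , ],
               case$image$intensities[sort(full$source_indices), , ])
})
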