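test_that("top-k selection is score-ordered and tie-stable", {
  models <- as.list(letters[1:5])
  expect_identical(select_top_k(models, c(0.9, 0.8, 0.7, 0.6, 0.5), 2L),
                   list("a", "b"))
  # ties: earlier training-completion order wins
  expect_identical(select_top_k(models, rep(0.5, 5), 3L), list("a", "b", "c"))
  # k = n returns all, sorted by score
  expect_identical(select_top_k(models, c(0.1, 0.5, 0.3, 0.2, 0.4), 5L),
                   list("b", "e", "c", "d", "a"))
  expect_error(select_top_k(models, rep(1, 5), 6L), "at least k")
})

test_that("mask_gate fuses consistent members into the multiclass map", {
  case <- generate_phantom(tiny_phantom_config(in_plane = 16L, slices = c(8L, 8L)), 6)
  stats <- compute_norm_stats(list(case$image))
  pm <- c(0.5, 0.3, 0.2)                       # multiclass member output
  mc <- constant_model(pm, dims = 2L)
  bin <- constant_model(c(pm[1], 1 - pm[1]), dims = 3L)  # B_fg = 1 - M_bg
  es <- ensemble_spec(list(bin), list(mc))
  out <- stacked_predict(es, case, window_spec(), stats, target_size = 16L,
                         n_slices = 8L)
  expect_equal(as.numeric(out$probs[1, 1, 1, ]), pm, tolerance = 1e-9)
  expect_lt(max(abs(apply(out$probs, 1:3, sum) - 1)), 1e-9)
})

test_that("zero binary foreground gates everything to background", {
  case <- generate_phantom(tiny_phantom_config(in_plane = 16L, slices = c(8L, 8L)), 6)
  stats <- compute_norm_stats(list(case$image))
  mc <- constant_model(c(0.2, 0.5, 0.3), dims = 2L)
  bin <- constant_model(c(1 - 1e-12, 1e-12), dims = 3L)
  es <- ensemble_spec(list(bin), list(mc))
  out <- stacked_predict(es, case, window_spec(), stats, target_size = 16L,
                         n_slices = 8L)
  expect_true(all(out$labels$classes == 0L))
})

test_that("averaging identical members is idempotent", {
  case <- generate_phantom(tiny_phantom_config(in_plane = 16L, slices = c(8L, 8L)), 6)
  stats <- compute_norm_stats(list(case$image))
  mc <- constant_model(c(0.2, 0.5, 0.3), dims = 2L)
  bin <- constant_model(c(0.4, 0.6), dims = 3L)
  one <- stacked_predict(ensemble_spec(list(bin), list(mc)), case,
                         window_spec(), stats, 16L, 8L)
  two <- stacked_predict(ensemble_spec(list(bin, bin), list(mc, mc)), case,
                         window_spec(), stats, 16L, 8L)
  expect_equal(one$probs, two$probs, tolerance = 1e-12)
})

test_that("prob_product fusion renormalises and respects the binary gate", {
  case <- generate_phantom(tiny_phantom_config(in_plane = 16L, slices = c(8L, 8L)), 6)
  stats <- compute_norm_stats(list(case$image))
  mc <- constant_model(c(0.2, 0.5, 0.3), dims = 2L)
  bin <- constant_model(c(0.4, 0.6), dims = 3L)
  es <- ensemble_spec(list(bin), list(mc), combiner = "prob_product")
  out <- stacked_predict(es, case, window_spec(), stats, 16L, 8L)
  expected <- c(0.2 * 0.4, 0.5 * 0.6, 0.3 * 0.6)
  expected <- expected / sum(expected)
  expect_equal(as.numeric(out$probs[2, 3, 4, ]), expected, tolerance = 1e-9)
})

test_that("the experiment grid emits a complete, deterministic table", {
  cohort <- generate_cohort(6, tiny_phantom_config(in_plane = 16L, slices = c(6L, 10L)), 12)
  folds <- assign_folds(cohort, 2L)
  cfg <- train_config(dims = 2L, batch_size = 4L, epochs = 1L, steps_per_epoch = 2L,
                      n_slices = 4L, target_size = 16L, seed = 9L)
  specs <- list(unet2d = model_spec("unet", 2L, 3L, depth = 1L, base_width = 2L))
  regimes <- list(ctia = augment_policy(2L), none = NULL)
  tbl <- run_experiment_grid(cohort, regimes, specs, folds, cfg)
  expect_s3_class(tbl, "robustness_table")
  expect_true(all(tbl$status == "ok"))
  expect_setequal(unique(tbl$regime), c("ctia", "none"))
  expect_true(all(c("1", "2", "total") %in% tbl$class))
  expect_true(all(tbl$mean_dice >= 0 & tbl$mean_dice <= 1))
  expect_true(all(tbl$sd_dice >= 0))
  tbl2 <- run_experiment_grid(cohort, regimes, specs, folds, cfg)
  expect_equal(as.data.frame(tbl), as.data.frame(tbl2))
  expect_false(is.null(attr(tbl, "scores")))
})
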