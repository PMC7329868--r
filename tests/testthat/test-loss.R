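test_that("loss identities hold exactly", {
  inst <- random_instance(1, V = 50L)
  y <- inst$truth
  # perfect prediction: zero Tanimoto loss in every class
  expect_equal(tanimoto_loss(y, y), 0)
  # class absent from pred and truth contributes 0 via smooth/smooth
  y2 <- array(0, c(10, 3)); y2[, 1] <- 1
  expect_equal(tanimoto_loss(y2, y2), 0)
  # degenerate weights reduce the compound loss to its parts
  expect_equal(combined_loss(inst$pred, y, loss_config(alpha = 1, beta = 0)),
               tanimoto_loss(inst$pred, y))
  expect_equal(combined_loss(inst$pred, y, loss_config(alpha = 0, beta = 1)),
               categorical_crossentropy(inst$pred, y))
  # uniform prediction: crossentropy is ln C
  unif <- array(1 / 3, c(20, 3))
  expect_equal(categorical_crossentropy(unif, inst$truth[1:20, , drop = FALSE]),
               log(3))
  # total mismatch on a single voxel
  p1 <- array(c(1, 0), c(1, 2)); t1 <- array(c(0, 1), c(1, 2))
  s <- 1e-5
  # per class: inner product 0, |p|^2 + |y|^2 = 1, so loss = 1 - s/(1 + s)
  expect_equal(tanimoto_loss(p1, t1, s), 1 - s / (1 + s), tolerance = 1e-12)
  expect_error(tanimoto_loss(array(0, c(2, 2)), array(0, c(3, 2))), "differ")
})

test_that("vectorised losses match brute-force voxel loops to 1e-12", {
  for (seed in 1:20) {
    inst <- random_instance(seed)
    expect_equal(tanimoto_loss(inst$pred, inst$truth),
                 tanimoto_oracle(inst$pred_m, inst$truth_m, 1e-5),
                 tolerance = 1e-12)
    expect_equal(categorical_crossentropy(inst$pred, inst$truth),
                 crossentropy_oracle(inst$pred_m, inst$truth_m),
                 tolerance = 1e-12)
    expect_equal(combined_loss(inst$pred, inst$truth),
                 0.6 * tanimoto_oracle(inst$pred_m, inst$truth_m, 1e-5) +
                   0.4 * crossentropy_oracle(inst$pred_m, inst$truth_m),
                 tolerance = 1e-12)
  }
})

test_that("Dice matches its oracle and the Tanimoto relation T = D/(2-D)", {
  set.seed(7)
  for (i in 1:20) {
    a <- array(sample(0:2, 200, TRUE), c(8, 5, 5))
    b <- array(sample(0:2, 200, TRUE), c(8, 5, 5))
    for (cl in 0:2) {
      expect_equal(as.numeric(dice_score(a, b, cl)), dice_oracle(a, b, cl),
                   tolerance = 1e-12)
    }
    # binary mask relation between the two overlap measures
    am <- as.integer(a == 1); bm <- as.integer(b == 1)
    pred <- cbind(1 - am, am); truth <- cbind(1 - bm, bm)
    tan_fg <- {
      inner <- sum(am * bm)
      1 - (inner + 1e-12) / (sum(am^2) + sum(bm^2) - inner + 1e-12)
    }
    d <- dice_oracle(a, b, 1)
    expect_equal(1 - tan_fg, d / (2 - d), tolerance = 1e-6)
  }
  # symmetry and fixed cases
  expect_equal(as.numeric(dice_score(array(1L, c(1, 2, 1)), array(1L, c(1, 2, 1)), 1)), 1)
  one <- array(c(1L, 0L), c(1, 2, 1)); two <- array(c(0L, 1L), c(1, 2, 1))
  expect_equal(as.numeric(dice_score(one, two, 1)), 0)
  p <- array(c(1L, 1L, 0L, 0L), c(1, 4, 1)); q <- array(c(1L, 0L, 1L, 0L), c(1, 4, 1))
  expect_equal(as.numeric(dice_score(p, q, 1)), 0.5)
  expect_equal(as.numeric(dice_score(p, q, 1)), as.numeric(dice_score(q, p, 1)))
  # absent class: 0/0 convention flagged
  none <- dice_score(array(0L, c(1, 2, 2)), array(0L, c(1, 2, 2)), 2)
  expect_equal(as.numeric(none), 1)
  expect_true(attr(none, "both_empty"))
})

test_that("aggregation reproduces a spreadsheet-style oracle", {
  tab <- data.frame(fold = rep(0:1, each = 4),
                    volume = rep(c("a", "b"), 4),
                    class = rep(rep(1:2, each = 2), 2),
                    score = c(0.9, 1.0, 0.8, 0.6, 0.7, 0.9, 0.5, 0.7))
  rep_ <- aggregate_dice(tab)
  expect_equal(rep_$pooled$mean[rep_$pooled$class == "1"], mean(c(0.9, 1, 0.7, 0.9)))
  expect_equal(rep_$pooled$sd[rep_$pooled$class == "1"], sd(c(0.9, 1, 0.7, 0.9)))
  # two-level: volumes within fold first, then across folds
  f0 <- mean(c(0.9, 1)); f1 <- mean(c(0.7, 0.9))
  expect_equal(rep_$two_level$mean[rep_$two_level$class == "1"], mean(c(f0, f1)))
  expect_equal(rep_$two_level$sd[rep_$two_level$class == "1"], sd(c(f0, f1)))
  # total = class-average per volume
  tot_a0 <- mean(c(0.9, 0.8))
  expect_true(any(abs(rep_$pooled$mean[rep_$pooled$class == "total"] -
                      mean(c(tot_a0, mean(c(1, 0.6)), mean(c(0.7, 0.5)),
                             mean(c(0.9, 0.7))))) < 1e-12))

  same <- data.frame(fold = 0, volume = c("a", "b"), class = 1, score = 0.5)
  r2 <- aggregate_dice(same)
  expect_equal(r2$pooled$sd[r2$pooled$class == "1"], 0)
  two <- data.frame(fold = 0, volume = c("a", "b"), class = 1, score = c(0.9, 1.0))
  expect_equal(aggregate_dice(two)$pooled$mean[1], 0.95)
  expect_error(aggregate_dice(data.frame()), "non-empty")

  # seeded random table against an independent split-apply oracle
  set.seed(11)
  big <- data.frame(fold = sample(0:2, 60, TRUE), volume = sample(letters[1:5], 60, TRUE),
                    class = sample(1:2, 60, TRUE), score = runif(60))
  rb <- aggregate_dice(big)
  for (cl in c("1", "2")) {
    sub <- big[big$class == cl, ]
    expect_equal(rb$pooled$mean[rb$pooled$class == cl], mean(sub$score), tolerance = 1e-12)
    pf <- tapply(sub$score, sub$fold, mean)
    expect_equal(rb$two_level$mean[rb$two_level$class == cl], mean(pf), tolerance = 1e-12)
    expect_equal(rb$two_level$sd[rb$two_level$class == cl], sd(pf), tolerance = 1e-12)
  }
})

test_that("loss decreases along the path from uniform to the truth", {
  inst <- random_instance(3, V = 200L)
  unif <- array(1 / 3, dim(inst$truth))
  vals <- vapply(seq(0, 1, length.out = 11), function(t) {
    combined_loss(unif * (1 - t) + inst$truth * t + 1e-9, inst$truth)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("analytic logit gradient matches numerical differentiation", {
  # 2-voxel instance, central differences at 1e-4 tolerance
  set.seed(9)
  logits <- matrix(rnorm(2 * 3), 2, 3)
  truth <- matrix(0, 2, 3); truth[1, 2] <- 1; truth[2, 3] <- 1
  r <- ctseg:::combined_loss_grad_logits(logits, truth)
  h <- 1e-6
  for (i in 1:2) for (j in 1:3) {
    lp <- logits; lp[i, j] <- lp[i, j] + h
    lm <- logits; lm[i, j] <- lm[i, j] - h
    num <- (ctseg:::combined_loss_grad_logits(lp, truth)$loss -
            ctseg:::combined_loss_grad_logits(lm, truth)$loss) / (2 * h)
    expect_lt(abs(num - r$grad[i, j]), 1e-4)
  }
})
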