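# Stacked ensembling: top-k model selection, fusion of a set of 3D binary
# localisers with a set of 2D multi-class classifiers, and the grid
# experiment comparing augmentation regimes across architectures.

#' Select the top-k models by validation score
#'
#' Ties are broken by input (training-completion) order, so selection is
#' deterministic.
#'
#' @param models List of candidate models.
#' @param scores Numeric validation score per candidate.
#' @param k Number to keep (default 5).
#' @return The k highest-scoring models, score-sorted.
#' @export
select_top_k <- function(models, scores, k = 5L) {
  stopifnot(length(models) == length(scores))
  if (length(models) < k) {
    stop("need at least k = ", k, " candidates, got ", length(models))
  }
  ord <- order(-scores, seq_along(scores))
  models[ord[seq_len(k)]]
}

#' Specify a stacked ensemble
#'
#' Combines a set of 3D MS-D networks trained for binary foreground
#' localisation with a set of 2D U-Nets trained for fine multi-class
#' classification. Within each set, member probability maps are averaged
#' voxel-wise; the combiner then fuses the binary foreground probability B
#' with the multi-class map M:
#' * `mask_gate` (default, no extra training): final background probability
#'   is `max(M_bg, 1 - B)`; the remaining foreground mass is distributed
#'   over the foreground classes proportionally to M.
#' * `prob_product`: class-wise product fusion treating B as
#'   (background, foreground), then renormalised.
#' * `meta_learner`: a per-voxel multinomial combiner fitted on validation
#'   data with [fit_meta_combiner()].
#'
#' @param binary_members List of trained 3D models (C = 2).
#' @param multiclass_members List of trained 2D models.
#' @param combiner One of `"mask_gate"`, `"prob_product"`, `"meta_learner"`.
#' @param meta_model Fitted combiner (required for `meta_learner`).
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(binary_members, multiclass_members,
                          combiner = c("mask_gate", "prob_product", "meta_learner"),
                          meta_model = NULL) {
  combiner <- match.arg(combiner)
  if (length(binary_members) == 0L || length(multiclass_members) == 0L) {
    stop("both member sets must be non-empty")
  }
  if (combiner == "meta_learner" && is.null(meta_model)) {
    stop("meta_learner combiner requires a fitted meta_model")
  }
  structure(list(binary_members = binary_members,
                 multiclass_members = multiclass_members,
                 combiner = combiner, meta_model = meta_model),
            class = "ensemble_spec")
}

# Voxel-wise average of member probability maps on a case.
.member_mean_probs <- function(members, case, window, stats, target_size, n_slices) {
  acc <- NULL
  for (m in members) {
    p <- predict_volume(m, case, window, stats, target_size, n_slices)$probs
    acc <- if (is.null(acc)) p else acc + p
  }
  acc / length(members)
}

#' Stacked ensemble prediction on one case
#'
#' @param spec An [ensemble_spec()].
#' @param case A `ct_case`.
#' @param window A [window_spec()].
#' @param stats Training `norm_stats` shared by the members.
#' @param target_size Working in-plane size shared by all members.
#' @param n_slices Slab depth for the 3D members.
#' @return List with `probs` (fused map, `(slices, t, t, C)`) and `labels`
#'   (native in-plane resolution).
#' @export
stacked_predict <- function(spec, case, window = window_spec(), stats,
                            target_size, n_slices = 16L) {
  stopifnot(inherits(spec, "ensemble_spec"))
  B <- .member_mean_probs(spec$binary_members, case, window, stats,
                          target_size, n_slices)
  M <- .member_mean_probs(spec$multiclass_members, case, window, stats,
                          target_size, n_slices)
  if (!identical(dim(B)[1:3], dim(M)[1:3])) {
    stop("member outputs disagree on working resolution: ",
         paste(dim(B)[1:3], collapse = "x"), " vs ", paste(dim(M)[1:3], collapse = "x"))
  }
  C <- dim(M)[4]
  d <- dim(M)
  V <- prod(d[1:3])
  b_fg <- as.numeric(B[, , , 2])
  Mm <- matrix(M, V, C)
  out <- switch(spec$combiner,
    mask_gate = {
      bg <- pmax(Mm[, 1], 1 - b_fg)
      fg_total <- 1 - bg
      m_fg_sum <- 1 - Mm[, 1]
      ratio <- ifelse(m_fg_sum > 0, fg_total / m_fg_sum, 0)
      cbind(bg, Mm[, -1, drop = FALSE] * ratio)
    },
    prob_product = {
      fused <- cbind(Mm[, 1] * (1 - b_fg), Mm[, -1, drop = FALSE] * b_fg)
      s <- rowSums(fused)
      bad <- s <= 0
      fused[bad, ] <- Mm[bad, , drop = FALSE]  # degenerate voxel: fall back to M
      fused / rowSums(fused)
    },
    meta_learner = {
      feats <- data.frame(b = b_fg, Mm)
      names(feats) <- c("b", paste0("m", seq_len(C)))
      pr <- stats::predict(spec$meta_model, newdata = feats, type = "probs")
      if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)
      pr
    })
  probs <- array(out, c(d[1:3], C))
  lab_small <- array(max.col(matrix(probs, ncol = C), ties.method = "first") - 1L, d[1:3])
  lab_native <- .resize_nn_stack(lab_small, dim(case$image$intensities)[2])
  list(probs = probs, labels = label_volume(lab_native,
       class_names = c("background", paste0("class", seq_len(C - 1L)))))
}

#' Fit the trainable per-voxel combiner on validation cases
#'
#' Learns a multinomial model mapping the per-voxel ensemble features
#' (binary foreground probability, multi-class member average) to the true
#' class — the literal "learn to balance the member strengths" reading of
#' stacking. Voxels are subsampled for tractability.
#'
#' @param binary_members,multiclass_members Member model lists.
#' @param cases Labelled validation cases.
#' @param window,stats,target_size,n_slices Shared preprocessing context.
#' @param n_voxels Voxels to subsample across cases.
#' @param seed Subsampling seed.
#' @return A fitted combiner usable as `meta_model` in [ensemble_spec()].
#' @export
fit_meta_combiner <- function(binary_members, multiclass_members, cases,
                              window = window_spec(), stats, target_size,
                              n_slices = 16L, n_voxels = 20000L, seed = 1L) {
  rng <- rng_stream(seed)
  feats <- list(); labs <- list()
  for (case in cases) {
    B <- .member_mean_probs(binary_members, case, window, stats, target_size, n_slices)
    M <- .member_mean_probs(multiclass_members, case, window, stats, target_size, n_slices)
    C <- dim(M)[4]
    V <- prod(dim(M)[1:3])
    truth <- .resize_nn_stack(case$labels$classes, target_size)
    take <- rs_sample(rng, seq_len(V), min(n_voxels %/% length(cases), V))
    f <- data.frame(b = as.numeric(B[, , , 2])[take],
                    matrix(M, V, C)[take, , drop = FALSE])
    names(f) <- c("b", paste0("m", seq_len(C)))
    feats[[length(feats) + 1L]] <- f
    labs[[length(labs) + 1L]] <- as.integer(truth)[take]
  }
  df <- do.call(rbind, feats)
  df$y <- factor(unlist(labs), levels = sort(unique(unlist(labs))))
  nnet::multinom(y ~ ., data = df, trace = FALSE)
}

#' Train/evaluate a grid of augmentation regimes and architectures
#'
#' For every combination of augmentation regime, model specification and
#' cross-validation fold: trains on the out-of-fold cases, predicts the
#' in-fold cases (optionally after a global intensity perturbation of the
#' test images, to probe robustness to vendor shifts), scores volume-wise
#' Dice per class, and aggregates. The whole grid is a pure function of the
#' seeds. A failed cell is marked and the grid continues.
#'
#' @param cohort List of labelled `ct_case`.
#' @param regimes Named list of [augment_policy()] (or `NULL` entries for
#'   no augmentation).
#' @param specs Named list of [model_spec()].
#' @param folds A [assign_folds()] result.
#' @param config A [train_config()] template (its `policy` is replaced per
#'   regime, its `seed` fanned out per cell).
#' @param test_perturb Optional `list(shift_hu =, scale =)` applied to test
#'   cases before prediction.
#' @return An object of class `robustness_table`: data frame with columns
#'   `regime, architecture, dims, class, mean_dice, sd_dice, status`, with
#'   the per-volume scores in `attr(, "scores")`.
#' @export
run_experiment_grid <- function(cohort, regimes, specs, folds, config,
                                test_perturb = NULL) {
  stopifnot(length(regimes) >= 1L, length(specs) >= 1L)
  ids <- vapply(cohort, function(x) x$id, character(1))
  rows <- list(); all_scores <- list()
  for (ri in seq_along(regimes)) {
    for (si in seq_along(specs)) {
      regime_name <- names(regimes)[ri]
      spec_name <- names(specs)[si]
      spec <- specs[[si]]
      scores <- NULL
      status <- "ok"
      for (fold in sort(unique(folds$fold))) {
        res <- tryCatch({
          test_ids <- folds$id[folds$fold == fold]
          train_cases <- cohort[!(ids %in% test_ids)]
          test_cases <- cohort[ids %in% test_ids]
          cfg <- config
          cfg$policy <- regimes[[ri]]
          cfg$dims <- spec$dims
          cfg$seed <- derive_seed(config$seed, ri * 1000L + si * 100L + fold)
          model <- build_model(spec, seed = cfg$seed)
          tr <- train(model, train_cases, cfg)
          if (!is.null(test_perturb)) {
            test_cases <- perturb_cohort(test_cases, test_perturb$shift_hu %||% 0,
                                         test_perturb$scale %||% 1)
          }
          fold_scores <- list()
          for (case in test_cases) {
            pred <- predict_volume(tr$model, case, cfg$window, tr$stats,
                                   cfg$target_size, cfg$n_slices)
            for (cl in seq_len(spec$num_classes - 1L)) {
              fold_scores[[length(fold_scores) + 1L]] <- data.frame(
                fold = fold, volume = case$id, class = cl,
                score = as.numeric(dice_score(pred$labels, case$labels, cl)))
            }
          }
          do.call(rbind, fold_scores)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          status <- paste0("failed: ", conditionMessage(res))
          break
        }
        scores <- rbind(scores, res)
      }
      if (!is.null(scores) && status == "ok") {
        for (cl in sort(unique(scores$class))) {
          sc <- scores$score[scores$class == cl]
          rows[[length(rows) + 1L]] <- data.frame(
            regime = regime_name, architecture = spec$family, dims = spec$dims,
            class = cl, mean_dice = mean(sc),
            sd_dice = if (length(sc) > 1) stats::sd(sc) else 0,
            status = status)
        }
        pervol <- stats::aggregate(score ~ fold + volume, scores, mean)
        rows[[length(rows) + 1L]] <- data.frame(
          regime = regime_name, architecture = spec$family, dims = spec$dims,
          class = "total", mean_dice = mean(pervol$score),
          sd_dice = if (nrow(pervol) > 1) stats::sd(pervol$score) else 0,
          status = status)
        scores$regime <- regime_name; scores$architecture <- spec$family
        all_scores[[length(all_scores) + 1L]] <- scores
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          regime = regime_name, architecture = spec$family, dims = spec$dims,
          class = NA_character_, mean_dice = NA_real_, sd_dice = NA_real_,
          status = status)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scores") <- if (length(all_scores)) do.call(rbind, all_scores) else NULL
  class(out) <- c("robustness_table", "data.frame")
  out
}
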