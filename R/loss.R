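# Compound segmentation loss (smoothed Tanimoto + categorical crossentropy)
# and Dice evaluation with volume-wise mean +/- std aggregation.
#
# Probability maps are arrays whose LAST axis indexes the C classes; one-hot
# truth arrays share the same layout. Voxel-wise probabilities must be
# non-negative and sum to 1.

.as_class_matrix <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array with a trailing class axis")
  matrix(x, nrow = prod(d[-length(d)]), ncol = d[length(d)])
}

.check_pair <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop("prediction shape (", paste(dim(pred), collapse = "x"),
         ") and truth shape (", paste(dim(truth), collapse = "x"), ") differ")
  }
}

#' One-hot encode an integer label array
#'
#' @param labels Integer array of class ids `0..C-1`.
#' @param num_classes C.
#' @return Array with an appended class axis of length C.
#' @export
one_hot <- function(labels, num_classes) {
  d <- dim(labels) %||% length(labels)
  out <- array(0, c(d, num_classes))
  m <- matrix(out, nrow = prod(d), ncol = num_classes)
  m[cbind(seq_len(prod(d)), as.integer(labels) + 1L)] <- 1
  array(m, c(d, num_classes))
}

#' Smoothed Tanimoto loss
#'
#' Per class c, with inner product `I = sum(p_c * y_c)` and squared norms
#' `P = sum(p_c^2)`, `Y = sum(y_c^2)`:
#' `L_c = 1 - (I + smooth) / (P + Y - I + smooth)`,
#' averaged unweighted over classes. Treating each class independently makes
#' the loss suitable for the high class imbalance typical of medical
#' segmentation; a class absent from both prediction and truth would
#' otherwise yield a maximal error, which the small smoothing constant
#' attenuates (the absent-class term becomes smooth/smooth = 1, i.e. zero
#' loss).
#'
#' @param pred Probability array, classes on the last axis.
#' @param truth One-hot truth of identical shape.
#' @param smooth Smoothing constant (> 0), default `1e-5`.
#' @return Scalar loss in `[0, 1]`.
#' @export
tanimoto_loss <- function(pred, truth, smooth = 1e-5) {
  .check_pair(pred, truth)
  if (smooth <= 0) stop("smooth must be > 0")
  P <- .as_class_matrix(pred); Y <- .as_class_matrix(truth)
  I <- colSums(P * Y)
  den <- colSums(P * P) + colSums(Y * Y) - I
  mean(1 - (I + smooth) / (den + smooth))
}

#' Categorical crossentropy
#'
#' Mean over voxels of `-log p(true class)`, with probabilities clamped to
#' `[epsilon, 1]` for log stability.
#'
#' @param pred Probability array, classes on the last axis.
#' @param truth One-hot truth of identical shape.
#' @param epsilon Clamp constant, default `1e-12`.
#' @return Scalar loss (>= 0).
#' @export
categorical_crossentropy <- function(pred, truth, epsilon = 1e-12) {
  .check_pair(pred, truth)
  P <- .as_class_matrix(pred); Y <- .as_class_matrix(truth)
  p_true <- rowSums(P * Y)
  mean(-log(clamp(p_true, epsilon, 1)))
}

#' Compound loss configuration
#'
#' @param alpha Weight of the Tanimoto term (default 0.6).
#' @param beta Weight of the crossentropy term (default 0.4).
#' @param smooth Tanimoto smoothing constant (default 1e-5).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.6, beta = 0.4, smooth = 1e-5) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  if (smooth <= 0) stop("smooth must be > 0")
  structure(list(alpha = alpha, beta = beta, smooth = smooth),
            class = "loss_config")
}

#' Weighted Tanimoto + crossentropy loss
#'
#' `alpha * L_Tanimoto + beta * L_CE`.
#'
#' @param pred Probability array, classes on the last axis.
#' @param truth One-hot truth of identical shape.
#' @param config A [loss_config()].
#' @return Scalar loss.
#' @export
combined_loss <- function(pred, truth, config = loss_config()) {
  config$alpha * tanimoto_loss(pred, truth, config$smooth) +
    config$beta * categorical_crossentropy(pred, truth)
}

#' Dice overlap score for one class
#'
#' With binary indicator volumes for `class_id`,
#' `s = 2 * sum(a * b) / (sum(a^2) + sum(b^2))`. When the class is absent
#' from both volumes the score is defined as 1 (0/0 convention); callers can
#' detect this via the `"both_empty"` attribute and exclude such volumes.
#'
#' @param pred_labels Predicted [label_volume()] or integer array.
#' @param truth_labels Ground-truth [label_volume()] or integer array.
#' @param class_id Class to score.
#' @return Scalar in `[0, 1]` with attribute `both_empty`.
#' @export
dice_score <- function(pred_labels, truth_labels, class_id) {
  a <- if (inherits(pred_labels, "label_volume")) pred_labels$classes else pred_labels
  b <- if (inherits(truth_labels, "label_volume")) truth_labels$classes else truth_labels
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b))) {
    stop("prediction and truth shapes differ")
  }
  ai <- a == class_id; bi <- b == class_id
  num <- 2 * sum(ai & bi)
  den <- sum(ai) + sum(bi)
  out <- if (den == 0) 1 else num / den
  attr(out, "both_empty") <- den == 0
  out
}

#' Aggregate volume-wise Dice scores into a report
#'
#' Input is a long-format table with columns `fold`, `volume`, `class`,
#' `score` (one row per volume and class). Two aggregations are computed per
#' class and for the class-averaged total:
#' * two-level (the headline): mean over volumes within each fold, then mean
#'   and standard deviation over folds;
#' * pooled: mean and standard deviation over all volumes directly.
#'
#' @param scores Data frame `(fold, volume, class, score)`.
#' @return An object of class `dice_report` with components `two_level`,
#'   `pooled` (data frames `class, mean, sd, n`) and `raw`.
#' @export
aggregate_dice <- function(scores) {
  if (!is.data.frame(scores) || nrow(scores) == 0L) {
    stop("scores must be a non-empty data frame")
  }
  stopifnot(all(c("fold", "volume", "class", "score") %in% names(scores)))
  if (any(scores$score < 0 | scores$score > 1)) stop("Dice scores must lie in [0, 1]")

  # per-volume class-average gives the "total" rows
  tot <- stats::aggregate(score ~ fold + volume, scores, mean)
  tot$class <- "total"
  long <- rbind(scores[c("fold", "volume", "class", "score")],
                tot[c("fold", "volume", "class", "score")])
  long$class <- as.character(long$class)

  pooled <- do.call(rbind, lapply(split(long, long$class), function(d) {
    data.frame(class = d$class[1], mean = mean(d$score),
               sd = if (nrow(d) > 1) stats::sd(d$score) else 0,
               n = nrow(d))
  }))
  per_fold <- stats::aggregate(score ~ fold + class, long, mean)
  two_level <- do.call(rbind, lapply(split(per_fold, per_fold$class), function(d) {
    data.frame(class = d$class[1], mean = mean(d$score),
               sd = if (nrow(d) > 1) stats::sd(d$score) else 0,
               n = nrow(d))
  }))
  rownames(pooled) <- rownames(two_level) <- NULL
  structure(list(two_level = two_level, pooled = pooled, raw = scores),
            class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat("<dice_report> mean +/- sd over folds (volumes within fold averaged first):\n")
  for (i in seq_len(nrow(x$two_level))) {
    cat(sprintf("  %-10s %.3f +/- %.3f  (n folds = %d)\n",
                x$two_level$class[i], x$two_level$mean[i],
                x$two_level$sd[i], x$two_level$n[i]))
  }
  invisible(x)
}

#' Write a Dice report to CSV and JSON
#'
#' @param report A [aggregate_dice()] result.
#' @param csv_path Long-format per-volume scores destination.
#' @param json_path Summary (two-level and pooled aggregates) destination.
#' @export
write_dice_report <- function(report, csv_path, json_path = NULL) {
  stopifnot(inherits(report, "dice_report"))
  utils::write.csv(report$raw, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(two_level = report$two_level, pooled = report$pooled),
                         json_path, dataframe = "rows", digits = NA, auto_unbox = TRUE)
  }
  invisible(NULL)
}

# Analytic gradient of the compound loss with respect to pre-softmax logits.
# Used by the training loop; verified against numerical differentiation in
# the test suite. `logits` and `truth` are (V x C) matrices.
combined_loss_grad_logits <- function(logits, truth_m, config = loss_config()) {
  V <- nrow(logits); C <- ncol(logits)
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)

  # Tanimoto term: dL_c/dp = -(y*D - N*(2p - y)) / D^2, averaged over classes
  I <- colSums(p * truth_m)
  Pq <- colSums(p * p); Yq <- colSums(truth_m * truth_m)
  num <- I + config$smooth
  den <- Pq + Yq - I + config$smooth
  gt <- -(truth_m * rep(den, each = V) - (2 * p - truth_m) * rep(num, each = V)) /
    rep(den^2, each = V) / C

  # crossentropy term: mean over voxels of -log p_true
  eps <- 1e-12
  p_true <- rowSums(p * truth_m)
  gc_ <- -truth_m / pmax(p_true, eps) / V

  g <- config$alpha * gt + config$beta * gc_
  # chain through the softmax Jacobian: dz = p * (g - sum(g * p))
  dz <- p * (g - rowSums(g * p))
  loss <- config$alpha * (mean(1 - num / den)) +
    config$beta * mean(-log(clamp(p_true, eps, 1)))
  list(loss = loss, grad = dz, probs = p)
}
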