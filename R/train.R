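# Training loop (batch sampling -> preprocessing -> CTIA augmentation ->
# forward -> compound loss -> ADAM update), slice-count-sorted fold
# assignment, and volume-wise inference.

#' Training configuration
#'
#' Defaults follow the training protocol: batch size 28 for 2D networks
#' (units are slices) and 1 for 3D (units are volumes), ADAM with the
#' standard proposed parameters (learning rate 1e-3, beta1 0.9, beta2
#' 0.999), the compound Tanimoto/crossentropy loss at alpha 0.6 / beta 0.4,
#' and the CTIA policy for the chosen dimensionality. An epoch is a fixed
#' number of batches, since volumes are sampled with replacement.
#'
#' @param dims 2 or 3.
#' @param batch_size Gradient-step batch size (slices in 2D, volumes in 3D).
#' @param epochs,steps_per_epoch Training length.
#' @param lr,beta1,beta2 ADAM parameters.
#' @param loss A [loss_config()].
#' @param policy An [augment_policy()]; `NULL` disables augmentation.
#' @param window A [window_spec()].
#' @param n_slices Slices sampled per volume (default 16).
#' @param target_size Working in-plane side (default 128).
#' @param seed Master seed for all training stochasticity.
#' @return An object of class `train_config`.
#' @export
train_config <- function(dims = 2L,
                         batch_size = if (dims == 2L) 28L else 1L,
                         epochs = 1L, steps_per_epoch = 100L,
                         lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         loss = loss_config(),
                         policy = augment_policy(dims),
                         window = window_spec(),
                         n_slices = 16L, target_size = 128L,
                         seed = 1L) {
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(dims = as.integer(dims), batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), steps_per_epoch = as.integer(steps_per_epoch),
                 lr = lr, beta1 = beta1, beta2 = beta2, loss = loss,
                 policy = policy, window = window,
                 n_slices = as.integer(n_slices), target_size = as.integer(target_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Assign cases to slice-count-sorted cross-validation folds
#'
#' Rather than balancing folds randomly, cases are sorted by slice count
#' (ties by slice thickness, then identifier) and the sorted sequence is cut
#' into k contiguous blocks of near-equal size. Validation volumes therefore
#' never occur in the training set in a similar form — the worst-case
#' scenario for clinical application.
#'
#' @param cases List of `ct_case` (with phantom metadata) or a data frame
#'   with columns `id`, `slice_count`, `slice_thickness`.
#' @param k Number of folds (default 5).
#' @return An object of class `fold_assignment`: a data frame with columns
#'   `id`, `slice_count`, `slice_thickness`, `fold` (0-based).
#' @export
assign_folds <- function(cases, k = 5L) {
  meta <- if (is.data.frame(cases)) cases else {
    data.frame(
      id = vapply(cases, function(x) x$id, character(1)),
      slice_count = vapply(cases, function(x)
        x$metadata$slice_count %||% dim(x$image$intensities)[1], numeric(1)),
      slice_thickness = vapply(cases, function(x)
        x$metadata$slice_thickness %||% x$image$spacing[1], numeric(1)))
  }
  n <- nrow(meta)
  if (n < k) stop("cohort of ", n, " cases is smaller than k = ", k)
  ord <- order(meta$slice_count, meta$slice_thickness, meta$id)
  meta <- meta[ord, , drop = FALSE]
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  meta$fold <- rep(seq_len(k) - 1L, times = sizes)
  rownames(meta) <- NULL
  structure(meta, class = c("fold_assignment", "data.frame"))
}

# Re-sample a stack to exactly n slices (after skip/interpolate changed it).
.fix_slice_count <- function(stack, n, rng) {
  cur <- dim(stack$slices)[1]
  if (cur == n) return(stack)
  idx <- if (cur > n) sort(rs_sample(rng, seq_len(cur), n)) else
    sort(rs_sample(rng, seq_len(cur), n, replace = TRUE))
  slice_stack(stack$slices[idx, , , drop = FALSE],
              if (!is.null(stack$label_slices)) stack$label_slices[idx, , , drop = FALSE],
              stack$source_indices[idx], fill_value = stack$fill_value)
}

# One preprocessed + augmented batch of stacks from a cohort.
.draw_batch_stacks <- function(cases, config, stats, rng, n_volumes) {
  ids <- rs_sample(rng, seq_along(cases), n_volumes, replace = TRUE)
  stacks <- lapply(cases[ids], function(case) {
    preprocess_case(case, config$window, stats,
                    n_slices = config$n_slices, target_size = config$target_size,
                    rng = rng)
  })
  if (!is.null(config$policy)) {
    wt <- transform_window_table(intensity_window_table(), stats)
    pol <- config$policy
    pol$cwvrs_max_shift_hu <- pol$cwvrs_max_shift_hu / stats$std
    stacks <- augment_batch(stacks, pol, rng, window_table = wt)
  }
  lapply(stacks, .fix_slice_count, n = config$n_slices, rng = rng)
}

# Stacks -> (x, y) training tensors for the model dimensionality.
.stacks_to_tensors <- function(stacks, dims, num_classes, batch_size, rng) {
  if (dims == 2L) {
    sl <- Reduce(abind3, lapply(stacks, function(s) s$slices))
    lb <- Reduce(abind3, lapply(stacks, function(s) s$label_slices))
    n <- dim(sl)[1]
    take <- if (n > batch_size) sort(rs_sample(rng, seq_len(n), batch_size)) else seq_len(n)
    sl <- sl[take, , , drop = FALSE]; lb <- lb[take, , , drop = FALSE]
    x <- aperm(sl, c(2, 3, 1))
    dim(x) <- c(dim(x), 1L)
    y <- one_hot(aperm(lb, c(2, 3, 1)), num_classes)
    list(x = x, y = y)
  } else {
    xs <- lapply(stacks, function(s) s$slices)
    ls <- lapply(stacks, function(s) s$label_slices)
    d <- dim(xs[[1]])
    N <- length(xs)
    x <- array(0, c(d[1], d[2], d[3], N, 1L))
    l <- array(0L, c(d[1], d[2], d[3], N))
    for (i in seq_len(N)) { x[, , , i, 1] <- xs[[i]]; l[, , , i] <- ls[[i]] }
    list(x = x, y = one_hot(l, num_classes))
  }
}

# Single gradient step; returns updated model/opt state and the loss.
.train_step <- function(model, opt, x, y, config) {
  C <- model$spec$num_classes
  fw <- model_forward(model, x)
  lg <- combined_loss_grad_logits(matrix(fw$logits, ncol = C),
                                                matrix(y, ncol = C), config$loss)
  if (!is.finite(lg$loss)) return(list(loss = lg$loss))
  grads <- model_backward(model, fw$cache, array(lg$grad, dim(fw$logits)))
  st <- adam_step(model$params, grads, opt, lr = config$lr,
                  beta1 = config$beta1, beta2 = config$beta2)
  model$params <- st$params
  list(model = model, opt = st$state, loss = lg$loss)
}

#' Overfit a model on one fixed batch
#'
#' Repeats ADAM updates against a single cached tensor pair. This is the
#' plumbing check used throughout the test suite: a working model, loss and
#' optimiser must be able to drive the compound loss near zero on a batch it
#' sees every step.
#'
#' @param model A [build_model()] result.
#' @param x Input tensor `(spatial..., N, in_channels)`.
#' @param y One-hot truth `(spatial..., N, C)`.
#' @param steps Number of ADAM steps.
#' @param loss A [loss_config()].
#' @param lr Learning rate.
#' @return List with the trained `model` and the per-step `losses`.
#' @export
fit_batch <- function(model, x, y, steps = 200L, loss = loss_config(), lr = 1e-3) {
  opt <- adam_init(model$params)
  cfg <- list(loss = loss, lr = lr, beta1 = 0.9, beta2 = 0.999)
  losses <- numeric(steps)
  for (s in seq_len(steps)) {
    st <- .train_step(model, opt, x, y, cfg)
    if (!is.finite(st$loss)) stop("non-finite loss at step ", s)
    model <- st$model; opt <- st$opt; losses[s] <- st$loss
  }
  list(model = model, losses = losses)
}

#' Train a segmentation model on a cohort
#'
#' Implements the full training procedure: per step a random batch of
#' volumes is preprocessed (windowing, normalisation, random foreground
#' slice sampling, downsampling) and augmented under the CTIA policy, then
#' the compound loss is minimised by ADAM. Fully reproducible given
#' `config$seed`. Aborts with diagnostics if the loss becomes non-finite.
#'
#' @param model A [build_model()] result.
#' @param cases List of labelled `ct_case` training volumes.
#' @param config A [train_config()].
#' @param stats Optional precomputed `norm_stats`; computed from a random
#'   windowed subset of `cases` when missing.
#' @return List with `model`, `history` (data frame `epoch, mean_loss`),
#'   `stats`, and `config`.
#' @export
train <- function(model, cases, config = train_config(model$spec$dims), stats = NULL) {
  stopifnot(inherits(model, "ctseg_model"), length(cases) >= 1L)
  if (model$spec$dims != config$dims) stop("model and config dimensionality differ")
  rng <- rng_stream(config$seed)
  if (is.null(stats)) {
    windowed <- lapply(cases, function(cs) {
      apply_window(cs$image, compute_window_bounds(cs$image$intensities, config$window))
    })
    stats <- norm_stats_from_subset(windowed, rng = rng)
  }
  n_volumes <- if (config$dims == 2L) {
    max(1L, ceiling(config$batch_size / config$n_slices))
  } else {
    config$batch_size
  }
  opt <- adam_init(model$params)
  cfg_step <- list(loss = config$loss, lr = config$lr,
                   beta1 = config$beta1, beta2 = config$beta2)
  history <- data.frame(epoch = integer(0), mean_loss = numeric(0))
  for (ep in seq_len(config$epochs)) {
    ep_losses <- numeric(config$steps_per_epoch)
    for (s in seq_len(config$steps_per_epoch)) {
      stacks <- .draw_batch_stacks(cases, config, stats, rng, n_volumes)
      tens <- .stacks_to_tensors(stacks, config$dims, model$spec$num_classes,
                                 config$batch_size, rng)
      st <- .train_step(model, opt, tens$x, tens$y, cfg_step)
      if (!is.finite(st$loss)) {
        stop("training aborted: non-finite loss at epoch ", ep, " step ", s,
             "; last batch drew ", length(stacks), " volume stack(s)")
      }
      model <- st$model; opt <- st$opt; ep_losses[s] <- st$loss
    }
    history <- rbind(history, data.frame(epoch = ep, mean_loss = mean(ep_losses)))
  }
  list(model = model, history = history, stats = stats, config = config)
}

# Nearest-neighbour in-plane resize of (n, h, w) to (n, t, t); works for
# both up- and downsampling.
.resize_nn_stack <- function(arr, target) {
  d <- dim(arr)
  if (d[2] == target && d[3] == target) return(arr)
  iy <- .nn_index(d[2], target); ix <- .nn_index(d[3], target)
  arr[, iy, ix, drop = FALSE]
}

#' Volume-wise inference
#'
#' Applies windowing and normalisation (no slice sampling, no augmentation),
#' downsamples in-plane to the model's working size, and runs the model over
#' the full volume: 2D models per slice, 3D models on 50%-overlapping slabs
#' of `n_slices` with uniform probability averaging. The argmax label volume
#' is nearest-neighbour upsampled back to the native in-plane size.
#'
#' @param model A trained [build_model()] result.
#' @param case A `ct_case` (labels not required).
#' @param window A [window_spec()].
#' @param stats The training `norm_stats`.
#' @param target_size Working in-plane side the model was trained at.
#' @param n_slices Slab depth for 3D models (default 16).
#' @param bounds Optional precomputed window bounds (cohort scope).
#' @return List with `probs` (array `(slices, target, target, C)`) and
#'   `labels` (a [label_volume()] at native in-plane size).
#' @export
predict_volume <- function(model, case, window = window_spec(), stats,
                           target_size, n_slices = 16L, bounds = NULL) {
  stopifnot(inherits(model, "ctseg_model"), inherits(case, "ct_case"))
  if (is.null(bounds)) {
    bounds <- compute_window_bounds(case$image$intensities, window)
  }
  vol <- znormalize(apply_window(case$image, bounds), stats)
  d <- dim(vol$intensities)
  stack <- slice_stack(vol$intensities, NULL, seq_len(d[1]),
                       fill_value = min(vol$intensities))
  stack <- downsample_stack(stack, target_size)
  v <- stack$slices
  C <- model$spec$num_classes
  if (model$spec$dims == 2L) {
    probs <- array(0, c(d[1], target_size, target_size, C))
    chunk <- 32L
    for (s0 in seq(1L, d[1], by = chunk)) {
      s1 <- min(d[1], s0 + chunk - 1L)
      x <- aperm(v[s0:s1, , , drop = FALSE], c(2, 3, 1))
      dim(x) <- c(dim(x), 1L)
      p <- model_predict_probs(model, x)          # (h, w, n, C)
      probs[s0:s1, , , ] <- aperm(p, c(3, 1, 2, 4))
    }
  } else {
    slab <- min(n_slices, d[1])
    step <- max(1L, slab %/% 2L)
    starts <- unique(c(seq(1L, max(1L, d[1] - slab + 1L), by = step),
                       max(1L, d[1] - slab + 1L)))
    probs <- array(0, c(d[1], target_size, target_size, C))
    cover <- numeric(d[1])
    for (s0 in starts) {
      sl <- s0:(s0 + slab - 1L)
      sl <- sl[sl <= d[1]]
      x <- v[sl, , , drop = FALSE]
      if (length(sl) < slab) {  # edge-replicate short final slab
        x <- x[c(seq_along(sl), rep(length(sl), slab - length(sl))), , , drop = FALSE]
      }
      dim(x) <- c(dim(x), 1L, 1L)
      p <- model_predict_probs(model, x)          # (slab, h, w, 1, C)
      p <- p[seq_along(sl), , , 1L, , drop = FALSE]
      dim(p) <- c(length(sl), target_size, target_size, C)
      probs[sl, , , ] <- probs[sl, , , , drop = FALSE] + p
      cover[sl] <- cover[sl] + 1
    }
    probs <- probs / array(rep(cover, times = target_size * target_size * C),
                           c(d[1], target_size, target_size, C))
  }
  lab_small <- array(max.col(matrix(probs, ncol = C), ties.method = "first") - 1L, c(d[1], target_size, target_size))
  lab_native <- .resize_nn_stack(lab_small, d[2])
  list(probs = probs,
       labels = label_volume(lab_native,
                             class_names = c("background",
                                             paste0("class", seq_len(C - 1L)))))
}
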