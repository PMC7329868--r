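# Shared fixtures: all test data is generated in code, at small sizes.

# Small noisy phantom cohort.
tiny_phantom_config <- function(in_plane = 32L, slices = c(8L, 12L),
                                noise = 4, tumour_p = 1) {
  phantom_config(in_plane_size = in_plane, slice_count_range = slices,
                 noise_sigma = noise, tumour_probability = tumour_p)
}

# Deterministic zero-noise phantom: every voxel exactly at its class mean.
flat_phantom_config <- function(in_plane = 24L, slices = c(8L, 10L)) {
  phantom_config(
    in_plane_size = in_plane, slice_count_range = slices,
    tissue_palette = list(background = c(-1000, 0), body = c(40, 0),
                          organ = c(60, 0), tumour = c(100, 0)),
    noise_sigma = 0, tumour_probability = 1)
}

# Normalised training tensors (x, y) for a binary organ-vs-background task
# on a zero-noise phantom: the standard overfit smoke fixture.
smoke_batch <- function(seed = 5L, in_plane = 24L, n_slices = 6L,
                        num_classes = 2L) {
  case <- generate_phantom(flat_phantom_config(in_plane = in_plane), seed)
  bounds <- compute_window_bounds(case$image$intensities, window_spec())
  wvol <- apply_window(case$image, bounds)
  vol <- znormalize(wvol, compute_norm_stats(list(wvol)))
  labs <- case$labels
  if (num_classes == 2L) {
    labs$classes[] <- as.integer(labs$classes > 0L)
    labs$class_names <- c("background", "foreground")
  }
  st <- sample_slices(ct_case(vol, labs), n = n_slices, rng = rng_stream(seed + 1L))
  x <- aperm(st$slices, c(2, 3, 1))
  dim(x) <- c(dim(x), 1L)
  y <- one_hot(aperm(st$label_slices, c(2, 3, 1)), num_classes)
  list(x = x, y = y, stack = st, case = case)
}

abind_test <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1] + dim(b)[1], d[2], d[3]))
  out[seq_len(d[1]), , ] <- a
  out[d[1] + seq_len(dim(b)[1]), , ] <- b
  if (is.integer(a)) storage.mode(out) <- "integer"
  out
}

# A slice stack with known content for augmentation tests.
ramp_stack <- function(n = 5L, side = 16L, with_labels = TRUE) {
  sl <- array(0, c(n, side, side))
  for (i in seq_len(n)) {
    sl[i, , ] <- outer(seq_len(side), seq_len(side),
                       function(r, c) (r - 1) * side + (c - 1) + (i - 1) * side^2)
  }
  lb <- NULL
  if (with_labels) {
    lb <- array(0L, c(n, side, side))
    lb[, (side %/% 4):(side %/% 2), (side %/% 4):(side %/% 2)] <- 1L
    lb[, (side %/% 2):(3 * side %/% 4), (side %/% 2):(3 * side %/% 4)] <- 2L
  }
  slice_stack(sl, lb, fill_value = 0)
}

# Build a model that outputs constant class probabilities everywhere:
# a single-layer MS-D net with zeroed weights and the softmax-inverting bias.
constant_model <- function(probs, dims = 2L) {
  C <- length(probs)
  spec <- model_spec("msd", dims = dims, num_classes = C, n_layers = 1L,
                     dilations = 1L)
  m <- build_model(spec, 1L)
  for (nm in names(m$params)) m$params[[nm]][] <- 0
  m$params$msd1_g[] <- 1
  m$params$final_b <- log(as.numeric(probs))
  m
}
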