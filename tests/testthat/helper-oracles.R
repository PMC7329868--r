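# Independent brute-force oracles shared by the unit and acceptance tests.
# Deliberately written as plain loops / sort-based formulas, independent of
# the vectorised implementations they check.

quantile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

tanimoto_oracle <- function(pred_m, truth_m, smooth) {
  C <- ncol(pred_m)
  per_class <- numeric(C)
  for (cl in seq_len(C)) {
    inner <- 0; p2 <- 0; y2 <- 0
    for (v in seq_len(nrow(pred_m))) {
      inner <- inner + pred_m[v, cl] * truth_m[v, cl]
      p2 <- p2 + pred_m[v, cl]^2
      y2 <- y2 + truth_m[v, cl]^2
    }
    per_class[cl] <- 1 - (inner + smooth) / (p2 + y2 - inner + smooth)
  }
  mean(per_class)
}

crossentropy_oracle <- function(pred_m, truth_m, epsilon = 1e-12) {
  tot <- 0
  for (v in seq_len(nrow(pred_m))) {
    p <- sum(pred_m[v, ] * truth_m[v, ])
    tot <- tot + (-log(min(max(p, epsilon), 1)))
  }
  tot / nrow(pred_m)
}

dice_oracle <- function(a, b, cl) {
  ai <- as.integer(a == cl); bi <- as.integer(b == cl)
  den <- sum(ai) + sum(bi)
  if (den == 0) return(1)
  2 * sum(ai * bi) / den
}

random_instance <- function(seed, V = 1000L, C = 3L) {
  set.seed(seed)
  p <- matrix(stats::rgamma(V * C, 1), V, C)
  p <- p / rowSums(p)
  y <- matrix(0, V, C)
  y[cbind(seq_len(V), sample.int(C, V, TRUE))] <- 1
  list(pred = array(p, c(V, C)), truth = array(y, c(V, C)),
       pred_m = p, truth_m = y)
}

fold_oracle <- function(meta, k) {
  meta <- meta[order(meta$slice_count, meta$slice_thickness, meta$id), ]
  n <- nrow(meta)
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  meta$fold <- rep(seq_len(k) - 1L, sizes)
  meta
}
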