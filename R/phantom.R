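# Synthetic HU-calibrated CT phantoms: ellipsoidal body / organ / tumour
# geometry with Gaussian tissue intensity clusters on the Hounsfield scale.

#' Configure the synthetic CT phantom generator
#'
#' The defaults encode the statistical structure real abdominal CT exhibits
#' and that the rest of the framework assumes: an air background around
#' -1000 HU, a soft-tissue body ellipse around +40 HU, an organ at +60 HU with
#' deliberately small contrast to the surrounding tissue (so that windowing
#' matters), an optional tumour blob at +100 HU intersecting the organ,
#' per-case variation in slice count and slice thickness, and additive
#' Gaussian acquisition noise. Intensities are stored as integers in the
#' 12-bit CT range [-1024, 3071].
#'
#' @param in_plane_size Voxels per side of the square slices.
#' @param slice_count_range Inclusive integer interval for slices per case.
#' @param slice_thickness_range Interval (mm) for through-plane spacing.
#' @param tissue_palette Named list mapping class name to `c(mean, sd)` in HU.
#'   Must contain at least `background`, `body`, and `organ`.
#' @param organ_radius_range In-plane organ semi-axis interval (voxels).
#' @param tumour_radius_range Tumour semi-axis interval (voxels).
#' @param tumour_probability Probability a case carries a tumour.
#' @param noise_sigma Additive acquisition noise, HU.
#' @param seed Default seed used when none is passed to the generator.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(in_plane_size = 64L,
                           slice_count_range = c(16L, 64L),
                           slice_thickness_range = c(1, 5),
                           tissue_palette = list(
                             background = c(-1000, 15),
                             body = c(40, 12),
                             organ = c(60, 10),
                             tumour = c(100, 12),
                             bone = c(1000, 50)),
                           organ_radius_range = NULL,
                           tumour_radius_range = NULL,
                           tumour_probability = 0.7,
                           noise_sigma = 8,
                           seed = 1L) {
  in_plane_size <- as.integer(in_plane_size)
  if (is.null(organ_radius_range)) {
    organ_radius_range <- c(max(3L, in_plane_size %/% 10), max(4L, in_plane_size %/% 5))
  }
  if (is.null(tumour_radius_range)) {
    tumour_radius_range <- c(max(2L, in_plane_size %/% 20), max(3L, in_plane_size %/% 10))
  }
  cfg <- structure(list(
    in_plane_size = in_plane_size,
    slice_count_range = as.integer(slice_count_range),
    slice_thickness_range = as.numeric(slice_thickness_range),
    tissue_palette = tissue_palette,
    organ_radius_range = as.numeric(organ_radius_range),
    tumour_radius_range = as.numeric(tumour_radius_range),
    tumour_probability = tumour_probability,
    noise_sigma = noise_sigma,
    seed = as.integer(seed)), class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (cfg$slice_count_range[1] < 4L) stop("slice_count_range minimum must be >= 4")
  rngs <- list(cfg$slice_count_range, cfg$slice_thickness_range,
               cfg$organ_radius_range, cfg$tumour_radius_range)
  if (any(vapply(rngs, function(r) r[2] < r[1], logical(1)))) {
    stop("all ranges must be non-empty (max >= min)")
  }
  need <- c("background", "body", "organ")
  if (!all(need %in% names(cfg$tissue_palette))) {
    stop("tissue_palette must contain at least: ", paste(need, collapse = ", "))
  }
  for (nm in names(cfg$tissue_palette)) {
    p <- cfg$tissue_palette[[nm]]
    if (length(p) != 2L || p[2] < 0) stop("palette entry '", nm, "' must be c(mean, sd>=0)")
    if (p[1] < HU_MIN || p[1] > HU_MAX) {
      stop("palette mean for '", nm, "' outside HU storage range [-1024, 3071]")
    }
  }
  if (cfg$tumour_probability < 0 || cfg$tumour_probability > 1) {
    stop("tumour_probability must be in [0, 1]")
  }
  if (cfg$noise_sigma < 0) stop("noise_sigma must be >= 0")
  invisible(cfg)
}

# Voxel-centre coordinates of an axis-aligned ellipsoid mask.
.ellipsoid_mask <- function(dims, centre, semi) {
  s <- seq_len(dims[1]); r <- seq_len(dims[2]); c <- seq_len(dims[3])
  ds <- ((s - centre[1]) / semi[1])^2
  dr <- ((r - centre[2]) / semi[2])^2
  dc <- ((c - centre[3]) / semi[3])^2
  outer(outer(ds, dr, `+`), dc, `+`) <= 1
}

#' Generate one synthetic CT phantom case
#'
#' Builds a soft-tissue body ellipse embedded in air, one ellipsoidal organ
#' inside the body, and (with configured probability) one tumour blob
#' intersecting the organ. Voxel intensities are drawn from the per-tissue
#' Gaussian palette, noise is added, and values are rounded and clamped to
#' the integer HU range. Labels: 0 = background (air and body), 1 = organ,
#' 2 = tumour. The same `(config, seed)` pair reproduces the identical case.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An object of class `ct_case` with `metadata` attached
#'   (slice count, slice thickness in mm, seed used).
#' @export
generate_phantom <- function(config, seed = config$seed) {
  validate_phantom_config(config)
  rng <- rng_stream(seed)
  n <- config$in_plane_size
  ns <- as.integer(rs_int(rng, 1L, config$slice_count_range[1], config$slice_count_range[2]))
  thick <- rs_unif(rng, 1L, config$slice_thickness_range[1], config$slice_thickness_range[2])
  dims <- c(ns, n, n)

  # body: large in-plane ellipse spanning most slices
  body_semi <- c(ns * rs_unif(rng, 1L, 0.45, 0.5),
                 n * rs_unif(rng, 1L, 0.33, 0.42),
                 n * rs_unif(rng, 1L, 0.33, 0.42))
  body_centre <- c((ns + 1) / 2, (n + 1) / 2, (n + 1) / 2)
  body <- .ellipsoid_mask(dims, body_centre, body_semi)

  # organ: must fit inside the body; reject-and-resample placement
  organ <- NULL
  for (try in seq_len(25L)) {
    orad <- rs_unif(rng, 1L, config$organ_radius_range[1], config$organ_radius_range[2])
    osemi <- c(max(2, ns * rs_unif(rng, 1L, 0.2, 0.35)), orad, orad)
    jit <- rs_unif(rng, 3L, -0.15, 0.15) * c(ns, n, n)
    ocen <- body_centre + jit
    cand <- .ellipsoid_mask(dims, ocen, osemi)
    if (any(cand) && all(body[cand])) { organ <- cand; break }
  }
  if (is.null(organ)) {
    stop("organ does not fit in the volume at the sampled radii; ",
         "reduce organ_radius_range relative to in_plane_size")
  }

  tumour <- array(FALSE, dims)
  if (rs_unif(rng, 1L) < config$tumour_probability) {
    for (try in seq_len(25L)) {
      trad <- rs_unif(rng, 1L, config$tumour_radius_range[1], config$tumour_radius_range[2])
      tsemi <- c(max(1.5, osemi[1] * 0.5), trad, trad)
      # centre near the organ boundary so the blob intersects the organ
      tcen <- ocen + rs_unif(rng, 3L, -0.6, 0.6) * osemi
      cand <- .ellipsoid_mask(dims, tcen, tsemi)
      if (any(cand & organ) && all(body[cand])) { tumour <- cand; break }
    }
  }

  labels <- array(0L, dims)
  labels[organ] <- 1L
  labels[tumour] <- 2L

  pal <- config$tissue_palette
  img <- array(0, dims)
  draw <- function(mask, mu, sd) {
    k <- sum(mask)
    if (k > 0) img[mask] <<- if (sd > 0) rs_norm(rng, k, mu, sd) else rep(mu, k)
  }
  draw(!body, pal$background[1], pal$background[2])
  draw(body & labels == 0L, pal$body[1], pal$body[2])
  draw(labels == 1L, pal$organ[1], pal$organ[2])
  if (any(labels == 2L)) {
    tp <- pal$tumour %||% pal$organ
    draw(labels == 2L, tp[1], tp[2])
  }
  if (config$noise_sigma > 0) img <- img + rs_norm(rng, length(img), 0, config$noise_sigma)
  img <- clamp_hu(round(img))

  case <- ct_case(ct_volume(img, spacing = c(thick, 1, 1)),
                  label_volume(labels, c("background", "organ", "tumour")),
                  id = sprintf("phantom_%d", as.integer(seed)))
  tissue <- array(0L, dims)          # 0 air, 1 body soft tissue, 2 organ, 3 tumour
  tissue[body] <- 1L
  tissue[organ] <- 2L
  tissue[tumour] <- 3L
  case$metadata <- list(slice_count = ns, slice_thickness = thick,
                        seed = as.integer(seed), tissue = tissue)
  case
}

#' Generate a cohort of phantom cases
#'
#' Per-case seeds are derived deterministically from the cohort seed (offset
#' by case index), so cohorts are reproducible and order-stable. Slice counts
#' vary across the configured range, which keeps slice-count-sorted folds
#' non-degenerate.
#'
#' @param n Number of cases (>= 1).
#' @param config A [phantom_config()].
#' @param seed Cohort seed.
#' @return A list of `ct_case` objects.
#' @export
generate_cohort <- function(n, config, seed = config$seed) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  lapply(seq_len(n), function(i) {
    case <- generate_phantom(config, seed = derive_seed(seed, i))
    case$id <- sprintf("phantom_%03d", i)
    case
  })
}

#' Apply a global intensity shift/scale to a cohort
#'
#' Simulates vendor- or patient-specific intensity calibration differences:
#' each image is mapped voxel-wise `v -> scale * v + shift_hu` and clamped to
#' the HU storage range. Labels are untouched. Used by robustness
#' experiments to build distribution-shifted test sets.
#'
#' @param cohort List of `ct_case`.
#' @param shift_hu Additive offset in HU.
#' @param scale Multiplicative factor (> 0).
#' @param seed Unused at present (reserved for per-case jitter); kept so the
#'   call is reproducible by signature.
#' @return List of shifted `ct_case` objects.
#' @export
perturb_cohort <- function(cohort, shift_hu = 0, scale = 1, seed = 0L) {
  if (!is.numeric(scale) || scale <= 0) stop("scale must be > 0")
  lapply(cohort, function(case) {
    v <- case$image$intensities
    if (scale != 1 || shift_hu != 0) {
      v <- clamp_hu(scale * v + shift_hu)
    }
    out <- case
    out$image$intensities <- v
    out
  })
}
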