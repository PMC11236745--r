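# Synthetic image/mask fixture generators. These emulate the visual
# structure of the target applications — dermoscopic lesions (one smooth
# dark blob, optional hair-like occlusions), microscopy nuclei (many
# small bright ellipses) and short-axis cardiac geometry (bright cavity,
# surrounding muscle ring, adjacent crescent-shaped chamber) — well
# enough to exercise the full pipeline without any download. They do not
# attempt photorealism or the intensity statistics of the real datasets.

#' Specification for a synthetic fixture set
#'
#' @param kind one of `"lesion"`, `"nuclei"`, `"ring"`.
#' @param size image side length (divisible by 16; default 64 so a full
#'   train/evaluate loop runs in CPU minutes).
#' @param n_samples number of samples.
#' @param seed RNG seed; every generated set is a pure function of
#'   (seed, spec).
#' @param noise_sd additive Gaussian intensity noise.
#' @param occlusion_prob probability that a lesion image receives dark
#'   hair-like polylines.
#' @return An object of class `plnet_fixture_spec`.
#' @export
fixture_spec <- function(kind = c("lesion", "nuclei", "ring"), size = 64L,
                         n_samples = 8L, seed = 1L, noise_sd = 0.05,
                         occlusion_prob = 0.3) {
  kind <- match.arg(kind)
  if (size %% 16 != 0) stop("`size` must be divisible by 16")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (occlusion_prob < 0 || occlusion_prob > 1) stop("`occlusion_prob` must be in [0, 1]")
  structure(list(kind = kind, size = as.integer(size),
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 noise_sd = noise_sd, occlusion_prob = occlusion_prob),
            class = "plnet_fixture_spec")
}

.pix_grid <- function(n) {
  list(x = matrix(rep(seq_len(n), n), n, n),
       y = matrix(rep(seq_len(n), each = n), n, n))
}

.add_noise <- function(img, sd) {
  if (sd > 0) img <- img + array(stats::rnorm(length(img), 0, sd), dim(img))
  img[img < 0] <- 0; img[img > 1] <- 1
  img
}

#' Generate one lesion-like sample
#'
#' A smooth random blob (low-order Fourier perturbation of an ellipse
#' boundary) with interior/exterior color contrast, additive Gaussian
#' noise and optional dark hair-like polyline occlusions; the mask is
#' the blob interior. Draws from the current R RNG state; see
#' [generate_fixtures()] for seeded batches.
#'
#' @param spec a [fixture_spec()].
#' @param id sample identifier.
#' @return A `seg_sample` with a binary mask.
#' @export
gen_lesion <- function(spec, id = "lesion") {
  n <- spec$size
  g <- .pix_grid(n)
  cx <- stats::runif(1, 0.38, 0.62) * n; cy <- stats::runif(1, 0.38, 0.62) * n
  rx <- stats::runif(1, 0.15, 0.32) * n; ry <- stats::runif(1, 0.15, 0.32) * n
  phi <- stats::runif(3, 0, 2 * pi)
  amp <- stats::rnorm(3, 0, 0.06) / (1:3)
  dx <- (g$x - cx) / rx; dy <- (g$y - cy) / ry
  th <- atan2(dy, dx)
  r <- sqrt(dx^2 + dy^2)
  bound <- 1 + amp[1] * cos(2 * th + phi[1]) + amp[2] * cos(3 * th + phi[2]) +
    amp[3] * cos(4 * th + phi[3])
  mask <- (r <= bound) * 1L
  skin <- stats::runif(3, c(0.75, 0.55, 0.45), c(0.9, 0.7, 0.6))
  lesion <- stats::runif(3, c(0.3, 0.15, 0.1), c(0.5, 0.35, 0.25))
  img <- array(0, c(n, n, 3))
  for (k in 1:3) img[, , k] <- skin[k] * (1 - mask) + lesion[k] * mask
  if (stats::runif(1) < spec$occlusion_prob) {
    for (h in seq_len(sample(1:3, 1))) {
      t <- seq(0, 1, length.out = 4 * n)
      p0 <- stats::runif(2, 1, n); p1 <- stats::runif(2, 1, n); pc <- stats::runif(2, 1, n)
      xs <- round((1 - t)^2 * p0[1] + 2 * t * (1 - t) * pc[1] + t^2 * p1[1])
      ys <- round((1 - t)^2 * p0[2] + 2 * t * (1 - t) * pc[2] + t^2 * p1[2])
      keep <- xs >= 1 & xs <= n & ys >= 1 & ys <= n
      shade <- stats::runif(1, 0.05, 0.2)
      for (k in 1:3) img[cbind(xs[keep], ys[keep], k)] <- shade
    }
  }
  seg_sample(.add_noise(img, spec$noise_sd), mask, id,
             class_names = c("background", "lesion"))
}

#' Generate one nuclei-like sample
#'
#' 5-40 small bright ellipses (possibly touching) on a dark noisy
#' background; the mask is their union.
#'
#' @inheritParams gen_lesion
#' @param n_nuclei optional fixed count; default uniform in 5..40,
#'   scaled down proportionally for images smaller than 128 px.
#' @export
gen_nuclei <- function(spec, id = "nuclei", n_nuclei = NULL) {
  n <- spec$size
  g <- .pix_grid(n)
  if (is.null(n_nuclei)) {
    hi <- max(6L, as.integer(40 * min(1, (n / 128)^2)))
    n_nuclei <- sample(5:max(5L, hi), 1)
  }
  mask <- matrix(0L, n, n)
  for (i in seq_len(n_nuclei)) {
    cx <- stats::runif(1, 3, n - 2); cy <- stats::runif(1, 3, n - 2)
    rx <- stats::runif(1, 1.5, max(2.5, n / 24)); ry <- stats::runif(1, 1.5, max(2.5, n / 24))
    a <- stats::runif(1, 0, pi)
    xr <- (g$x - cx) * cos(a) + (g$y - cy) * sin(a)
    yr <- -(g$x - cx) * sin(a) + (g$y - cy) * cos(a)
    mask[(xr / rx)^2 + (yr / ry)^2 <= 1] <- 1L
  }
  base <- stats::runif(1, 0.05, 0.15)
  bright <- stats::runif(1, 0.65, 0.85)
  tint <- stats::runif(3, 0.9, 1)
  img <- array(0, c(n, n, 3))
  for (k in 1:3) img[, , k] <- pmin(1, (base + (bright - base) * mask) * tint[k])
  seg_sample(.add_noise(img, spec$noise_sd), mask, id,
             class_names = c("background", "nucleus"))
}

#' Generate one cardiac-ring sample
#'
#' Three-class geometry emulating a short-axis cardiac slice: class 1 is
#' a bright inner disk (cavity), class 2 the muscle annulus strictly
#' surrounding it, class 3 an adjacent crescent-shaped chamber; label 0
#' is background. Radii are drawn so all four labels are present and the
#' annulus fully encloses the disk.
#'
#' @inheritParams gen_lesion
#' @export
gen_ring <- function(spec, id = "ring") {
  n <- spec$size
  g <- .pix_grid(n)
  cx <- stats::runif(1, 0.45, 0.55) * n; cy <- stats::runif(1, 0.45, 0.55) * n
  r1 <- stats::runif(1, 0.08, 0.12) * n
  r2 <- r1 + stats::runif(1, 0.05, 0.08) * n
  r3 <- stats::runif(1, 0.08, 0.12) * n
  ang <- stats::runif(1, 0, 2 * pi)
  d3 <- r2 + 0.7 * r3
  c3x <- cx + d3 * cos(ang); c3y <- cy + d3 * sin(ang)
  rr <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
  rc <- sqrt((g$x - c3x)^2 + (g$y - c3y)^2)
  mask <- matrix(0L, n, n)
  mask[rc <= r3] <- 3L              # crescent chamber (clipped below by the ring)
  mask[rr <= r2] <- 2L              # annulus
  mask[rr <= r1] <- 1L              # cavity
  lev <- c(0.12, 0.85, 0.35, 0.6)   # background, cavity, muscle, chamber
  img <- array(0, c(n, n, 3))
  base <- lev[mask + 1L]
  for (k in 1:3) img[, , k] <- base * stats::runif(1, 0.95, 1)
  seg_sample(.add_noise(img, spec$noise_sd), mask, id,
             class_names = c("background", "cavity", "myocardium", "chamber"))
}

#' Generate a reproducible list of fixture samples
#'
#' Seeds the R RNG from `spec$seed` and draws `spec$n_samples` samples of
#' `spec$kind`, so the result is a pure function of the spec.
#'
#' @param spec a [fixture_spec()].
#' @return List of `seg_sample` objects.
#' @export
generate_fixtures <- function(spec) {
  stopifnot(inherits(spec, "plnet_fixture_spec"))
  set.seed(spec$seed)
  gen <- switch(spec$kind, lesion = gen_lesion, nuclei = gen_nuclei, ring = gen_ring)
  lapply(seq_len(spec$n_samples), function(i)
    gen(spec, id = sprintf("%s_%03d", spec$kind, i)))
}

#' Write a fixture dataset to disk
#'
#' Writes `images/` and `masks/` PNG pairs (mask label `k` stored as
#' gray value `k/255`, so values round-trip exactly) plus a
#' `manifest.csv`, in the layout [load_dataset()] consumes.
#'
#' @param dir output directory (created if needed).
#' @param spec a [fixture_spec()].
#' @return Invisibly, the manifest path.
#' @export
write_fixture_dataset <- function(dir, spec) {
  samples <- generate_fixtures(spec)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    ip <- file.path("images", paste0(s$id, ".png"))
    mp <- file.path("masks", paste0(s$id, ".png"))
    png::writePNG(s$image, file.path(dir, ip))
    png::writePNG(s$mask / 255, file.path(dir, mp))
    data.frame(id = s$id, image_path = ip, mask_path = mp)
  })
  mf <- file.path(dir, "manifest.csv")
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), image_path = character(), mask_path = character())
  utils::write.csv(tab, mf, row.names = FALSE)
  invisible(mf)
}
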