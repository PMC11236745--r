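# Dataset reading, preprocessing and geometric augmentation.

#' Construct an image/mask sample
#'
#' @param image numeric array `H x W x C` (or `H x W`, promoted to one
#'   channel), values in `[0, 1]`.
#' @param mask integer matrix `H x W` of class labels (0 = background).
#' @param id sample identifier.
#' @param class_names optional ordered label vocabulary (including
#'   background first).
#' @return An object of class `seg_sample`.
#' @export
seg_sample <- function(image, mask, id = "sample", class_names = NULL) {
  if (length(dim(image)) == 2L) dim(image) <- c(dim(image), 1L)
  mask <- matrix(as.integer(round(mask)), nrow(mask), ncol(mask))
  if (!identical(dim(image)[1:2], dim(mask)))
    stop("image and mask spatial dims differ")
  if (any(mask < 0)) stop("mask labels must be non-negative")
  structure(list(image = image, mask = mask, id = as.character(id),
                 class_names = class_names),
            class = "seg_sample")
}

#' Gray-world color constancy
#'
#' Scales each color channel so that all channel means equal the global
#' mean of the channel means (the gray-world assumption used to
#' normalize dermoscopy image colors). The result is clipped to
#' `[0, 1]`. A channel whose mean is zero is passed through unscaled;
#' single-channel images are returned unchanged with a warning.
#'
#' @param image numeric array `H x W x 3`, values in `[0, 1]`.
#' @return Corrected image of the same dims.
#' @export
gray_world <- function(image) {
  d <- dim(image)
  if (length(d) < 3L || d[3] != 3L) {
    warning("gray-world correction is undefined for non-RGB images; returning input")
    return(image)
  }
  mu <- apply(image, 3L, mean)
  target <- mean(mu)
  out <- image
  for (k in 1:3) if (mu[k] > 0) out[, , k] <- image[, , k] * (target / mu[k])
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Resize a sample to the network input size
#'
#' The image is resized with bilinear interpolation, the mask with
#' nearest-neighbor so labels are preserved exactly; intensities are
#' rescaled to `[0, 1]` if they arrive on a 0-255 scale. When
#' `color_constancy` is set, [gray_world()] runs before resizing.
#'
#' @param sample a `seg_sample`.
#' @param size target side length (default 224).
#' @param color_constancy apply gray-world normalization first.
#' @return The preprocessed `seg_sample`.
#' @export
preprocess_sample <- function(sample, size = 224L, color_constancy = FALSE) {
  stopifnot(inherits(sample, "seg_sample"))
  img <- sample$image
  if (length(img) == 0L || any(dim(img)[1:2] == 0L)) stop("empty image")
  if (max(img) > 1) img <- img / 255
  if (color_constancy) img <- gray_world(img)
  d <- dim(img)
  if (!identical(d[1:2], c(size, size))) {
    img <- vapply(seq_len(d[3]), function(k)
      EBImage::imageData(EBImage::resize(EBImage::Image(img[, , k]), size, size,
                                         filter = "bilinear")),
      matrix(0, size, size))
    dim(img) <- c(size, size, d[3])
    msk <- EBImage::imageData(EBImage::resize(EBImage::Image(sample$mask), size, size,
                                              filter = "none"))
    msk <- matrix(as.integer(round(msk)), size, size)
  } else msk <- sample$mask
  img[img < 0] <- 0; img[img > 1] <- 1
  seg_sample(img, msk, sample$id, sample$class_names)
}

# reflect-pad a matrix by p pixels on each side
.reflect_pad <- function(M, p) {
  n1 <- nrow(M); n2 <- ncol(M)
  i <- c((p + 1L):2L, 1:n1, (n1 - 1L):(n1 - p))
  j <- c((p + 1L):2L, 1:n2, (n2 - 1L):(n2 - p))
  M[i, j]
}

.zero_pad <- function(M, p) {
  out <- matrix(0, nrow(M) + 2L * p, ncol(M) + 2L * p)
  out[p + seq_len(nrow(M)), p + seq_len(ncol(M))] <- M
  out
}

#' Random geometric augmentation
#'
#' One random geometric transform — rotation uniform in `[-max_rotate,
#' max_rotate]` degrees, horizontal/vertical shifts uniform in plus or
#' minus `max_shift` of each dimension, and independent 50% horizontal
#' and vertical flips — applied identically to image and mask. The image
#' is warped bilinearly over reflect padding; the mask is warped
#' nearest-neighbor over zero (background) padding. Randomness comes
#' from the R RNG, so results are reproducible under `set.seed()`.
#'
#' @param sample a preprocessed `seg_sample`.
#' @param max_rotate rotation bound in degrees.
#' @param max_shift shift bound as a fraction of each dimension.
#' @return The augmented `seg_sample`.
#' @export
augment_sample <- function(sample, max_rotate = 25, max_shift = 0.15) {
  stopifnot(inherits(sample, "seg_sample"))
  H <- nrow(sample$mask); W <- ncol(sample$mask)
  ang <- stats::runif(1, -max_rotate, max_rotate) * pi / 180
  sh <- c(stats::runif(1, -max_shift, max_shift) * H,
          stats::runif(1, -max_shift, max_shift) * W)
  fh <- stats::runif(1) < 0.5
  fv <- stats::runif(1) < 0.5
  img <- sample$image; msk <- sample$mask
  if (fh) { img <- img[, W:1, , drop = FALSE]; msk <- msk[, W:1, drop = FALSE] }
  if (fv) { img <- img[H:1, , , drop = FALSE]; msk <- msk[H:1, , drop = FALSE] }
  p <- ceiling(0.35 * max(H, W)) + 2L
  ctr <- c((H + 2 * p + 1) / 2, (W + 2 * p + 1) / 2)
  A <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)  # p' = p %*% A + b
  b <- ctr - ctr %*% A + sh
  m <- rbind(A, b)
  warp1 <- function(M, filter, pad) {
    Mp <- pad(M, p)
    out <- EBImage::imageData(EBImage::affine(EBImage::Image(Mp), m, filter = filter,
                                              output.dim = dim(Mp), bg.col = 0))
    out[p + seq_len(H), p + seq_len(W)]
  }
  img2 <- vapply(seq_len(dim(img)[3]),
                 function(k) warp1(img[, , k], "bilinear", .reflect_pad),
                 matrix(0, H, W))
  dim(img2) <- dim(img)
  img2[img2 < 0] <- 0; img2[img2 > 1] <- 1
  msk2 <- matrix(as.integer(round(warp1(msk, "none", .zero_pad))), H, W)
  seg_sample(img2, msk2, sample$id, sample$class_names)
}

#' Train/validation/test split fractions
#'
#' @param train,val,test fractions summing to one.
#' @param seed RNG seed for the deterministic shuffle.
#' @return An object of class `plnet_split_spec`.
#' @export
split_spec <- function(train = 0.6, val = 0.2, test = 0.2, seed = 1L) {
  if (abs(train + val + test - 1) > 1e-8) stop("fractions must sum to 1")
  if (min(train, val, test) < 0) stop("fractions must be non-negative")
  structure(list(train = train, val = val, test = test, seed = as.integer(seed)),
            class = "plnet_split_spec")
}

.img_exts <- c("png", "jpg", "jpeg", "tif", "tiff")

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]  # drop alpha
  img
}

read_mask_file <- function(path) {
  m <- read_image_file(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  v <- round(m * 255)
  u <- sort(unique(as.vector(v)))
  if (identical(u, c(0, 255)) || identical(u, 0) || identical(u, 255))
    v <- v / 255                                   # {0,255} -> {0,1}
  matrix(as.integer(v), nrow(m), ncol(m))
}

#' Load an image/mask folder dataset and split it
#'
#' Expects `images/` and `masks/` subfolders whose files pair by
#' filename stem (case-insensitive png/jpg/jpeg/tif/tiff extensions).
#' Masks stored on a 0/255 scale are binarized to 0/1. Ids are sorted,
#' shuffled with the split's seed, and partitioned by the split
#' fractions, so membership is reproducible.
#'
#' @param dir dataset directory.
#' @param split a [split_spec()].
#' @param size if non-`NULL`, each sample is passed through
#'   [preprocess_sample()] at this size.
#' @param color_constancy forwarded to [preprocess_sample()].
#' @return list with `train`, `val`, `test` (lists of `seg_sample`) and
#'   `problems` (character vector naming orphan files).
#' @export
load_dataset <- function(dir, split = split_spec(), size = NULL,
                         color_constancy = FALSE) {
  imgdir <- file.path(dir, "images"); mskdir <- file.path(dir, "masks")
  if (!dir.exists(imgdir) || !dir.exists(mskdir))
    stop("`dir` must contain images/ and masks/ subfolders")
  list_stems <- function(d) {
    fs <- list.files(d)
    fs <- fs[tolower(tools::file_ext(fs)) %in% .img_exts]
    stats::setNames(fs, tools::file_path_sans_ext(fs))
  }
  imgs <- list_stems(imgdir); msks <- list_stems(mskdir)
  ids <- sort(intersect(names(imgs), names(msks)))
  problems <- c(
    sprintf("image without mask: %s", imgs[setdiff(names(imgs), ids)]),
    sprintf("mask without image: %s", msks[setdiff(names(msks), ids)]))
  if (length(ids) == 0L) stop("no paired image/mask files found")
  samples <- lapply(ids, function(id) {
    s <- seg_sample(read_image_file(file.path(imgdir, imgs[[id]])),
                    read_mask_file(file.path(mskdir, msks[[id]])), id = id)
    if (!is.null(size)) s <- preprocess_sample(s, size, color_constancy)
    s
  })
  names(samples) <- ids
  n <- length(samples)
  withr_seed <- function(seed, code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed); on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    code
  }
  ord <- withr_seed(split$seed, sample.int(n))
  n_train <- round(split$train * n)
  n_val <- round(split$val * n)
  idx_train <- ord[seq_len(n_train)]
  idx_val <- if (n_val > 0) ord[n_train + seq_len(min(n_val, n - n_train))] else integer()
  idx_test <- setdiff(ord, c(idx_train, idx_val))
  list(train = samples[idx_train], val = samples[idx_val],
       test = samples[idx_test], problems = problems)
}

#' Write / read a CSV manifest of a split dataset
#'
#' @param splits result of [load_dataset()] (or any list of sample lists
#'   named train/val/test).
#' @param dir dataset directory the paths are relative to.
#' @param path manifest file path.
#' @return `write_manifest` returns `path`; `read_manifest` a data frame
#'   with columns id, image_path, mask_path, split.
#' @export
write_manifest <- function(splits, dir, path = file.path(dir, "manifest.csv")) {
  rows <- do.call(rbind, lapply(c("train", "val", "test"), function(sp) {
    ss <- splits[[sp]]
    if (length(ss) == 0L) return(NULL)
    data.frame(id = vapply(ss, `[[`, "", "id"),
               image_path = file.path("images", paste0(vapply(ss, `[[`, "", "id"), ".png")),
               mask_path = file.path("masks", paste0(vapply(ss, `[[`, "", "id"), ".png")),
               split = sp)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
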