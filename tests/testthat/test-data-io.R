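test_that("gray-world correction equalizes channel means", {
  # uniform gray image: already balanced, unchanged
  g <- array(0.4, c(8, 8, 3))
  expect_equal(gray_world(g), g)
  # distinct channel means: all post-correction means equal the grand mean
  set.seed(1)
  img <- array(0, c(16, 16, 3))
  for (k in 1:3) img[, , k] <- runif(256, 0, 0.2 * k)
  out <- gray_world(img)
  mu <- apply(out, 3, mean)
  expect_equal(mu[1], mu[2], tolerance = 1e-12)
  expect_equal(mu[2], mu[3], tolerance = 1e-12)
  expect_equal(mean(mu), mean(img), tolerance = 1e-12)
  expect_true(all(out >= 0 & out <= 1))
  # single-channel input: returned unchanged with a warning
  expect_warning(out1 <- gray_world(array(0.3, c(4, 4, 1))), "non-RGB")
  expect_equal(out1, array(0.3, c(4, 4, 1)))
  # a zero-mean channel passes through unscaled
  img[, , 2] <- 0
  expect_silent(out2 <- gray_world(img))
  expect_equal(out2[, , 2], img[, , 2])
})

test_that("preprocessing resizes images bilinearly and masks exactly", {
  set.seed(2)
  img <- array(runif(48 * 40 * 3), c(48, 40, 3))
  msk <- matrix(0L, 48, 40); msk[10:30, 8:25] <- 1L
  s <- seg_sample(img, msk, "a")
  p <- preprocess_sample(s, size = 32)
  expect_identical(dim(p$image), c(32L, 32L, 3L))
  expect_identical(dim(p$mask), c(32L, 32L))
  expect_true(all(p$mask %in% c(0L, 1L)))        # labels survive resizing
  expect_true(sum(p$mask) > 0)
  # already-at-size samples pass through bit-identically
  p2 <- preprocess_sample(p, size = 32)
  expect_identical(p2$mask, p$mask)
  expect_equal(p2$image, p$image, tolerance = 0)
  # 0-255 intensities are rescaled
  s255 <- seg_sample(img * 255, msk, "b")
  expect_lt(max(preprocess_sample(s255, 32)$image), 1 + 1e-9)
})

test_that("augmentation is deterministic and applies one transform to both maps", {
  smp <- generate_fixtures(fixture_spec("lesion", size = 32, n_samples = 1, seed = 3))[[1]]
  set.seed(11); a <- augment_sample(smp)
  set.seed(11); b <- augment_sample(smp)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  # flips only: mask and a mask-valued image channel transform identically
  probe <- smp
  probe$image[, , 1] <- smp$mask
  set.seed(4)
  fa <- augment_sample(probe, max_rotate = 0, max_shift = 0)
  expect_equal(fa$image[, , 1], fa$mask + 0, tolerance = 1e-12)
  # label set is preserved by nearest-neighbor warping
  set.seed(5)
  for (i in 1:25) {
    aug <- augment_sample(smp)
    expect_true(all(aug$mask %in% c(0L, 1L)))
    expect_identical(dim(aug$mask), dim(smp$mask))
  }
})

test_that("folder datasets load, binarize and split deterministically", {
  dir <- file.path(tempdir(), "ds1")
  unlink(dir, recursive = TRUE)
  write_fixture_dataset(dir, fixture_spec("lesion", size = 32, n_samples = 10, seed = 6))
  # an orphan image is reported and skipped
  png::writePNG(matrix(0.5, 8, 8), file.path(dir, "images", "orphan.png"))
  ds1 <- load_dataset(dir, split_spec(0.6, 0.2, 0.2, seed = 1))
  expect_length(ds1$train, 6); expect_length(ds1$val, 2); expect_length(ds1$test, 2)
  expect_match(ds1$problems, "orphan", all = FALSE)
  ds2 <- load_dataset(dir, split_spec(0.6, 0.2, 0.2, seed = 1))
  ids <- function(d) lapply(d[c("train", "val", "test")], names)
  expect_identical(ids(ds1), ids(ds2))                 # reproducible membership
  all_ids <- unname(unlist(ids(ds1)))
  expect_identical(sort(all_ids), sort(unique(all_ids)))  # a true partition
  expect_length(all_ids, 10L)
  # masks stored on the 0/255 convention binarize to {0, 1}
  m <- ds1$train[[1]]$mask
  png::writePNG(matrix(c(0, 1, 1, 0), 2, 2), file.path(dir, "masks", m255 <- "m255.png"))
  png::writePNG(matrix(0.5, 2, 2, byrow = TRUE), file.path(dir, "images", "m255.png"))
  ds3 <- load_dataset(dir, split_spec(1, 0, 0, seed = 1))
  lab <- sort(unique(as.vector(ds3$train[["m255"]]$mask)))
  expect_true(all(lab %in% c(0L, 1L)))
})

test_that("the 80/20 split reproduces the published nuclei protocol counts", {
  # 670 ids, 80% train / 20% test
  n <- 670L
  sp <- split_spec(0.8, 0, 0.2, seed = 1)
  n_train <- as.integer(round(sp$train * n))
  expect_identical(n_train, 536L)
  expect_identical(n - n_train, 134L)
})

test_that("manifests round-trip through CSV", {
  dir <- file.path(tempdir(), "ds2")
  unlink(dir, recursive = TRUE)
  write_fixture_dataset(dir, fixture_spec("ring", size = 32, n_samples = 4, seed = 8))
  ds <- load_dataset(dir, split_spec(0.5, 0.25, 0.25, seed = 2))
  mf <- write_manifest(ds, dir, file.path(dir, "split.csv"))
  tab <- read_manifest(mf)
  expect_identical(sort(tab$id), sort(names(c(ds$train, ds$val, ds$test))))
  expect_setequal(unique(tab$split), c("train", "val", "test"))
})
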