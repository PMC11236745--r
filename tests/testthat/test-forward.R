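test_that("every stage output conserves the input's spatial dims", {
  for (sz in c(32L, 48L)) {
    for (K in c(1L, 3L)) {
      set.seed(5)
      m <- build_plnet(small_cfg(input_size = sz, n_classes = K))
      img <- rand_image(sz)
      for (stage in 1:2) {
        y <- ipl_forward(m, img, stage)
        expect_identical(dim(y), c(sz, sz, K))
        expect_true(all(is.finite(y)))
      }
    }
  }
})

test_that("a batch forward equals per-image forwards", {
  m <- small_model()
  imgs <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  yb <- ipl_forward(m, imgs, 2)
  expect_identical(dim(yb), c(32L, 32L, 1L, 2L))
  y1 <- ipl_forward(m, imgs[, , , 1], 2)
  expect_equal(yb[, , 1, 1], y1[, , 1], tolerance = 1e-12)
})

test_that("input dims must be compatible with the network depth", {
  m <- small_model()
  expect_error(ipl_forward(m, rand_image(30)), "divisible")
  expect_error(ipl_forward(m, rand_image(32), stage = 5), "out of range")
})

test_that("fsc_merge equals a hand-composed concat-conv-norm-relu computation", {
  m <- small_model()
  ch <- m$config$channels
  set.seed(11)
  x <- array(rnorm(16 * 16 * ch[2]), c(16, 16, ch[2]))
  xh <- array(rnorm(16 * 16 * ch[2]), c(16, 16, ch[2]))
  got <- fsc_merge(m, x, xh, level = 2, step = 1)
  expect_identical(dim(got), c(16L, 16L, ch[2]))
  # oracle: compose the primitives manually
  u <- m$params$dec2_s1
  cat4 <- array(c(x, xh), c(16, 16, 1, 2 * ch[2]))
  M <- matrix(cat4, 16 * 16, 2 * ch[2])
  Kmat <- matrix(aperm(u$W, c(3, 1, 2, 4)), , ch[2])
  Mp <- array(0, c(18, 18, 1, 2 * ch[2])); Mp[2:17, 2:17, 1, ] <- cat4
  cols <- list(); k <- 0
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1
    cols[[k]] <- matrix(Mp[di + 1:16, dj + 1:16, 1, ], 256, 2 * ch[2])
  }
  conv <- do.call(cbind, cols) %*% Kmat
  # eval-mode batch norm with default statistics (mean 0, var 1)
  bn <- t(t(conv) * (u$g / sqrt(1 + 1e-5)) + u$be)
  oracle <- array(pmax(bn, 0), c(16, 16, ch[2]))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("fsc_merge on all-zero features is a deterministic bias response", {
  m <- small_model()
  z <- array(0, c(16, 16, m$config$channels[2]))
  a <- fsc_merge(m, z, z, level = 2, step = 1)
  b <- fsc_merge(m, z, z, level = 2, step = 1)
  expect_identical(a, b)
  expect_error(fsc_merge(m, z, array(0, c(8, 8, 16)), 2, 1), "spatial")
})

test_that("bsc_merge enforces its backward-feature contract", {
  m <- small_model()
  img <- rand_image()
  ch <- m$config$channels
  # (step 1, stage 1): no backward feature exists yet
  out11 <- bsc_merge(m, img, NULL, level = 1, step = 1, stage = 1)
  expect_identical(dim(out11), c(32L, 32L, ch[1]))
  expect_error(bsc_merge(m, img, NULL, level = 1, step = 2, stage = 1), "step 1 of stage 1")
  expect_error(bsc_merge(m, img, NULL, level = 1, step = 1, stage = 2), "step 1 of stage 1")
  # (step 2): previous pass's decoder feature is concatenated before the conv
  prev <- array(rnorm(32 * 32 * ch[1]), c(32, 32, ch[1]))
  x1 <- array(rnorm(32 * 32 * ch[1]), c(32, 32, ch[1]))
  out <- bsc_merge(m, x1, prev, level = 2, step = 2, stage = 1)
  expect_identical(dim(out), c(16L, 16L, ch[2]))
  # oracle: explicit concat -> pool -> conv unit
  cat4 <- array(c(x1, prev), c(32, 32, 1, 2 * ch[1]))
  pooled <- plnet:::nd_val(plnet:::op_maxpool2(NULL, plnet:::tp_node(NULL, cat4)))
  oracle <- plnet:::nd_val(plnet:::conv_unit_fwd(NULL, m, "enc2_s2",
                                                 plnet:::tp_node(NULL, pooled), FALSE))
  expect_equal(out, array(oracle, c(16, 16, ch[2])), tolerance = 1e-12)
})

test_that("the recursive forward equals an explicitly unrolled composition", {
  # two steps, fixed random weights: every pass composed by hand from the
  # merge primitives (see helper-plnet.R), no recursion abstraction
  m <- small_model(input_size = 32L)
  img <- rand_image(32)
  oracle <- unrolled_forward(m, img)
  expect_equal(ipl_forward(m, img, 1), oracle$y1, tolerance = 0)
  expect_equal(ipl_forward(m, img, 2), oracle$y2, tolerance = 0)
})

test_that("a single step degenerates to one plain encode-decode pass per stage", {
  set.seed(9)
  m1 <- build_plnet(small_cfg(n_steps = 1L))
  img <- rand_image()
  y <- ipl_forward(m1, img, 2)
  expect_identical(dim(y), c(32L, 32L, 1L))
  # structurally one conv per block: no step-2 units exist
  expect_false(any(grepl("_s2$", names(m1$params))))
})
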