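test_that("zero-residual units are exact identities on nonnegative input", {
  set.seed(1)
  x <- array(abs(rnorm(12 * 12 * 3)), c(12, 12, 3))
  w <- residual_weights(3, 3, seed = 1, zero_residual = TRUE)

  expect_equal(residual_unit(x, w), x)

  ## telescoping through a 6-unit stack
  y <- x
  for (i in 1:6) y <- residual_unit(y, w)
  expect_equal(y, x)

  ## negative entries are clipped by the outer ReLU
  xn <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  expect_equal(residual_unit(xn, w), pmax(xn, 0))
})

test_that("identity and convolutional blocks respect their shape contracts", {
  set.seed(2)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2))

  ## identity block preserves shape, zero-residual version is the identity
  wi <- residual_weights(2, 2, seed = 2, zero_residual = TRUE)
  expect_equal(identity_block(abs(x), wi), abs(x))

  ## conv block with stride 2 halves the spatial size
  wc <- residual_weights(2, 4, stride = 2, seed = 3)
  out <- conv_block(x, wc)
  expect_equal(dim(out), c(8L, 8L, 4L))

  ## misuse raises shape errors
  w_wrong <- residual_weights(5, 5, seed = 4)
  expect_error(identity_block(x, w_wrong), "shape error")
  expect_error(identity_block(x, wc), "shape error")
  expect_error(conv_block(x, wi), "projected shortcut")
})

test_that("analytic input gradient matches finite differences through a
           randomly initialized block", {
  set.seed(5)
  w <- residual_weights(3, 3, seed = 5)
  for (nm in c("bn1", "bn2")) {
    w[[nm]]$run_mean <- rnorm(3) * 0.1
    w[[nm]]$run_var <- runif(3, 0.5, 1.5)
  }
  x <- array(rnorm(10 * 10 * 3), c(10, 10, 3))
  upstream <- array(rnorm(10 * 10 * 3), c(10, 10, 3))
  g <- residual_unit_grad_x(x, w, upstream)

  h <- 1e-5
  idx <- sample(length(x), 80)
  fd <- vapply(idx, function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (sum(residual_unit(xp, w) * upstream) -
       sum(residual_unit(xm, w) * upstream)) / (2 * h)
  }, numeric(1))
  rel_err <- sqrt(sum((fd - g[idx])^2)) / sqrt(sum(fd^2))
  expect_lt(rel_err, 1e-3)

  ## the shortcut contributes an additive identity path: with zero
  ## residual weights the gradient is the upstream signal gated by ReLU
  w0 <- residual_weights(3, 3, seed = 6, zero_residual = TRUE)
  xpos <- array(abs(rnorm(8 * 8 * 3)) + 0.1, c(8, 8, 3))
  up <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  expect_equal(residual_unit_grad_x(xpos, w0, up), up)
})

test_that("image encoding is deterministic with a constant output dimension", {
  rn <- resnet(seed = 7)
  z <- matrix(0, 32, 32)
  v0 <- encode_image(z, rn)
  expect_true(all(is.finite(v0)))
  expect_identical(v0, encode_image(z, rn))

  set.seed(8)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(encode_image(img, rn), encode_image(img, rn))
  expect_length(encode_image(img, rn), 32L)
  expect_length(encode_image(matrix(runif(24 * 24), 24, 24), rn), 32L)

  expect_error(encode_image(matrix(0, 4, 4), rn), "receptive minimum")
  expect_error(encode_image(matrix(c(NA, rep(0, 63)), 8, 8), rn), "finite")
})

test_that("encoded vectors separate blob classes better than chance", {
  sch <- tiny_schema(40, 2)
  tr <- generate_kg(sch, 1, seed = 1)
  imgs <- generate_images(tr, 32, seed = 1)
  pr <- attr(imgs, "params")
  feats <- encode_images(imgs, resnet(seed = 1))

  sel <- which(pr$n_blobs %in% c(1, 3))
  X <- feats[sel, ]
  y <- pr$n_blobs[sel] == 3
  ## stratified half split, nearest-centroid linear probe
  tr_i <- c(which(y)[seq(1, sum(y), 2)], which(!y)[seq(1, sum(!y), 2)])
  te_i <- setdiff(seq_along(sel), tr_i)
  c1 <- colMeans(X[intersect(tr_i, which(y)), , drop = FALSE])
  c0 <- colMeans(X[intersect(tr_i, which(!y)), , drop = FALSE])
  pred <- apply(X[te_i, , drop = FALSE], 1,
                function(v) sum((v - c1)^2) < sum((v - c0)^2))
  acc <- mean(unname(pred) == y[te_i])
  expect_gt(acc, 0.5 + 3 * sqrt(0.25 / length(te_i)))
})
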