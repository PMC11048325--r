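test_that("first convolution yields 256 x 7 x 8 with non-negative output", {
  set.seed(11)
  x <- array(rnorm(3 * 16 * 18), c(3, 16, 18))
  W <- matrix(rnorm(256 * 27, sd = 0.1), 256, 27)
  out <- conv_relu(x, W, stride = 2)
  expect_equal(dim(out), c(256, 7, 8))
  expect_true(all(out >= 0))
  expect_true(all(conv_relu(array(0, c(3, 16, 18)), W) == 0))
  expect_error(conv_relu(array(0, c(3, 16)), W), class = "eegcaps_argument_error")
})

test_that("ECA kernel size follows the adaptive odd mapping", {
  expect_equal(eca_kernel_size(256, 2, 1), 5L) # t = 4.5
  expect_equal(eca_kernel_size(2, 2, 1), 1L)   # t = 1.0
  expect_equal(eca_kernel_size(64, 2, 1), 3L)  # t = 3.5
  expect_true(all(vapply(2^(1:10), eca_kernel_size, integer(1)) %% 2 == 1))
})

test_that("ECA block preserves shape, halves under zero weights, and is
           permutation-equivariant at k = 1", {
  set.seed(12)
  x <- array(rnorm(8 * 4 * 5), c(8, 4, 5))
  w <- rnorm(3, sd = 0.3)
  out <- eca_block(x, w)
  expect_equal(dim(out), dim(x))
  expect_equal(eca_block(x, rep(0, 3)), x / 2) # sigmoid(0) = 1/2
  # k = 1: each channel gated only by itself
  w1 <- 0.7
  perm <- sample(8)
  expect_equal(eca_block(x, w1)[perm, , ], eca_block(x[perm, , ], w1))
})

test_that("SE block preserves shape with the analytic degenerate cases", {
  set.seed(13)
  C <- 8
  x <- array(rnorm(C * 4 * 5), c(C, 4, 5))
  W1 <- matrix(rnorm(2 * C, sd = 0.3), 2, C)
  W2 <- matrix(rnorm(C * 2, sd = 0.3), C, 2)
  out <- se_block(x, W1, W2)
  expect_equal(dim(out), dim(x))
  expect_equal(se_block(x, W1 * 0, W2 * 0), x / 2)
  expect_equal(se_block(x * 0, W1, W2), x * 0)
})

test_that("squash preserves direction and maps norms into [0, 1)", {
  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
  v <- squash(c(1, 0, 0))
  expect_equal(sqrt(sum(v^2)), 0.5) # unit input -> norm 1/2
  set.seed(14)
  norms <- c()
  prev <- 0
  for (a in c(0.1, 1, 10, 100, 1000)) {
    s <- a * c(3, 4) / 5
    v <- squash(s)
    n <- sqrt(sum(v^2))
    expect_lt(n, 1)
    expect_gt(n, prev)
    prev <- n
    expect_equal(v / n, s / sqrt(sum(s^2))) # direction preserved
  }
})

test_that("primary capsules count positions x channels and stay sub-unit", {
  set.seed(15)
  x <- array(rnorm(256 * 7 * 8, sd = 0.2), c(256, 7, 8))
  W <- matrix(rnorm(256 * 256 * 9, sd = 0.01), 256, 256 * 9)
  caps <- primary_caps(x, W, caps_dim = 8)
  expect_equal(dim(caps), c(32 * 5 * 6, 8)) # 960 capsules of dimension 8
  expect_true(all(sqrt(rowSums(caps^2)) < 1))
  expect_true(all(primary_caps(x * 0, W, caps_dim = 8) == 0))
})

test_that("dynamic routing matches a straight-line oracle and normalises
           couplings at every iteration", {
  set.seed(16)
  primary <- matrix(rnorm(3 * 8, sd = 0.5), 3, 8)
  weights <- array(rnorm(32 * 8 * 3, sd = 0.2), c(32, 8, 3))
  for (iters in 1:3) {
    v <- dynamic_routing(primary, weights, n_out = 2, n_iters = iters)
    vo <- routing_bruteforce(primary, weights, n_out = 2, n_iters = iters)
    expect_equal(v, vo, tolerance = 1e-6, ignore_attr = TRUE)
    expect_true(all(sqrt(rowSums(v^2)) < 1))
  }
  # inspect couplings through the internal forward
  ulist <- lapply(1:2, function(j) array(rnorm(3 * 8 * 1), c(3, 8, 1)))
  rf <- eegcaps:::routing_forward(ulist, 3)
  for (it in 1:3) {
    csum <- Reduce(`+`, rf$iters[[it]]$clist)
    expect_equal(csum, matrix(1, 3, 1), tolerance = 1e-12)
  }
  # iteration 1 couplings are uniform (softmax of zero logits)
  expect_equal(rf$iters[[1]]$clist[[1]], matrix(0.5, 3, 1))
})

test_that("one routing iteration equals squash of the uniform-coupling mean", {
  set.seed(17)
  primary <- matrix(rnorm(5 * 4), 5, 4)
  weights <- array(rnorm(2 * 6 * 4 * 5, sd = 0.3), c(12, 4, 5))
  v1 <- dynamic_routing(primary, weights, n_out = 2, n_iters = 1)
  for (j in 1:2) {
    uh <- vapply(1:5, function(i) {
      (weights[, , i] %*% primary[i, ])[(j - 1) * 6 + 1:6]
    }, numeric(6))
    # uniform couplings c = 1/2: s_j is half the sum of predictions
    expect_equal(v1[j, ], squash(rowSums(uh) / 2), tolerance = 1e-9)
  }
})
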