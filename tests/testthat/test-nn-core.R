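# Forward-semantics checks for the network primitives against hand-computed
# values and independent scalar-loop oracles.

test_that("conv2d computes strided cross-correlation", {
  expect_equal(conv2d(matrix(c(1, 3, 2, 4), 2), diag(2)),
               matrix(5))
  M <- matrix(rnorm(36), 6)
  expect_equal(conv2d(M, matrix(1)), M)          # identity kernel
  expect_error(conv2d(matrix(1), matrix(0, 2, 2)), class = "pg_shape_error")

  set.seed(101)
  for (i in 1:25) {
    M <- matrix(rnorm(48), 6, 8)
    N <- matrix(rnorm(9), 3, 3)
    s <- sample(1:2, 1)
    p <- sample(0:2, 1)
    expect_equal(conv2d(M, N, stride = s, padding = p),
                 oracle_conv2d(M, N, stride = s, padding = p),
                 tolerance = 1e-12)
  }
})

test_that("relu clamps negatives and preserves shape", {
  expect_identical(relu(-3), 0)
  expect_identical(relu(0), 0)
  expect_identical(relu(2.5), 2.5)
  m <- matrix(c(-1, 2, -3, 4), 2)
  expect_equal(relu(m), matrix(c(0, 2, 0, 4), 2))
})

test_that("max_pool takes block maxima with floor-halved dims", {
  expect_equal(max_pool(matrix(1:4, 2, byrow = TRUE)), matrix(4))
  expect_equal(max_pool(matrix(7, 4, 6)), matrix(7, 2, 3))
  set.seed(102)
  for (i in 1:25) {
    M <- matrix(rnorm(7 * 9), 7, 9)   # odd dims: trailing rows/cols dropped
    expect_equal(max_pool(M), oracle_max_pool(M), tolerance = 1e-15)
  }
  expect_equal(max_pool1d(c(1, 5, 2, 2, 9)), c(5, 2))
  expect_error(max_pool(matrix(1)), class = "pg_shape_error")
})

test_that("lstm_cell follows the gate recurrences", {
  zero_params <- function(H, D, tie = FALSE) {
    W <- matrix(0, H, H + D)
    lstm_params(W, numeric(H), W, numeric(H), W, numeric(H), W, numeric(H),
                tie_candidate_to_input_gate = tie)
  }
  # zero weights, zero state: gates 0.5, candidate 0 -> everything stays 0
  st <- lstm_cell(0, lstm_state(0, 0), zero_params(1, 1))
  expect_equal(st$C, 0)
  expect_equal(st$h, 0)
  # zero weights, C_prev = 1: C' = 0.5, h' = 0.5 * tanh(0.5)
  st <- lstm_cell(0, lstm_state(1, 0), zero_params(1, 1))
  expect_equal(st$C, 0.5, tolerance = 1e-12)
  expect_equal(st$h, 0.5 * tanh(0.5), tolerance = 1e-12)
  expect_equal(st$h, 0.2310585786, tolerance = 1e-9)

  set.seed(103)
  for (i in 1:25) {
    H <- 3L; D <- 2L
    p <- lstm_params(
      matrix(rnorm(H * (H + D)), H), rnorm(H),
      matrix(rnorm(H * (H + D)), H), rnorm(H),
      matrix(rnorm(H * (H + D)), H), rnorm(H),
      matrix(rnorm(H * (H + D)), H), rnorm(H))
    x <- rnorm(D); h0 <- rnorm(H); C0 <- rnorm(H)
    got <- lstm_cell(x, lstm_state(C0, h0), p)
    want <- oracle_lstm_cell(x, h0, C0, p)
    expect_equal(got$C, want$C, tolerance = 1e-10)
    expect_equal(got$h, want$h, tolerance = 1e-10)
  }
  expect_error(lstm_cell(c(1, 2, 3), lstm_state(0, 0), zero_params(1, 1)),
               class = "pg_shape_error")
})

test_that("tying the candidate to the input gate reproduces the literal form", {
  set.seed(104)
  H <- 2L; D <- 2L
  Wi <- matrix(rnorm(H * (H + D)), H); bi <- rnorm(H)
  Wf <- matrix(rnorm(H * (H + D)), H); bf <- rnorm(H)
  Wo <- matrix(rnorm(H * (H + D)), H); bo <- rnorm(H)
  Wc <- matrix(rnorm(H * (H + D)), H); bc <- rnorm(H)
  x <- rnorm(D); st0 <- lstm_state(rnorm(H), rnorm(H))
  tied <- lstm_cell(x, st0, lstm_params(Wi, bi, Wc, bc, Wf, bf, Wo, bo,
                                        tie_candidate_to_input_gate = TRUE))
  # equivalent to setting the candidate parameters equal to the input gate's
  manual <- lstm_cell(x, st0, lstm_params(Wi, bi, Wi, bi, Wf, bf, Wo, bo))
  expect_equal(tied$C, manual$C, tolerance = 1e-14)
  expect_equal(tied$h, manual$h, tolerance = 1e-14)
})

test_that("lstm_sequence folds lstm_cell and shows geometric cell decay", {
  set.seed(105)
  H <- 2L; D <- 1L
  p <- lstm_params(
    matrix(rnorm(H * (H + D)), H), rnorm(H),
    matrix(rnorm(H * (H + D)), H), rnorm(H),
    matrix(rnorm(H * (H + D)), H), rnorm(H),
    matrix(rnorm(H * (H + D)), H), rnorm(H))
  x1 <- list(rnorm(D))
  init <- lstm_state(rnorm(H), rnorm(H))
  states <- lstm_sequence(x1, init, p)
  single <- lstm_cell(x1[[1]], init, p)
  expect_length(states, 1L)
  expect_equal(states[[1]]$h, single$h)

  # zero parameters: gates 0.5 forever, so C_T = 0.5^T from C_0 = 1
  W0 <- matrix(0, 1, 2)
  p0 <- lstm_params(W0, 0, W0, 0, W0, 0, W0, 0)
  for (T in c(1L, 5L, 12L, 30L)) {
    xs <- as.list(rep(0, T))
    states <- lstm_sequence(xs, lstm_state(1, 0), p0)
    expect_equal(states[[T]]$C, 0.5^T, tolerance = 1e-12)
  }
  expect_error(lstm_sequence(list(), lstm_state(0, 0), p0),
               class = "pg_empty_input_error")
})

test_that("residual_apply computes F(x) + x", {
  x <- rnorm(5)
  expect_identical(residual_apply(x, residual_block(function(v) v * 0)), x)
  expect_equal(residual_apply(x, residual_block(identity)), 2 * x)
  set.seed(106)
  for (i in 1:10) {
    A <- matrix(rnorm(25), 5)
    x <- rnorm(5)
    expect_equal(residual_apply(x, residual_block(function(v) drop(A %*% v))),
                 drop(A %*% x) + x, tolerance = 1e-12)
  }
  # shape change requires a projection
  expect_error(
    residual_apply(x, residual_block(function(v) v[1:3])),
    class = "pg_shape_error")
  P <- matrix(rnorm(15), 3, 5)
  expect_equal(
    residual_apply(x, residual_block(function(v) rep(0, 3), projection = P)),
    drop(P %*% x))
})

test_that("softmax is a stable probability simplex map", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(log(2), 0)), c(2 / 3, 1 / 3), tolerance = 1e-12)
  set.seed(107)
  for (i in 1:20) {
    x <- rnorm(6) * 10
    p <- softmax(x)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(softmax(x + 123.456), p, tolerance = 1e-12)
  }
  # extreme values do not overflow
  expect_equal(sum(softmax(c(1e4, 0, -1e4))), 1)
})

test_that("dense applies activation(Wx + b)", {
  x <- rnorm(4)
  expect_equal(dense(x, diag(4), numeric(4)), x)
  expect_equal(dense(3, matrix(2), 1), 7)
  set.seed(108)
  for (i in 1:20) {
    W <- matrix(rnorm(12), 3, 4)
    b <- rnorm(3)
    x <- rnorm(4)
    want <- numeric(3)
    for (r in 1:3) want[r] <- sum(W[r, ] * x) + b[r]
    expect_equal(dense(x, W, b), want, tolerance = 1e-12)
    expect_equal(dense(x, W, b, "relu"), pmax(want, 0), tolerance = 1e-12)
  }
  expect_error(dense(x, matrix(1, 2, 3), c(0, 0)), class = "pg_shape_error")
})

test_that("lstm gate activations stay in their open ranges", {
  set.seed(109)
  for (i in 1:20) {
    H <- 3L; D <- 2L
    p <- lstm_params(
      matrix(rnorm(H * (H + D), sd = 3), H), rnorm(H),
      matrix(rnorm(H * (H + D), sd = 3), H), rnorm(H),
      matrix(rnorm(H * (H + D), sd = 3), H), rnorm(H),
      matrix(rnorm(H * (H + D), sd = 3), H), rnorm(H))
    st <- lstm_cell(rnorm(D), lstm_state(rnorm(H), rnorm(H)), p)
    # |h| = |o * tanh(C)| < 1 since o in (0,1) and |tanh| < 1
    expect_true(all(abs(st$h) < 1))
  }
})
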