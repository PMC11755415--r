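# Forward-pass primitives of the network stack. Each operation has a pinned
# mathematical contract (cross-correlation convolution, ReLU thresholding, LSTM
# gate recurrences, residual skip mapping, stabilised softmax) and is kept
# framework-free so it can be checked against scalar-loop references.

#' 2-D convolution (cross-correlation) of a matrix with a kernel
#'
#' Computes `G(x, y) = sum_i sum_j M(x + i, y + j) * N(i, j)` over the valid
#' region of the (optionally zero-padded) input, then subsamples by `stride`.
#' The kernel is applied un-flipped, i.e. this is the cross-correlation form
#' used throughout deep learning.
#'
#' @param input Numeric matrix `M`.
#' @param kernel Numeric matrix `N` (the filter). A vector is treated as a
#'   one-row matrix for the 1-D case.
#' @param stride Positive integer subsampling step (both axes).
#' @param padding Non-negative integer count of zero rows/columns added on
#'   every side before convolving.
#' @return Numeric matrix of the strided valid-region feature map.
#' @examples
#' conv2d(matrix(1:4, 2, byrow = TRUE), diag(2))  # 1*1 + 4*1 = 5
#' @export
conv2d <- function(input, kernel, stride = 1L, padding = 0L) {
  if (is.vector(input)) input <- matrix(input, nrow = 1L)
  if (is.vector(kernel)) kernel <- matrix(kernel, nrow = 1L)
  if (!is.matrix(input) || !is.numeric(input)) {
    pg_stop("pg_shape_error", "`input` must be a numeric matrix")
  }
  if (!is.matrix(kernel) || !is.numeric(kernel) || any(dim(kernel) < 1L)) {
    pg_stop("pg_shape_error", "`kernel` must be a non-empty numeric matrix")
  }
  check_scalar_number(stride, "stride", lower = 1, integer = TRUE)
  check_scalar_number(padding, "padding", lower = 0, integer = TRUE)
  if (padding > 0L) {
    padded <- matrix(0, nrow(input) + 2L * padding, ncol(input) + 2L * padding)
    padded[padding + seq_len(nrow(input)), padding + seq_len(ncol(input))] <-
      input
    input <- padded
  }
  ki <- nrow(kernel); kj <- ncol(kernel)
  no <- nrow(input) - ki + 1L
  mo <- ncol(input) - kj + 1L
  if (no < 1L || mo < 1L) {
    pg_stop("pg_shape_error",
            "kernel (%dx%d) larger than padded input (%dx%d)",
            ki, kj, nrow(input), ncol(input))
  }
  out <- matrix(0, no, mo)
  # accumulate one shifted copy of the input per kernel tap
  for (i in seq_len(ki)) {
    for (j in seq_len(kj)) {
      out <- out + kernel[i, j] *
        input[(i - 1L) + seq_len(no), (j - 1L) + seq_len(mo), drop = FALSE]
    }
  }
  out[seq(1L, no, by = stride), seq(1L, mo, by = stride), drop = FALSE]
}

#' Rectified linear unit
#'
#' Elementwise `max(0, x)`; shape-preserving for vectors, matrices and arrays.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape with negative entries clamped to zero.
#' @export
relu <- function(x) {
  pmax(x, 0)
}

#' Non-overlapping max pooling
#'
#' Downsamples a matrix by taking the maximum over non-overlapping
#' `window x window` blocks (stride equals the window). Trailing rows/columns
#' that do not fill a block are dropped, so the output dimensions are
#' `floor(dim(input) / window)`.
#'
#' @param input Numeric matrix.
#' @param window Positive integer pooling window (default 2).
#' @return Pooled numeric matrix.
#' @export
max_pool <- function(input, window = 2L) {
  if (is.vector(input)) input <- matrix(input, nrow = 1L)
  if (!is.matrix(input) || !is.numeric(input) || length(input) == 0L) {
    pg_stop("pg_shape_error", "`input` must be a non-empty numeric matrix")
  }
  check_scalar_number(window, "window", lower = 1, integer = TRUE)
  no <- nrow(input) %/% window
  mo <- ncol(input) %/% window
  if (no < 1L || mo < 1L) {
    pg_stop("pg_shape_error", "input smaller than pooling window")
  }
  out <- matrix(-Inf, no, mo)
  for (i in seq_len(window)) {
    for (j in seq_len(window)) {
      rows <- (seq_len(no) - 1L) * window + i
      cols <- (seq_len(mo) - 1L) * window + j
      out <- pmax(out, input[rows, cols, drop = FALSE])
    }
  }
  out
}

#' 1-D max pooling over length-`window` segments
#'
#' @param x Numeric vector.
#' @param window Positive integer pooling window (default 2).
#' @return Numeric vector of length `floor(length(x) / window)`.
#' @export
max_pool1d <- function(x, window = 2L) {
  if (!is.numeric(x) || length(x) == 0L) {
    pg_stop("pg_shape_error", "`x` must be a non-empty numeric vector")
  }
  check_scalar_number(window, "window", lower = 1, integer = TRUE)
  n <- length(x) %/% window
  if (n < 1L) pg_stop("pg_shape_error", "input shorter than pooling window")
  apply(matrix(x[seq_len(n * window)], nrow = window), 2L, max)
}

#' LSTM parameter set
#'
#' Bundles the four gate weight matrices and biases of an LSTM cell. Each
#' weight acts on the concatenation `[h_prev, x]`, so its column count is
#' `hidden + input` and its row count is `hidden`. Some published descriptions
#' tie the candidate transformation to the input gate's parameters; setting
#' `tie_candidate_to_input_gate = TRUE` reproduces that behaviour (`W_c`, `b_c`
#' are ignored and `W_i`, `b_i` are used for the candidate as well).
#'
#' @param W_i,W_c,W_f,W_o Numeric matrices `hidden x (hidden + input)` for the
#'   input gate, candidate, forget gate and output gate.
#' @param b_i,b_c,b_f,b_o Numeric bias vectors of length `hidden`.
#' @param tie_candidate_to_input_gate Logical; reuse the input-gate parameters
#'   for the candidate transform.
#' @return An object of class `lstm_params`.
#' @export
lstm_params <- function(W_i, b_i, W_c, b_c, W_f, b_f, W_o, b_o,
                        tie_candidate_to_input_gate = FALSE) {
  mats <- list(W_i = W_i, W_c = W_c, W_f = W_f, W_o = W_o)
  vecs <- list(b_i = b_i, b_c = b_c, b_f = b_f, b_o = b_o)
  hidden <- nrow(W_i)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!is.matrix(m) || nrow(m) != hidden || ncol(m) != ncol(W_i)) {
      pg_stop("pg_shape_error",
              "`%s` must be a %d x %d matrix (hidden x hidden+input)",
              nm, hidden, ncol(W_i))
    }
  }
  for (nm in names(vecs)) {
    v <- vecs[[nm]]
    if (!is.numeric(v) || length(v) != hidden) {
      pg_stop("pg_shape_error", "`%s` must have length %d (hidden size)",
              nm, hidden)
    }
  }
  if (ncol(W_i) <= hidden) {
    pg_stop("pg_shape_error",
            "weight column count (%d) must exceed hidden size (%d)",
            ncol(W_i), hidden)
  }
  structure(
    list(W_i = W_i, b_i = b_i, W_c = W_c, b_c = b_c, W_f = W_f, b_f = b_f,
         W_o = W_o, b_o = b_o,
         hidden = hidden, input = ncol(W_i) - hidden,
         tie_candidate_to_input_gate = isTRUE(tie_candidate_to_input_gate)),
    class = "lstm_params"
  )
}

#' Randomly initialised LSTM parameters
#'
#' Uniform fan-in-scaled initialisation (`U(-s, s)` with
#' `s = sqrt(6 / fan_in)`), seeded for reproducibility.
#'
#' @param input_size,hidden_size Positive integer dimensions.
#' @param seed Integer RNG seed.
#' @inheritParams lstm_params
#' @return An `lstm_params` object.
#' @export
lstm_params_init <- function(input_size, hidden_size, seed = 1L,
                             tie_candidate_to_input_gate = FALSE) {
  check_scalar_number(input_size, "input_size", lower = 1, integer = TRUE)
  check_scalar_number(hidden_size, "hidden_size", lower = 1, integer = TRUE)
  d <- input_size + hidden_size
  s <- sqrt(6 / d)
  with_seed(seed, {
    mk <- function() matrix(stats::runif(hidden_size * d, -s, s),
                            hidden_size, d)
    lstm_params(mk(), numeric(hidden_size), mk(), numeric(hidden_size),
                mk(), numeric(hidden_size), mk(), numeric(hidden_size),
                tie_candidate_to_input_gate = tie_candidate_to_input_gate)
  })
}

#' LSTM cell/hidden state pair
#'
#' @param C Numeric cell-state vector.
#' @param h Numeric hidden-output vector of the same length.
#' @return An object of class `lstm_state`.
#' @export
lstm_state <- function(C, h) {
  if (!is.numeric(C) || !is.numeric(h) || length(C) != length(h)) {
    pg_stop("pg_shape_error", "`C` and `h` must be numeric and equal length")
  }
  structure(list(C = as.numeric(C), h = as.numeric(h)), class = "lstm_state")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One LSTM time step
#'
#' Applies the gate recurrences
#' `i = sigma(W_i [h, x] + b_i)`, `c~ = tanh(W_c [h, x] + b_c)`,
#' `f = sigma(W_f [h, x] + b_f)`, `C' = f * C + i * c~`,
#' `o = sigma(W_o [h, x] + b_o)`, `h' = o * tanh(C')`
#' (elementwise products), returning the new state.
#'
#' @param x Numeric input vector for this step.
#' @param prev An `lstm_state` carrying the previous cell state and output.
#' @param params An `lstm_params` object.
#' @return An `lstm_state` with the updated `C` and `h`.
#' @export
lstm_cell <- function(x, prev, params) {
  stopifnot(inherits(params, "lstm_params"), inherits(prev, "lstm_state"))
  if (length(x) != params$input) {
    pg_stop("pg_shape_error", "input `x` has length %d, params expect %d",
            length(x), params$input)
  }
  if (length(prev$h) != params$hidden) {
    pg_stop("pg_shape_error", "state `prev` has length %d, params expect %d",
            length(prev$h), params$hidden)
  }
  z <- c(prev$h, x)
  i <- sigmoid(drop(params$W_i %*% z) + params$b_i)
  if (params$tie_candidate_to_input_gate) {
    ctil <- tanh(drop(params$W_i %*% z) + params$b_i)
  } else {
    ctil <- tanh(drop(params$W_c %*% z) + params$b_c)
  }
  f <- sigmoid(drop(params$W_f %*% z) + params$b_f)
  C_new <- f * prev$C + i * ctil
  o <- sigmoid(drop(params$W_o %*% z) + params$b_o)
  lstm_state(C_new, o * tanh(C_new))
}

#' Run an LSTM over a sequence of inputs
#'
#' Left fold of [lstm_cell()] over `xs`, returning every intermediate state.
#'
#' @param xs A list of numeric input vectors (or a matrix whose columns are the
#'   per-step inputs).
#' @param init Initial `lstm_state`.
#' @param params An `lstm_params` object.
#' @return A list of `lstm_state` objects, one per step.
#' @export
lstm_sequence <- function(xs, init, params) {
  if (is.matrix(xs)) xs <- lapply(seq_len(ncol(xs)), function(j) xs[, j])
  if (length(xs) == 0L) {
    pg_stop("pg_empty_input_error", "`xs` must contain at least one step")
  }
  states <- vector("list", length(xs))
  st <- init
  for (t in seq_along(xs)) {
    st <- lstm_cell(xs[[t]], st, params)
    states[[t]] <- st
  }
  states
}

#' Residual (skip-connection) block
#'
#' Wraps a transform `F` so that applying the block computes `F(x) + x`; an
#' optional linear `projection` matrix maps `x` when `F` changes the shape.
#'
#' @param inner A function mapping a numeric vector to one of the same length
#'   (or of the projection's output length).
#' @param projection Optional numeric matrix applied to `x` before the skip
#'   addition.
#' @return An object of class `residual_block`.
#' @export
residual_block <- function(inner, projection = NULL) {
  stopifnot(is.function(inner))
  if (!is.null(projection) && !is.matrix(projection)) {
    pg_stop("pg_shape_error", "`projection` must be a matrix when given")
  }
  structure(list(inner = inner, projection = projection),
            class = "residual_block")
}

#' Apply a residual block: `F(x) + x`
#'
#' @param x Numeric vector (or array, when `inner` preserves its shape).
#' @param block A [residual_block()].
#' @return `block$inner(x) + x` (with `x` projected first if a projection is
#'   configured).
#' @export
residual_apply <- function(x, block) {
  stopifnot(inherits(block, "residual_block"))
  fx <- block$inner(x)
  skip <- if (is.null(block$projection)) x else drop(block$projection %*% x)
  if (length(fx) != length(skip)) {
    pg_stop("pg_shape_error",
            "inner transform output length %d does not match skip length %d; supply a projection",
            length(fx), length(skip))
  }
  fx + skip
}

#' Numerically stable softmax
#'
#' `softmax(x)_i = exp(x_i) / sum_j exp(x_j)`, computed after subtracting
#' `max(x)` so large inputs do not overflow. The output is a probability
#' vector.
#'
#' @param x Non-empty numeric vector of finite values.
#' @return Numeric vector of the same length, non-negative, summing to 1.
#' @export
softmax <- function(x) {
  if (length(x) == 0L) {
    pg_stop("pg_empty_input_error", "`x` must be non-empty")
  }
  e <- exp(x - max(x))
  e / sum(e)
}

#' Fully connected (dense) layer application
#'
#' Computes `activation(W x + b)`.
#'
#' @param x Numeric input vector.
#' @param W Numeric weight matrix with `length(x)` columns.
#' @param b Numeric bias vector with `nrow(W)` entries.
#' @param activation One of `"linear"`, `"relu"`, `"tanh"`, `"sigmoid"`,
#'   `"softmax"`.
#' @return Numeric output vector of length `nrow(W)`.
#' @export
dense <- function(x, W, b, activation = c("linear", "relu", "tanh",
                                          "sigmoid", "softmax")) {
  activation <- match.arg(activation)
  if (!is.matrix(W) || ncol(W) != length(x)) {
    pg_stop("pg_shape_error", "`W` must have %d columns, has %s",
            length(x), if (is.matrix(W)) ncol(W) else "none")
  }
  if (length(b) != nrow(W)) {
    pg_stop("pg_shape_error", "`b` must have length %d (rows of W)", nrow(W))
  }
  y <- drop(W %*% x) + b
  switch(activation,
         linear = y,
         relu = relu(y),
         tanh = tanh(y),
         sigmoid = sigmoid(y),
         softmax = softmax(y))
}
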