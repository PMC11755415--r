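# Independent brute-force references. These deliberately use plain scalar
# loops (no vectorisation shared with the implementation) so they act as
# independent oracles for the numerical primitives.

oracle_conv2d <- function(M, N, stride = 1L, padding = 0L) {
  if (padding > 0) {
    P <- matrix(0, nrow(M) + 2 * padding, ncol(M) + 2 * padding)
    P[padding + seq_len(nrow(M)), padding + seq_len(ncol(M))] <- M
    M <- P
  }
  no <- nrow(M) - nrow(N) + 1L
  mo <- ncol(M) - ncol(N) + 1L
  G <- matrix(0, no, mo)
  for (x in seq_len(no)) {
    for (y in seq_len(mo)) {
      acc <- 0
      for (i in seq_len(nrow(N))) {
        for (j in seq_len(ncol(N))) {
          acc <- acc + M[x + i - 1L, y + j - 1L] * N[i, j]
        }
      }
      G[x, y] <- acc
    }
  }
  G[seq(1, no, by = stride), seq(1, mo, by = stride), drop = FALSE]
}

oracle_max_pool <- function(M, w = 2L) {
  no <- nrow(M) %/% w
  mo <- ncol(M) %/% w
  G <- matrix(0, no, mo)
  for (i in seq_len(no)) {
    for (j in seq_len(mo)) {
      best <- -Inf
      for (a in seq_len(w)) {
        for (b in seq_len(w)) {
          v <- M[(i - 1L) * w + a, (j - 1L) * w + b]
          if (v > best) best <- v
        }
      }
      G[i, j] <- best
    }
  }
  G
}

# scalar-loop LSTM step on plain vectors/matrices
oracle_lstm_cell <- function(x, h_prev, C_prev, p) {
  H <- length(h_prev)
  z <- c(h_prev, x)
  sig <- function(v) 1 / (1 + exp(-v))
  lin <- function(W, b) {
    out <- numeric(H)
    for (r in seq_len(H)) {
      acc <- b[r]
      for (c in seq_along(z)) acc <- acc + W[r, c] * z[c]
      out[r] <- acc
    }
    out
  }
  i <- sig(lin(p$W_i, p$b_i))
  ctil <- tanh(lin(p$W_c, p$b_c))
  f <- sig(lin(p$W_f, p$b_f))
  C <- f * C_prev + i * ctil
  o <- sig(lin(p$W_o, p$b_o))
  list(C = C, h = o * tanh(C))
}

oracle_mae <- function(a, b) {
  acc <- 0
  for (i in seq_along(a)) acc <- acc + abs(a[i] - b[i])
  acc / length(a)
}

oracle_rmse <- function(a, b) {
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  sqrt(acc / length(a))
}

oracle_euclid <- function(a, b) {
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  sqrt(acc)
}

oracle_colmean <- function(M) {
  out <- numeric(ncol(M))
  for (j in seq_len(ncol(M))) {
    acc <- 0
    for (i in seq_len(nrow(M))) acc <- acc + M[i, j]
    out[j] <- acc / nrow(M)
  }
  out
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# small dataset used by several test files
tiny_dataset <- function(n_subjects = 3L, duration_s = 20, fs = 50,
                         seed = 11L, noise_sd = 0.05, coupling = 1) {
  cfg <- sim_config(n_subjects = n_subjects, duration_s = duration_s,
                    fs = fs, noise_sd = noise_sd,
                    coupling_strength = coupling, seed = seed)
  make_dataset(cfg, window_s = 4, stride_s = 2)
}
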