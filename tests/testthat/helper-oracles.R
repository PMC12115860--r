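# Brute-force oracle for the Sj-window background predictor: an explicit
# double loop over the 40 offsets, independent of the vectorized
# implementation. Border offsets are clipped and the weight renormalized.
oracle_predict <- function(f, m, n) {
  vals <- c()
  for (l in -3:3) {
    for (k in -3:3) {
      if (abs(l) <= 1 && abs(k) <= 1) next
      mm <- m - l
      nn <- n - k
      if (mm >= 1 && mm <= nrow(f) && nn >= 1 && nn <= ncol(f)) {
        vals <- c(vals, f[mm, nn])
      }
    }
  }
  mean(vals)
}

oracle_predict_all <- function(f) {
  y <- matrix(NA_real_, nrow(f), ncol(f))
  for (m in seq_len(nrow(f))) {
    for (n in seq_len(ncol(f))) {
      y[m, n] <- oracle_predict(f, m, n)
    }
  }
  y
}

# sliding-window correlation with the [-1, 0, 1]/2 stencil, as an
# independent check of the central-difference gradient
oracle_central_diff <- function(g) {
  n <- length(g)
  out <- rep(NA_real_, n)
  for (k in 2:(n - 1)) {
    out[k] <- sum(c(-1, 0, 1) / 2 * g[(k - 1):(k + 1)])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_gray <- function(M, N, seed) {
  withr::with_seed(seed, gray_image(matrix(stats::runif(M * N), M, N)))
}
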