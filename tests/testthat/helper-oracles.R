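# Brute-force I-DT oracle: naive window growing with dispersion recomputed
# from scratch at every step (O(n^2)); intentionally simple and independent
# of the package's optimised implementation.
oracle_idt <- function(t, x, y, min_dur = 0.1, max_disp = 2) {
  n <- length(t)
  disp <- function(i, j)
    (max(x[i:j]) - min(x[i:j])) + (max(y[i:j]) - min(y[i:j]))
  fix <- list()
  i <- 1
  while (i <= n) {
    j <- i
    while (j <= n && t[j] - t[i] < min_dur - 1e-9) j <- j + 1
    if (j > n) break
    if (disp(i, j) > max_disp + 1e-9) { i <- i + 1; next }
    while (j + 1 <= n && disp(i, j + 1) <= max_disp + 1e-9) j <- j + 1
    fix[[length(fix) + 1]] <- c(start = i, end = j)
    i <- j + 1
  }
  if (length(fix)) do.call(rbind, fix)
  else matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
}

# random gaze-like test trace: alternating stable clusters and fast moves
random_trace <- function(n_samples, seed, rate = 60) {
  set.seed(seed)
  t <- (seq_len(n_samples) - 1) / rate
  x <- numeric(n_samples); y <- numeric(n_samples)
  i <- 1
  px <- 0; py <- 0
  while (i <= n_samples) {
    len <- sample(3:30, 1)
    len <- min(len, n_samples - i + 1)
    if (runif(1) < 0.55) {          # stable cluster
      x[i:(i + len - 1)] <- px + rnorm(len, 0, 0.2)
      y[i:(i + len - 1)] <- py + rnorm(len, 0, 0.2)
    } else {                        # fast ramp to a new location
      nx <- runif(1, -30, 30); ny <- runif(1, -30, 30)
      x[i:(i + len - 1)] <- seq(px, nx, length.out = len)
      y[i:(i + len - 1)] <- seq(py, ny, length.out = len)
      px <- nx; py <- ny
    }
    i <- i + len
  }
  data.frame(t = t, x = x, y = y, valid = TRUE)
}

# constant-gaze trace helper
stable_trace <- function(n, x0 = 0, y0 = 0, rate = 60, t0 = 0) {
  data.frame(t = t0 + (seq_len(n) - 1) / rate, x = x0, y = y0, valid = TRUE)
}
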