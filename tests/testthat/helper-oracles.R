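# Independent oracles kept deliberately different in form from the package
# implementation.

# Joseph-form textbook Kalman step (numerically distinct covariance update,
# explicit solve of the innovation system instead of an inverse-times product)
oracle_kalman_step <- function(x, P, y, A, C, Q, R) {
  xp <- A %*% x
  Pp <- A %*% P %*% t(A) + Q
  S <- C %*% Pp %*% t(C) + R
  K <- t(solve(S, C %*% Pp))          # Pp C' S^-1 via solve on the transpose
  xn <- xp + K %*% (y - C %*% xp)
  IKC <- diag(nrow(Pp)) - K %*% C
  Pn <- IKC %*% Pp %*% t(IKC) + K %*% R %*% t(K)   # Joseph form
  list(x = as.vector(xn), P = (Pn + t(Pn)) / 2)
}

# scalar Kalman filter recursion for one decoupled state
oracle_scalar_kalman <- function(y, x0, p0, q, r) {
  x <- numeric(length(y))
  xc <- x0; pc <- p0
  for (k in seq_along(y)) {
    pp <- pc + q
    g <- pp / (pp + r)
    xc <- xc + g * (y[k] - xc)
    pc <- (1 - g) * pp
    x[k] <- xc
  }
  x
}

# batch low-pass via signal::filter applied section by section
oracle_batch_lowpass <- function(x, design) {
  y <- x
  for (s in seq_len(nrow(design$sos))) {
    b <- design$sos[s, 1:3]
    a <- c(1, design$sos[s, 5:6])
    y <- as.numeric(signal::filter(b, a, y))
  }
  y
}

# brute-force best balanced accuracy over a dense threshold grid
oracle_best_balanced_accuracy <- function(scores, labels, n_grid = 20000L) {
  grid <- seq(min(scores) - 1, max(scores) + 1, length.out = n_grid)
  grid <- sort(unique(c(grid, scores, scores - 1e-9, scores + 1e-9)))
  npos <- sum(labels); nneg <- sum(!labels)
  max(vapply(grid, function(t) {
    pred <- scores >= t
    (sum(pred & labels) / npos + sum(!pred & !labels) / nneg) / 2
  }, numeric(1)))
}
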