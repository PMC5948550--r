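test_that("default noise matrices are the squared printed values", {
  nz <- default_noise()
  expect_equal(nz$Q[1, 1], 1e-6)
  expect_equal(diag(nz$Q), rep(1e-6, 4), ignore_attr = TRUE)
  expect_equal(diag(nz$R), c(2.5e-3, 2.5e-3, 2.5e-3, 1e-4), ignore_attr = TRUE)
  expect_equal(nz$Q[upper.tri(nz$Q)], rep(0, 6))
  expect_equal(nz$R[upper.tri(nz$R)], rep(0, 6))
})

test_that("initialization seeds the vertical state and bias at -1 G", {
  st <- kalman_init(kalman_config())
  expect_equal(st$x, c(0, -256, 0, 0))
  expect_equal(st$bay, -256)
  expect_identical(st$P, kalman_config()$Q)
  # uninformative option
  st0 <- kalman_init(kalman_config(init = "zero"))
  expect_equal(st0$x, rep(0, 4))
  expect_equal(st0$bay, 0)
  expect_true(isSymmetric(st0$P))
  # non-PSD covariances are rejected
  expect_error(kalman_config(Q = diag(c(-1, 1, 1, 1))), "positive semi-definite")
})

test_that("a constant measurement equal to the state is a fixed point", {
  cfg <- kalman_config(init = "zero")
  st <- kalman_init(cfg)
  st$x <- c(10, 10, 10, 10)
  for (k in 1:50) st <- kalman_step(st, c(10, 10, 10, 10), cfg)
  expect_equal(st$x, c(10, 10, 10, 10), tolerance = 1e-12)
})

test_that("process noise dominating measurement noise makes states track data", {
  cfg <- kalman_config(Q = diag(4) * 1e6, R = diag(4) * 1e-6, init = "zero")
  set.seed(6)
  y <- matrix(rnorm(200 * 3, 0, 100), 200, 3)
  kal <- run_kalman(y, cfg)
  expect_lt(max(abs(kal$states[, 1:3] - y)) / max(abs(y)), 0.01)
})

test_that("single steps agree with a Joseph-form textbook filter to 1e-9", {
  cfg <- kalman_config()
  set.seed(7)
  worst <- 0
  for (i in 1:1000) {
    x <- rnorm(4, 0, 100)
    Pr <- matrix(rnorm(16), 4)
    P <- Pr %*% t(Pr) + diag(4) * 0.1
    y <- rnorm(4, 0, 100)
    st <- list(x = x, P = P)
    got <- kalman_step(st, y, cfg)
    ref <- oracle_kalman_step(x, P, y, cfg$A, cfg$C, cfg$Q, cfg$R)
    worst <- max(worst, max(abs(got$x - ref$x)), max(abs(got$P - ref$P)))
  }
  expect_lt(worst, 1e-9)
  # the documented one-step example: rest-noise matrices, uninformative start
  st <- list(x = rep(0, 4), P = cfg$Q)
  got <- kalman_step(st, rep(10, 4), cfg)
  ref <- oracle_kalman_step(rep(0, 4), cfg$Q, rep(10, 4),
                            cfg$A, cfg$C, cfg$Q, cfg$R)
  expect_equal(got$x, ref$x, tolerance = 1e-12)
})

test_that("full trajectories agree with the textbook filter to 1e-9", {
  cfg <- kalman_config()
  set.seed(8)
  worst <- 0
  for (rep in 1:100) {
    n <- 200
    y <- matrix(rnorm(n * 4, 0, 50), n, 4)
    st <- list(x = rnorm(4, 0, 10), P = diag(4) * abs(rnorm(1, 1, 0.5)))
    ox <- st$x; oP <- st$P
    for (k in seq_len(n)) {
      st <- kalman_step(st, y[k, ], cfg)
      ref <- oracle_kalman_step(ox, oP, y[k, ], cfg$A, cfg$C, cfg$Q, cfg$R)
      ox <- ref$x; oP <- ref$P
      worst <- max(worst, max(abs(st$x - ox)))
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("with diagonal noise the first three states are scalar filters", {
  cfg <- kalman_config()
  set.seed(9)
  y <- matrix(rnorm(300 * 3, -200, 60), 300, 3)
  kal <- run_kalman(y, cfg)
  for (a in 1:3) {
    x0 <- if (a == 2) -256 else 0
    ref <- oracle_scalar_kalman(y[, a], x0, cfg$Q[a, a],
                                cfg$Q[a, a], cfg$R[a, a])
    expect_lt(max(abs(kal$states[, a] - ref)), 1e-9)
  }
})

test_that("the covariance stays symmetric positive semi-definite", {
  cfg <- kalman_config()
  st <- kalman_init(cfg)
  set.seed(10)
  for (k in 1:300) {
    st <- kalman_advance(st, rnorm(3, -100, 150), cfg)
    expect_identical(st$P, t(st$P))
    ev <- eigen(st$P, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-9)
  }
})

test_that("x4 is zero-bias on a synthetic walk after warm-up", {
  rec <- gen_recording(synth_spec("walk", gait_period_s = 0.8,
                                  gait_amplitude_bits = 40, seed = 3))
  tr <- compute_features(rec)
  m <- mean(tr$x4[51:nrow(tr)])
  expect_gte(m, -5)
  expect_lte(m, 5)
})

test_that("the bias tracker averages the last second of the vertical state", {
  cfg <- kalman_config(bias_window = 25L)
  st <- kalman_init(cfg)
  x2s <- numeric(0)
  set.seed(11)
  for (k in 1:40) {
    st <- kalman_advance(st, c(0, -256 + rnorm(1, 0, 20), 0), cfg)
    x2s <- c(x2s, st$x[2])
    expected <- mean(utils::tail(x2s, 25))
    expect_equal(st$bay, expected)
  }
})

test_that("the tuning schedule starts at identity and flattens monotonically", {
  rec <- gen_recording(synth_spec("jog_trip_fall", duration_s = 15, seed = 4))
  rep <- tune_heuristic(rec)
  expect_gte(nrow(rep), 3L)
  expect_equal(rep$q_std_xyz[1], 1)
  # first adjustment shrinks the Q standard deviation by 10 -> variance (1/10)^2
  expect_equal(rep$q_std_xyz[2], 1 / 10)
  expect_equal(rep$stage[2], "Q_xyz")
  # each Q shrink flattens the orientation states relative to the step before
  qsteps <- which(rep$stage == "Q_xyz")
  expect_true(all(rep$flatness[qsteps] <= rep$flatness[qsteps - 1] + 1e-9))
  # too-short recordings are rejected
  short <- gen_recording(synth_spec("walk", duration_s = 5, seed = 1))
  expect_error(tune_heuristic(short), "too short")
})
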