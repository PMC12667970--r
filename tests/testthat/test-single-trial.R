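test_that("trial bias input is the basis image of the trial's coefficients", {
  net <- toy_network(N = 12, P = 4)
  Tm <- matrix(rnorm(12), 4, 3)
  expect_equal(trial_bias_input(matrix(0, 4, 3), 2, net$U), rep(0, 12))
  e1 <- c(1, 0, 0, 0)
  expect_equal(trial_bias_input(matrix(e1, 4, 1), 1, net$U), net$U[, 1])
  # explicit double-sum oracle
  k <- 3
  oracle <- vapply(1:12, function(i) sum(net$U[i, ] * Tm[, k]), numeric(1))
  expect_equal(trial_bias_input(Tm, k, net$U), oracle, tolerance = 1e-12)
  expect_error(trial_bias_input(Tm, 4, net$U), "out of range")
})

test_that("epoch-average loss matches the offset formula and is permutation-invariant", {
  set.seed(50)
  K <- 3; Tn <- 20; N <- 4
  time <- seq(-2, -0.1, length.out = Tn)
  epochs <- list(a = c(-2, -1), b = c(-1, 0))
  data <- array(rnorm(K * Tn * N), dim = c(K, Tn, N))
  expect_equal(epoch_average_loss(data, data, time, epochs), 0)
  # constant offset delta: E * K * N * delta^2
  delta <- 0.7
  expect_equal(epoch_average_loss(data + delta, data, time, epochs),
               2 * K * N * delta^2, tolerance = 1e-10)
  # permuting time bins within an epoch leaves the loss unchanged
  idx1 <- which(time >= -2 & time < -1)
  perm <- data
  perm[, idx1, ] <- perm[, sample(idx1), ]
  model <- array(rnorm(K * Tn * N), dim = c(K, Tn, N))
  expect_equal(epoch_average_loss(model, perm, time, epochs),
               epoch_average_loss(model, data, time, epochs),
               tolerance = 1e-10)
  expect_error(epoch_average_loss(data, data, time, list(c(5, 6))), "empty")
})

test_that("projection loss sees only the coding-axis components", {
  set.seed(51)
  K <- 2; Tn <- 15; N <- 8
  U <- qr.Q(qr(matrix(rnorm(N * 4), N, 4)))
  dims <- U[, 1:3]
  data <- array(rnorm(K * Tn * N), dim = c(K, Tn, N))
  expect_equal(projection_loss(data, data, dims, dims), 0)
  # adding activity orthogonal to the axes changes nothing
  perp <- U[, 4]
  model <- data
  for (k in 1:K) model[k, , ] <- model[k, , ] + outer(rnorm(Tn), perp)
  expect_equal(projection_loss(model, data, dims, dims), 0, tolerance = 1e-20)
  # sign-flipped axis: loss = sum over that axis of (2 proj)^2
  flipped <- dims; flipped[, 2] <- -flipped[, 2]
  expected <- 0
  for (k in 1:K) expected <- expected + sum((2 * data[k, , ] %*% dims[, 2])^2)
  expect_equal(projection_loss(data, data, flipped, dims), expected,
               tolerance = 1e-8)
})

test_that("jittered start times are uniform on [-4.35, -2.35] and seeded", {
  s1 <- jittered_start(1e4, seed = 9)
  s2 <- jittered_start(1e4, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(s1 >= -4.35 & s1 <= -2.35))
  se <- sqrt(2^2 / 12) / sqrt(1e4)
  expect_lt(abs(mean(s1) - (-3.35)), 3 * se)
})

test_that("frozen-network bias fitting recovers planted biases", {
  gt <- make_ground_truth(40, 5, 3, seed = 52, bias_scale = 0.4,
                          noise_sd = 1.5)
  # unsmoothed observations isolate the bias-recovery machinery from the
  # systematic distortion of the 50 ms measurement filter
  d <- generate_recordings(gt, 8, dt = 0.01, smooth = FALSE)
  fit <- list(network = gt$network, spec = gt$spec)
  out <- fit_test_trial_biases(fit, d, c_reg = 0.01, measurement_filter = FALSE,
                               opt = optimizer_config(learning_rate = 0.03,
                                                      max_iterations = 600))
  # compare recovered and planted biases as input vectors in neural space
  cs <- vapply(seq_len(ncol(d$bias)), function(k) {
    a <- gt$network$U %*% d$bias[, k]
    b <- gt$network$U %*% out$trial_bias$T_matrix[, k]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  expect_gt(median(cs), 0.7)
  expect_gt(out$explained_variance, 0.5)
  # network untouched by construction: bias fit returns biases only
  expect_identical(fit$network, gt$network)
})

test_that("strong bias regularisation shrinks the fitted biases", {
  gt <- make_ground_truth(25, 4, 3, seed = 53, bias_scale = 0.3,
                          noise_sd = 1)
  d <- generate_recordings(gt, 4, dt = 0.01)
  fit <- list(network = gt$network, spec = gt$spec)
  opt <- optimizer_config(learning_rate = 0.02, max_iterations = 150)
  n_lo <- sum(fit_test_trial_biases(fit, d, c_reg = 0.01,
                                    opt = opt)$trial_bias$T_matrix^2)
  n_mid <- sum(fit_test_trial_biases(fit, d, c_reg = 10,
                                     opt = opt)$trial_bias$T_matrix^2)
  n_hi <- sum(fit_test_trial_biases(fit, d, c_reg = 1e8,
                                    opt = opt)$trial_bias$T_matrix^2)
  expect_gt(n_lo, n_mid)
  expect_gt(n_mid, n_hi)
  expect_lt(n_hi, 1e-2)
})

test_that("joint single-trial training tracks planted biases and stays finite", {
  gt <- make_ground_truth(25, 4, 3, seed = 54, bias_scale = 0.5,
                          noise_sd = 1)
  d <- generate_recordings(gt, 6, dt = 0.01, span = c(-2.2, 0.3),
                           smooth = FALSE)
  # basis = the generating network's own coding columns, so the truth is a
  # consistent optimum of every loss term
  basis <- orthogonalize_basis(gt$network$U[, 1:3], source = "model-derived")
  fit <- train_single_trial(d, basis, P = 4,
                            init = list(network = gt$network,
                                        spec = gt$spec),
                            opt = optimizer_config(learning_rate = 8e-3,
                                                   max_iterations = 800,
                                                   checkpoint_every = 50),
                            jitter = TRUE, activation_frac = 2,
                            measurement_filter = FALSE)
  expect_true(all(is.finite(fit$trial_bias$T_matrix)))
  cs <- vapply(seq_len(ncol(d$bias)), function(k) {
    a <- gt$network$U %*% d$bias[, k]
    b <- fit$network$U %*% fit$trial_bias$T_matrix[, k]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  expect_gt(median(cs), 0.5)
})

test_that("error-axis decoder recovers a planted hit/miss offset", {
  set.seed(55)
  P <- 6; n_hit <- 60; n_miss <- 25
  offset <- rnorm(P); offset <- offset / sqrt(sum(offset^2))
  # hits and misses sit on opposite sides of the origin along the offset:
  # a no-intercept decoder's boundary passes through the origin, so this is
  # the separable configuration it can express
  make_side <- function() {
    hits <- matrix(rnorm(P * n_hit, sd = 0.3), P, n_hit) - offset
    miss <- matrix(rnorm(P * n_miss, sd = 0.3), P, n_miss) + offset
    cbind(hits, miss)
  }
  Tm <- cbind(make_side(), make_side())
  cond <- rep(c("left", "right"), each = n_hit + n_miss)
  out <- rep(rep(c(1L, 0L), c(n_hit, n_miss)), 2)
  tb <- trial_bias(Tm, cond, out)
  ax <- estimate_error_axis(tb, n_boot = 50, seed = 3)
  for (side in c("left", "right")) {
    expect_gt(abs(sum(ax$weights[, side] * offset)), 0.95)
    expect_gt(ax$accuracy[side], 0.8)
  }
  expect_true(all(is.finite(ax$bootstrap_sd)))
  # label permutation gives chance-level accuracy
  set.seed(56)
  tb_null <- trial_bias(Tm, cond, sample(out))
  ax0 <- estimate_error_axis(tb_null, n_boot = 0, seed = 4)
  expect_lt(mean(ax0$accuracy), 0.75)
  expect_error(estimate_error_axis(trial_bias(Tm, cond, rep(1L, ncol(Tm)))),
               "both hit and miss")
})

test_that("stratified splits preserve class ratios", {
  ns <- asNamespace("latentloop")
  set.seed(57)
  y <- rep(c(0, 1), c(20, 60))
  sp <- ns$stratified_split(y, 0.8)
  expect_equal(sum(y[sp$train] == 0), 16)
  expect_equal(sum(y[sp$train] == 1), 48)
  expect_equal(length(sp$test), 16)
})

test_that("error-axis interpolation endpoints are the pure components", {
  set.seed(58)
  ax <- rnorm(6); ax <- ax / sqrt(sum(ax^2))
  C <- 3
  coding <- c(ax[1:3], 0, 0, 0); coding <- coding / sqrt(sum(coding^2))
  residual <- c(0, 0, 0, ax[4:6]); residual <- residual / sqrt(sum(residual^2))
  expect_equal(interpolate_error_axis(ax, -1, C), coding, tolerance = 1e-12)
  expect_equal(interpolate_error_axis(ax, 1, C), residual, tolerance = 1e-12)
  expect_equal(interpolate_error_axis(ax, 0, C), ax, tolerance = 1e-12)
  expect_equal(sum(interpolate_error_axis(ax, 0.37, C)^2), 1,
               tolerance = 1e-12)
  expect_error(interpolate_error_axis(ax, 1.5, C), "alpha")
})
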