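test_that("zero-magnitude perturbation reproduces the unperturbed run", {
  gt <- make_ground_truth(25, 4, 3, seed = 20)
  base <- simulate_trial(gt$network, gt$spec, "left", span = c(-3, 0.9),
                         go_shift = Inf)
  pert <- perturb_dimension(gt$network, gt$spec, "left", dim_index = 2,
                            g = 0)
  expect_equal(pert$rates, base$rates, tolerance = 1e-14)
})

test_that("small perturbations respond linearly in g", {
  gt <- make_ground_truth(25, 4, 3, seed = 21)
  base <- simulate_trial(gt$network, gt$spec, "left", span = c(-3, -0.9),
                         go_shift = Inf)
  dev <- function(g) {
    p <- perturb_dimension(gt$network, gt$spec, "left", dim_index = 1,
                           g = g, window = c(-1.2, -1.1), span = c(-3, -0.9))
    max(abs(p$rates - base$rates))
  }
  g <- 1e-4
  ratio <- dev(g) / dev(g / 2)
  expect_equal(ratio, 2, tolerance = 1e-3)
})

test_that("random orthogonal directions are unit, seeded, and outside span(U)", {
  net <- toy_network(N = 20, P = 4, seed = 22)
  d1 <- orthocomplement_direction(net$U, seed = 7)
  d2 <- orthocomplement_direction(net$U, seed = 7)
  expect_identical(d1, d2)
  expect_equal(sum(d1^2), 1, tolerance = 1e-12)
  expect_lt(max(abs(crossprod(net$U, d1))), 1e-8)
})

test_that("flip counting follows the margin rule and the enumeration oracle", {
  # epsilon = 0.25 * (1 - (-1)) = 0.5
  fr <- flip_rate(-1, 1, xhat_L = 0.9)
  expect_equal(fr$epsilon, 0.5)
  expect_equal(fr$flips_to_right, 1)
  expect_equal(fr$rate, 1)
  fr2 <- flip_rate(-1, 1, xhat_L = -1)
  expect_equal(fr2$rate, 0)
  expect_error(flip_rate(1, 1, 0.5), "degenerate")
  # grid of 40 endpoints against a brute-force count
  xL <- -2; xR <- 2; eps <- 0.25 * (xR - xL)
  set.seed(23)
  hatL <- runif(20, -3, 3); hatR <- runif(20, -3, 3)
  manual <- sum(abs(hatL - xR) < eps) + sum(abs(hatR - xL) < eps)
  fr3 <- flip_rate(xL, xR, hatL, hatR)
  expect_equal(fr3$flips_to_right + fr3$flips_to_left, manual)
  expect_equal(fr3$rate, manual / 40)
})

test_that("flip rate is monotone in |g| on the bistable toy and zero at g = 0", {
  toy <- bistable_toy()
  net <- toy$net; spec <- toy$spec
  span <- c(-1.6, 0.9)
  bl <- simulate_trial(net, spec, "left", span = span, go_shift = Inf)
  br <- simulate_trial(net, spec, "right", span = span, go_shift = Inf)
  xL <- choice_endpoint(bl, net$U[, 2])
  xR <- choice_endpoint(br, net$U[, 2])
  expect_lt(xR * xL, 0)  # two basins with opposite signs
  sgn <- sign(xL)
  rate_at <- function(g) {
    pl <- perturb_dimension(net, spec, "left", dim_index = 2, g = g,
                            window = c(-1.1, -1.0), span = span)
    pr <- perturb_dimension(net, spec, "right", dim_index = 2, g = g,
                            window = c(-1.1, -1.0), span = span)
    flip_rate(xL, xR, choice_endpoint(pl, net$U[, 2]),
              choice_endpoint(pr, net$U[, 2]))$rate
  }
  rates <- vapply(-sgn * c(0, 1, 4, 12), rate_at, numeric(1))
  expect_equal(rates[1], 0)
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[4], 0.5)  # the signed pulse flips exactly one side
})

test_that("flip-rate sweep has the protocol shape and symmetry", {
  toy <- bistable_toy()
  net <- toy$net; spec <- toy$spec
  mags <- c(-8, 0, 8)
  sweep <- flip_rate_sweep(net, spec, n_windows = 3, magnitudes = mags,
                           dims = 1:2, span = c(-1.6, 0.9), dt = 0.005,
                           choice_axis = net$U[, 2])
  expect_equal(dim(sweep), c(2, 3, 3))
  expect_true(all(sweep[, , 2] == 0))  # g = 0 column
  # odd-symmetric toy: +g on left matches -g on right, so cell rates agree
  expect_equal(sweep[, , 1], sweep[, , 3], tolerance = 1e-12)
})

test_that("neuron ranking follows |loading| with index tie-breaks", {
  U <- cbind(c(0, 0, 0, 1), c(0.2, -0.9, 0.2, 0.1))
  expect_equal(rank_neurons(U, "choice")[1], 2L)
  expect_equal(rank_neurons(U, 1L)[1], 4L)
  # ties: equal |loading| resolved by lower index
  expect_equal(rank_neurons(U, "choice")[2:3], c(1L, 3L))
  set.seed(24)
  U2 <- matrix(rnorm(40), 20, 2)
  expect_equal(rank_neurons(U2, "choice"), order(-abs(U2[, 2])))
})

test_that("top-K perturbation delivers alpha/K per neuron and reports separation", {
  gt <- make_ground_truth(25, 4, 3, seed = 25)
  rk <- rank_neurons(gt$network$U, "choice")
  for (K in c(1, 5, 12)) {
    out <- perturb_topk_neurons(gt$network, gt$spec, rk, K = K, alpha = 10)
    expect_equal(sum(out$input), 10)
    expect_equal(sum(out$input > 0), K)
    expect_equal(max(out$input), 10 / K)
  }
  # unperturbed separation equals the baseline choice selectivity
  base <- perturb_topk_neurons(gt$network, gt$spec, rk, K = 1, alpha = 0)
  bl <- simulate_trial(gt$network, gt$spec, "left")
  br <- simulate_trial(gt$network, gt$spec, "right")
  idx <- bl$time >= -0.1 & bl$time < 0
  sep <- abs(mean((bl$rates[idx, ] - br$rates[idx, ]) %*% gt$network$U[, 2]))
  expect_equal(base$separation, sep, tolerance = 1e-10)
})

test_that("feedforward toy's impulse response matches the two-exponential closed form", {
  # two neurons, identity basis, lower-triangular interaction: mode 1 decays
  # and drives mode 2 through the feedforward weight w (Schur form already)
  a11 <- -0.5; a22 <- -1.5; w <- 4
  A <- matrix(c(a11, 0, w, a22), 2, 2, byrow = TRUE)
  rmax <- c(12, 16); tau <- 0.04
  net <- lowrank_network(diag(2), A, rmax, tau = tau, C = 1)
  spec <- input_spec(2, 2)
  fp <- find_fixed_point(net, spec, "left", span_start = -1, polish = TRUE)
  rstar <- fp$state
  h <- as.numeric(A %*% rstar)
  d <- transfer_gain(h, rmax)
  l1 <- (-1 + d[1] * a11) / tau
  l2 <- (-1 + d[2] * a22) / tau
  delta <- 1e-5
  tr <- simulate_trial(net, spec, "left", span = c(0, 0.3), dt = 0.001,
                       init = rstar + c(delta, 0), go_shift = Inf,
                       method = "rk4")
  resp <- (tr$rates[, 2] - rstar[2]) / delta
  tt <- tr$time
  closed <- (d[2] * w / tau) * (exp(l1 * tt) - exp(l2 * tt)) / (l1 - l2)
  expect_lt(max(abs(resp - closed)), 1e-4)
  # the peak transient exceeds the direct (unamplified) response scale
  expect_gt(max(abs(closed)), 1)
})

test_that("upstream residual-like mode flips the bistable readout at lower |g|", {
  toy <- bistable_toy(w = 2.5)
  net <- toy$net; spec <- toy$spec
  span <- c(-1.6, 0.9)
  bl <- simulate_trial(net, spec, "left", span = span, go_shift = Inf)
  br <- simulate_trial(net, spec, "right", span = span, go_shift = Inf)
  xL <- choice_endpoint(bl, net$U[, 2]); xR <- choice_endpoint(br, net$U[, 2])
  sgn <- sign(xL)
  threshold <- function(dim) {
    for (g in seq(0.5, 15, by = 0.5)) {
      p <- perturb_dimension(net, spec, "left", dim_index = dim,
                             g = -sgn * g, window = c(-1.1, -1.0),
                             span = span)
      fr <- flip_rate(xL, xR, choice_endpoint(p, net$U[, 2]))
      if (fr$flips_to_right == 1) return(g)
    }
    Inf
  }
  g_upstream <- threshold(1)
  g_readout <- threshold(2)
  expect_lt(g_upstream, g_readout)
  expect_true(is.finite(g_readout))
})

test_that("perturbations orthogonal to span(U) leave a linear rank-P system unchanged", {
  # A = 0: the recurrent term vanishes, and an orthogonal input moves rates
  # only within the orthocomplement; the latent trajectory is untouched in
  # the linear regime
  N <- 20; P <- 3
  set.seed(26)
  U <- qr.Q(qr(matrix(rnorm(N * P), N, P)))
  net <- lowrank_network(U, matrix(0, P, P), rep(10, N))
  spec <- input_spec(P, N)
  dir <- orthocomplement_direction(U, seed = 2)
  base <- simulate_trial(net, spec, "left", span = c(-2, 0.5), go_shift = Inf)
  pert <- simulate_trial(net, spec, "left", span = c(-2, 0.5), go_shift = Inf,
                         perturbation = list(direction = dir, g = 1e-3,
                                             window = c(-1.2, -1.1)))
  m0 <- project_latent(base, U)$m
  m1 <- project_latent(pert, U)$m
  expect_lt(max(abs(m1 - m0)), 1e-9)
})
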