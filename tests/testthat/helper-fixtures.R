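# Shared fixtures: tiny networks and an independent dense R simulator used
# as oracle against the package's factored C++ integrator.

# plain-R forward Euler with an explicitly materialised N x N connectivity
dense_simulate <- function(J, rmax, tau, init, Ifull, dt) {
  Tn <- nrow(Ifull)
  R <- matrix(0, Tn, length(init))
  R[1, ] <- init
  r <- init
  for (t in seq_len(Tn - 1)) {
    h <- as.numeric(J %*% r) + Ifull[t, ]
    r <- r + dt / tau * (-r + rmax / 2 * (tanh(h) + 1))
    R[t + 1, ] <- r
  }
  R
}

# small deterministic network with mild dynamics
toy_network <- function(N = 12, P = 3, seed = 1, C = min(3L, P)) {
  set.seed(seed)
  U <- qr.Q(qr(matrix(rnorm(N * P), N, P)))
  A <- matrix(rnorm(P * P, sd = 0.05), P, P)
  rmax <- runif(N, 5, 20)
  lowrank_network(U, A, rmax, C = C, orth_tol = 1e-8)
}

# 2-latent toy with a bistable readout mode (index 2) fed by an upstream
# feedforward mode (index 1); gain-normalised couplings
bistable_toy <- function(N = 30, w = 2.5, seed = 4) {
  set.seed(seed)
  rmax <- rep(16, N)
  gbar <- mean(rmax) / 2
  v <- rmax / sqrt(sum(rmax^2))
  X <- matrix(rnorm(N * 2), N, 2)
  X <- X - v %*% (rbind(v) %*% X)
  U <- qr.Q(qr(X))
  At <- matrix(c(-0.5, 0, w, 1.2), 2, 2, byrow = TRUE)  # row2: w*m1 + 1.2*m2
  net <- lowrank_network(U, At / gbar, rmax, C = 1L, orth_tol = 1e-8)
  # odd-symmetric sample drive on the upstream mode tips the readout into
  # opposite basins for the two conditions
  spec <- input_spec(2, N, i_low = c(0.5, 0), i_high = c(-0.5, 0))
  list(net = net, spec = spec)
}

expect_orthonormal <- function(M, tol = 1e-8) {
  expect_lt(norm(diag(ncol(M)) - crossprod(M), "F"), tol)
}
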