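#' Ground-truth networks and synthetic recordings
#'
#' These generators produce a known low-rank network together with simulated
#' "recordings" that mimic the statistical structure of population activity
#' in a delayed-response task: two stimulus conditions, tone pulses followed
#' by a 1.2 s delay, a go cue at time zero, condition-selective ramping along
#' the choice dimension during the delay, slow across-trial drift of the
#' operating point, additive observation noise, and causal exponential
#' smoothing with a 50 ms timescale. Every downstream stage of the package
#' (coding-axis extraction, fitting, perturbation, attractor and single-trial
#' analyses) is testable against these ground truths without any external
#' data.
#'
#' @name synthetic_data
NULL

#' Construct a ground-truth low-rank network
#'
#' Builds a random orthonormal basis \code{U} and an interaction matrix
#' \code{A} engineered so that (i) the sample input tips the choice latent
#' into one of two basins of a saturating positive-feedback loop, giving
#' condition-selective ramping during the delay and two stable
#' condition-specific attractors when the go cue is withheld, and (ii) a
#' residual dimension feeds the choice dimension through an asymmetric
#' (feedforward) coupling, so the interaction matrix is non-normal and
#' residual perturbations can influence the choice. Interaction strengths
#' are expressed in gain-normalised units and divided by the mean baseline
#' gain \eqn{\bar g = \mathrm{mean}(r^{max})/2}, so the effective latent
#' coupling is independent of the firing-rate scale.
#'
#' @param N neuron count.
#' @param P total latent dimensionality.
#' @param C number of coding dimensions (sample, choice, response order);
#'   must satisfy \code{1 <= C <= P <= N}.
#' @param seed integer seed; the construction is fully deterministic given it.
#' @param bias_scale standard deviation of the per-trial latent input bias
#'   (input units; 0.08 default).
#' @param drift_timescale across-trial autocorrelation timescale of the bias,
#'   in trials (AR(1) with correlation \code{exp(-1/drift_timescale)}).
#' @param noise_sd additive observation noise on rates, spikes/s.
#' @param rmax_range range of per-neuron maximum rates, spikes/s.
#' @return a \code{ground_truth} object: list with \code{network}
#'   (a \code{\link{lowrank_network}}), \code{spec} (an
#'   \code{\link{input_spec}}), \code{true_coding_basis} (N x C),
#'   \code{bias_scale}, \code{drift_timescale}, \code{noise_sd}, \code{seed}.
#' @export
make_ground_truth <- function(N, P, C = 3L, seed = 1L,
                              bias_scale = 0.08, drift_timescale = 20,
                              noise_sd = 3, rmax_range = c(10, 30)) {
  N <- as.integer(N); P <- as.integer(P); C <- as.integer(C)
  if (!(1L <= C && C <= P && P <= N))
    stop("dimensions must satisfy 1 <= C <= P <= N")
  if (bias_scale < 0 || noise_sd < 0)
    stop("bias_scale and noise_sd must be nonnegative")
  set.seed(as.integer(seed))
  rmax <- runif(N, rmax_range[1], rmax_range[2])
  gbar <- mean(rmax) / 2
  # Construct U orthogonal to the rmax vector: the zero-input baseline
  # r = rmax/2 then projects to m = 0 and is an exact fixed point, so the
  # choice bistability develops symmetrically around it.
  X <- matrix(rnorm(N * P), N, P)
  if (P < N) {
    v <- rmax / sqrt(sum(rmax^2))
    X <- X - v %*% (rbind(v) %*% X)
  }
  U <- qr.Q(qr(X))

  # gain-normalised latent couplings (see vignette for the regime)
  At <- diag(-0.4, P)
  At[1, 1] <- -0.6            # sample latent: leaky integrator of the tones
  At[2, 2] <- 1.15            # choice latent: weakly unstable -> bistable
  At[2, 1] <- 0.9             # sample feeds the choice latent
  if (C >= 3) {
    At[3, 3] <- -0.7          # response latent: fast, driven by the go cue
    At[3, 2] <- 1.2           # choice biases the response
  }
  i_low <- numeric(P); i_high <- numeric(P); i_go <- numeric(P)
  i_low[1] <- 1.2; i_high[1] <- -1.2
  if (C >= 3) i_go[3] <- 1.5    # go cue drives the response latent
  if (P > C) {
    # residual dimensions are active but weakly selective: a slow
    # condition-independent ramp and a fast, mildly selective transient,
    # both feeding the choice latent through asymmetric (feedforward)
    # couplings, so the interaction matrix is non-normal and the residual
    # subspace shapes the condition-averaged trajectories
    r1 <- C + 1
    At[r1, r1] <- 0.85          # slow mode (effective rate -0.15/tau)
    At[2, r1] <- 0.25
    i_low[r1] <- 0.25; i_high[r1] <- 0.25
    if (P > C + 1) {
      r2 <- C + 2
      At[r2, r2] <- -0.3
      At[2, r2] <- 0.5
      At[r1, r2] <- 0.4
      i_low[r2] <- 0.4; i_high[r2] <- -0.4
    }
    if (P > C + 2) for (j in (C + 3):P) At[j, j] <- -0.5
  }
  # Exact gain compensation: with G = U' diag(rmax/2) U the baseline
  # linearisation of the latent dynamics is tau dm/dt = (-I + At) m, so the
  # designed couplings hold for every random draw of U and rmax (a plain
  # 1/mean-gain scaling leaves O(1/sqrt(N)) seed-dependent coupling
  # fluctuations that can rival the design at small N).
  A <- At / gbar  # fallback scale
  G <- crossprod(U, U * (rmax / 2))
  A <- tryCatch(solve(G, At), error = function(e) At / gbar)
  net <- lowrank_network(U, A, rmax, tau = 0.040, C = C, orth_tol = 1e-8)

  # proprioceptive lick feedback after the go cue, distinct per choice, so
  # the response epoch carries selectivity independent of the delay-period
  # choice signal
  zL <- rnorm(N); zR <- rnorm(N)
  lick_left <- 0.5 * zL / sqrt(sum(zL^2))
  lick_right <- 0.5 * zR / sqrt(sum(zR^2))
  lick_rate <- function(t) ifelse(t > 0, 7 * (1 - exp(-t / 0.1)), 0)
  # gain-compensate the latent inputs the same way, so the effective latent
  # drive G i equals gbar times the designed vector
  comp <- function(v) tryCatch(gbar * solve(G, v), error = function(e) v)
  spec <- input_spec(P, N, i_low = comp(i_low), i_high = comp(i_high),
                     i_go = comp(i_go),
                     lick_left = lick_left, lick_right = lick_right,
                     lick_rate = lick_rate)

  # The recoverable coding basis: LDA axes of the noiseless condition
  # averages (what the coding-axes pipeline converges to as trials grow),
  # not the raw columns of U -- the choice latent already saturates during
  # the sample period, so the discriminant directions mix the latent
  # coordinates.
  true_basis <- if (C == 3L) noiseless_coding_basis(net, spec)
                else U[, seq_len(C), drop = FALSE]

  structure(list(network = net, spec = spec,
                 true_coding_basis = true_basis,
                 bias_scale = bias_scale, drift_timescale = drift_timescale,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> seed %d, noise_sd = %g sp/s, bias_scale = %g, drift over %g trials\n",
              x$seed, x$noise_sd, x$bias_scale, x$drift_timescale))
  print(x$network)
  invisible(x)
}

# LDA coding axes of the deterministic condition-averaged trajectories,
# passed through the same 50 ms smoothing the recordings receive
noiseless_coding_basis <- function(net, spec, dt = 0.005, span = c(-3, 0.4)) {
  avgL <- exp_smooth(simulate_trial(net, spec, "left", span = span,
                                    dt = dt)$rates, dt)
  avgR <- exp_smooth(simulate_trial(net, spec, "right", span = span,
                                    dt = dt)$rates, dt)
  time <- seq(span[1], span[2], by = dt)
  wins <- default_windows(sample_start = min(spec$tone_windows),
                          go_time = spec$go_window[1])
  V <- vapply(wins, function(w)
    extract_coding_dimension(avgL, avgR, time, w, shrinkage = 1),
    numeric(net$N))
  basis <- orthogonalize_basis(V, windows = wins, source = "model-derived")
  delay <- time >= wins$choice[1] & time < wins$choice[2]
  if (mean(avgR[delay, , drop = FALSE] %*% basis$vectors[, 2]) < 0)
    basis$vectors[, 2] <- -basis$vectors[, 2]
  basis$vectors
}

# causal exponential smoothing, timescale tau_s seconds, applied column-wise
exp_smooth <- function(X, dt, tau_s = 0.05) {
  beta <- 1 - exp(-dt / tau_s)
  out <- X
  for (t in 2:nrow(X)) out[t, ] <- (1 - beta) * out[t - 1, ] + beta * X[t, ]
  out
}

# adjoint of exp_smooth: maps gradients with respect to the filtered signal
# back to gradients with respect to the raw signal
exp_smooth_adjoint <- function(G, dt, tau_s = 0.05) {
  beta <- 1 - exp(-dt / tau_s)
  Tn <- nrow(G)
  out <- G
  q <- G[Tn, ]
  out[Tn, ] <- beta * q
  if (Tn > 1) for (t in (Tn - 1):1) {
    q <- G[t, ] + (1 - beta) * q
    out[t, ] <- if (t == 1) q else beta * q
  }
  out
}

#' Generate a synthetic recording session
#'
#' Simulates \code{n_trials_per_condition} trials per condition from a ground
#' truth. Each trial's rates are the deterministic network trajectory plus a
#' constant low-dimensional input bias (drawn as an AR(1) process across
#' trials, emulating slow drift of internal state), plus i.i.d. Gaussian
#' observation noise, clipped at zero and causally smoothed with a 50 ms
#' exponential kernel (the same smoothing applied to recorded spikes).
#' Conditions are interleaved in the session order so the drift affects both
#' equally.
#'
#' @param gt a \code{ground_truth} from \code{\link{make_ground_truth}}.
#' @param n_trials_per_condition trials per condition (>= 1).
#' @param dt sampling/integration step in seconds (default 0.005).
#' @param span simulated interval around the go cue (default \code{c(-3, 0.4)}).
#' @param seed integer seed for biases and noise (defaults to \code{gt$seed}).
#' @param go_shift go-cue shift passed to the simulator (0 = nominal).
#' @param smooth apply the 50 ms exponential smoothing (default TRUE).
#' @return an \code{activity_tensor}: list with \code{rates}
#'   (trials x time x neurons, spikes/s), \code{time}, \code{condition}
#'   (factor left/right), \code{outcome} (1 = hit, 0 = miss: a trial whose
#'   late-delay choice projection lands in the basin of the opposite
#'   condition — large input biases occasionally flip the choice, which is
#'   exactly the error mechanism the single-trial analyses probe),
#'   \code{bias} (P x trials, the true planted biases),
#'   \code{lick_rate}, \code{tone_windows}, \code{go_window},
#'   \code{epochs}, \code{dt}, \code{seed}.
#' @export
generate_recordings <- function(gt, n_trials_per_condition, dt = 0.005,
                                span = c(-3, 0.4), seed = gt$seed,
                                go_shift = 0, smooth = TRUE) {
  stopifnot(n_trials_per_condition >= 1, dt > 0)
  net <- gt$network; spec <- gt$spec
  time <- seq(span[1], span[2], by = dt)
  Tn <- length(time); N <- net$N; P <- net$P
  K <- 2L * as.integer(n_trials_per_condition)
  condition <- factor(rep(c("left", "right"), length.out = K),
                      levels = c("left", "right"))

  set.seed(as.integer(seed))
  rho <- exp(-1 / gt$drift_timescale)
  bias <- matrix(0, P, K)
  if (gt$bias_scale > 0) {
    bias[, 1] <- gt$bias_scale * rnorm(P)
    if (K > 1) for (k in 2:K)
      bias[, k] <- rho * bias[, k - 1] +
        gt$bias_scale * sqrt(1 - rho^2) * rnorm(P)
  }

  # reference late-delay choice projections of the unbiased trajectories,
  # used to label each trial's outcome by the basin it ends up in
  choice_axis <- net$U[, min(2L, net$P)]
  go_on <- spec$go_window[1] + if (is.finite(go_shift)) go_shift else 0
  late <- time >= go_on - 0.1 & time < go_on
  base <- lapply(c(left = "left", right = "right"), function(cc)
    simulate_trial(net, spec, cc, span = span, dt = dt,
                   go_shift = go_shift)$rates)
  ref <- if (any(late)) vapply(base, function(R)
    mean(R[late, , drop = FALSE] %*% choice_axis), numeric(1))
  else c(left = 0, right = 0)

  rates <- array(0, dim = c(K, Tn, N))
  outcome <- rep(1L, K)
  for (k in seq_len(K)) {
    cond <- as.character(condition[k])
    if (all(bias[, k] == 0)) {
      R <- base[[cond]]
    } else {
      R <- simulate_trial(net, spec, cond, span = span, dt = dt,
                          go_shift = go_shift,
                          bias = as.numeric(net$U %*% bias[, k]))$rates
    }
    if (abs(ref["left"] - ref["right"]) > 1e-6) {
      proj <- mean(R[late, , drop = FALSE] %*% choice_axis)
      other <- if (cond == "left") "right" else "left"
      if (abs(proj - ref[[other]]) < abs(proj - ref[[cond]]))
        outcome[k] <- 0L
    }
    if (gt$noise_sd > 0) R <- R + matrix(rnorm(Tn * N, sd = gt$noise_sd), Tn, N)
    R <- pmax(R, 0)
    if (smooth) R <- exp_smooth(R, dt)
    rates[k, , ] <- R
  }

  go_lick <- spec$go_window[1] + if (is.finite(go_shift)) go_shift else Inf
  lick_rate_t <- ifelse(time > go_lick,
                        spec$lick_rate(time - (go_lick - spec$go_window[1])), 0)
  structure(list(rates = rates, time = time, condition = condition,
                 outcome = outcome, bias = bias,
                 lick_rate = lick_rate_t,
                 tone_windows = spec$tone_windows,
                 go_window = spec$go_window + if (is.finite(go_shift)) go_shift else 0,
                 epochs = default_epochs(spec, span),
                 dt = dt, seed = as.integer(seed)),
            class = "activity_tensor")
}

#' Task epochs implied by the input schedule
#'
#' Pre-sample, sample, delay and response epochs, as half-open intervals in
#' seconds relative to the (nominal) go cue.
#'
#' @param spec an \code{\link{input_spec}}.
#' @param span simulated interval.
#' @return named list of length-2 numeric intervals.
#' @export
default_epochs <- function(spec, span = c(-3, 0.4)) {
  s0 <- min(spec$tone_windows)
  d0 <- max(spec$tone_windows)
  g0 <- spec$go_window[1]
  list(presample = c(span[1], s0), sample = c(s0, d0),
       delay = c(d0, g0), response = c(g0, span[2]))
}

#' @export
print.activity_tensor <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf("<activity_tensor> %d trials x %d time bins x %d neurons, dt = %g s, span [%g, %g] s\n",
              d[1], d[2], d[3], x$dt, min(x$time), max(x$time)))
  invisible(x)
}

#' Condition-averaged rates
#'
#' @param tensor an \code{activity_tensor}.
#' @param hit_only average only over hit (correct) trials (default TRUE).
#' @return list with \code{left} and \code{right} T x N matrices.
#' @export
condition_average <- function(tensor, hit_only = TRUE) {
  keep <- if (hit_only) tensor$outcome == 1L else rep(TRUE, length(tensor$outcome))
  avg <- lapply(c(left = "left", right = "right"), function(cond) {
    idx <- which(keep & tensor$condition == cond)
    if (!length(idx)) stop("no trials for condition ", cond)
    apply(tensor$rates[idx, , , drop = FALSE], c(2, 3), mean)
  })
  avg
}

#' Generate catch trials with a delayed go cue
#'
#' Same stimulus schedule as \code{\link{generate_recordings}}, with the go
#' cue (and the lick input tied to it) shifted to
#' \code{[go_time, go_time + 0.1)}. The simulated span is extended so that
#' 0.4 s after the delayed go cue is still observed.
#'
#' @inheritParams generate_recordings
#' @param go_time absolute go-cue onset in seconds on the trial clock whose
#'   zero is the nominal go cue; must be >= the nominal onset (0).
#' @return an \code{activity_tensor}; the \code{go_window} metadata reflects
#'   the delayed cue.
#' @export
generate_catch_trials <- function(gt, go_time, n_trials_per_condition = 1,
                                  dt = 0.005, seed = gt$seed, smooth = TRUE) {
  nominal <- gt$spec$go_window[1]
  if (go_time < nominal)
    stop("go_time must not precede the nominal go cue (end of the delay)")
  span <- c(-3, go_time + 0.4)
  generate_recordings(gt, n_trials_per_condition, dt = dt, span = span,
                      seed = seed, go_shift = go_time - nominal,
                      smooth = smooth)
}
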