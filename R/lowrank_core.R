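#' @useDynLib latentloop, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif setNames
NULL

#' Construct a low-rank recurrent rate network
#'
#' The network obeys the standard rate equation
#' \deqn{\tau \dot r = -r + \phi(J r + I(t)),}
#' where the connectivity is constrained to rank \eqn{P \le N},
#' \eqn{J = U A U^\top}. The columns of \eqn{U} span the low-dimensional
#' subspace in which all recurrent interactions live: the first \code{C}
#' columns are the task-coding dimensions (sample, choice, response) and the
#' remaining \eqn{R = P - C} columns are residual dimensions. The
#' \eqn{P \times P} interaction matrix \eqn{A} couples the latent
#' coordinates.
#'
#' @param U N x P matrix with (approximately) orthonormal columns.
#' @param A P x P interaction matrix.
#' @param rmax length-N vector of per-neuron maximum firing rates (spikes/s),
#'   all positive.
#' @param tau neuronal integration time constant in seconds (default 0.040).
#' @param C number of coding dimensions (first \code{C} columns of \code{U});
#'   default \code{min(3, P)}.
#' @param orth_tol tolerance on \eqn{\|I - U^\top U\|_F}. Fitted networks are
#'   only softly constrained to orthonormality, so the tolerance is
#'   configurable; exceeding it is an error.
#' @return an object of class \code{lowrank_network}.
#' @export
lowrank_network <- function(U, A, rmax, tau = 0.040, C = NULL,
                            orth_tol = 1e-4) {
  U <- as.matrix(U); A <- as.matrix(A)
  N <- nrow(U); P <- ncol(U)
  if (is.null(C)) C <- min(3L, P)
  if (nrow(A) != P || ncol(A) != P)
    stop("A must be ", P, " x ", P, " to match ncol(U)")
  if (length(rmax) != N) stop("rmax must have one entry per neuron")
  if (any(rmax <= 0)) stop("rmax entries must be positive")
  if (tau <= 0) stop("tau must be positive")
  C <- as.integer(C)
  if (C < 1L || C > P) stop("C must satisfy 1 <= C <= P")
  dev <- norm(diag(P) - crossprod(U), "F")
  if (dev > orth_tol)
    stop(sprintf("columns of U deviate from orthonormality (%.3g > %.3g)",
                 dev, orth_tol))
  structure(list(U = U, A = A, rmax = as.numeric(rmax), tau = tau,
                 N = N, P = P, C = C),
            class = "lowrank_network")
}

#' @export
print.lowrank_network <- function(x, ...) {
  cat(sprintf("<lowrank_network> N = %d neurons, P = %d latent (C = %d coding, R = %d residual), tau = %g s\n",
              x$N, x$P, x$C, x$P - x$C, x$tau))
  invisible(x)
}

#' Saturating transfer function
#'
#' \eqn{\phi_i(x) = r^{max}_i / 2 \, (\tanh(x) + 1)}: a sigmoid bounded in
#' \eqn{(0, r^{max}_i)} with \eqn{\phi_i(0) = r^{max}_i/2}.
#'
#' @param x net input (any numeric array).
#' @param rmax maximum firing rate(s); recycled against \code{x}.
#' @return firing rate(s), same shape as \code{x}.
#' @export
transfer <- function(x, rmax) {
  rmax / 2 * (tanh(x) + 1)
}

#' Derivative of the transfer function with respect to its input
#' @inheritParams transfer
#' @return gain \eqn{\phi_i'(x) = r^{max}_i/2 (1 - \tanh^2 x)}.
#' @export
transfer_gain <- function(x, rmax) {
  rmax / 2 * (1 - tanh(x)^2)
}

#' Materialise the rank-P connectivity matrix
#'
#' Computes \eqn{J = U A U^\top}, the full N x N recurrent weight matrix
#' implied by the low-rank factors. Only needed for diagnostics (Jacobians,
#' dense-simulation cross-checks); the simulator itself works in the factored
#' form.
#'
#' @param U N x P basis matrix.
#' @param A P x P interaction matrix.
#' @return N x N matrix of rank at most P.
#' @export
build_connectivity <- function(U, A) {
  U <- as.matrix(U); A <- as.matrix(A)
  if (nrow(A) != ncol(U) || ncol(A) != ncol(U))
    stop("shape mismatch: A must be ncol(U) x ncol(U)")
  U %*% A %*% t(U)
}

#' Task input specification
#'
#' Bundles the external inputs of the delayed-response task: three latent
#' input vectors (low tone, high tone, go cue) delivered inside fixed time
#' windows, per-choice lick input vectors active only after the go cue, and
#' the window schedule itself. Times are in seconds relative to the go cue;
#' all windows are half-open \code{[start, end)}. The default schedule has
#' three 150 ms tone pulses at [-1.85,-1.7), [-1.6,-1.45), [-1.35,-1.2) s and
#' a 100 ms go pulse at [0, 0.1) s.
#'
#' @param P latent dimensionality (length of the tone/go input vectors).
#' @param N neuron count (length of the lick input vectors).
#' @param i_low,i_high,i_go length-P latent input vectors (defaults: zero).
#' @param lick_left,lick_right length-N lick input vectors (defaults: zero).
#' @param lick_rate function of time returning the instantaneous lick rate
#'   (licks/s); only evaluated for t > 0. Default: identically zero.
#' @param tone_windows 3 x 2 matrix of tone window starts/ends.
#' @param go_window length-2 go-cue window.
#' @return an object of class \code{input_spec}.
#' @export
input_spec <- function(P, N,
                       i_low = numeric(P), i_high = numeric(P),
                       i_go = numeric(P),
                       lick_left = numeric(N), lick_right = numeric(N),
                       lick_rate = function(t) rep(0, length(t)),
                       tone_windows = default_tone_windows(),
                       go_window = c(0, 0.1)) {
  stopifnot(length(i_low) == P, length(i_high) == P, length(i_go) == P,
            length(lick_left) == N, length(lick_right) == N,
            is.function(lick_rate))
  tone_windows <- matrix(as.numeric(tone_windows), ncol = 2)
  structure(list(P = P, N = N, i_low = i_low, i_high = i_high, i_go = i_go,
                 lick_left = lick_left, lick_right = lick_right,
                 lick_rate = lick_rate, tone_windows = tone_windows,
                 go_window = as.numeric(go_window)),
            class = "input_spec")
}

#' Default tone-pulse schedule
#' @return 3 x 2 matrix of window starts and ends (seconds before go cue).
#' @export
default_tone_windows <- function() {
  matrix(c(-1.85, -1.7, -1.6, -1.45, -1.35, -1.2), ncol = 2, byrow = TRUE)
}

in_window <- function(t, w) t >= w[1] & t < w[2]

#' External task input at a single time point
#'
#' During each tone pulse the network receives \eqn{U I^{(sample)}} with
#' \eqn{I^{(sample)}} equal to the low- or high-tone latent vector depending
#' on the trial condition; during the go window it receives \eqn{U I^{Go}};
#' otherwise the task component is zero. After the go cue a proprioceptive
#' lick input (per-choice vector times the lick rate) is added.
#'
#' @param t time in seconds relative to the go cue.
#' @param condition \code{"left"} (low tone) or \code{"right"} (high tone).
#' @param spec an \code{\link{input_spec}}.
#' @param U N x P low-rank basis mapping latent inputs to neurons.
#' @param go_shift shift of the go window in seconds (0 = nominal);
#'   \code{Inf} withholds the go cue (and the lick input with it).
#' @return length-N input vector.
#' @export
task_input <- function(t, condition, spec, U, go_shift = 0) {
  condition <- match.arg(condition, c("left", "right"))
  i_samp <- if (condition == "left") spec$i_low else spec$i_high
  I <- numeric(nrow(U))
  tone <- any(apply(spec$tone_windows, 1, function(w) in_window(t, w)))
  if (tone) I <- I + as.numeric(U %*% i_samp)
  if (is.finite(go_shift)) {
    gw <- spec$go_window + go_shift
    if (in_window(t, gw)) I <- I + as.numeric(U %*% spec$i_go)
    if (t > gw[1]) {
      lv <- if (condition == "left") spec$lick_left else spec$lick_right
      I <- I + lv * spec$lick_rate(t - go_shift)
    }
  }
  I
}

# Build the T x N input matrix for a whole simulation in one shot.
# Optional extras: a constant bias vector (length N) and a perturbation
# list(direction = length-N vector, g = magnitude, window = c(start, end)).
build_input_matrix <- function(time, condition, spec, U, go_shift = 0,
                               bias = NULL, perturbation = NULL) {
  Tn <- length(time); N <- nrow(U)
  I <- matrix(0, Tn, N)
  i_samp <- if (condition == "left") spec$i_low else spec$i_high
  tone_idx <- rep(FALSE, Tn)
  for (k in seq_len(nrow(spec$tone_windows)))
    tone_idx <- tone_idx | in_window(time, spec$tone_windows[k, ])
  if (any(tone_idx))
    I[tone_idx, ] <- I[tone_idx, ] +
      matrix(as.numeric(U %*% i_samp), sum(tone_idx), N, byrow = TRUE)
  if (is.finite(go_shift)) {
    gw <- spec$go_window + go_shift
    go_idx <- in_window(time, gw)
    if (any(go_idx))
      I[go_idx, ] <- I[go_idx, ] +
        matrix(as.numeric(U %*% spec$i_go), sum(go_idx), N, byrow = TRUE)
    lick_idx <- time > gw[1]
    if (any(lick_idx)) {
      lv <- if (condition == "left") spec$lick_left else spec$lick_right
      if (any(lv != 0)) {
        lr <- spec$lick_rate(time[lick_idx] - go_shift)
        I[lick_idx, ] <- I[lick_idx, ] + outer(lr, lv)
      }
    }
  }
  if (!is.null(bias)) I <- sweep(I, 2, as.numeric(bias), `+`)
  if (!is.null(perturbation)) {
    p <- perturbation
    idx <- in_window(time, p$window)
    if (any(idx))
      I[idx, ] <- I[idx, ] +
        matrix(p$g * as.numeric(p$direction), sum(idx), N, byrow = TRUE)
  }
  I
}

#' Simulate a trial of the low-rank network
#'
#' Integrates \eqn{\tau \dot r = -r + \phi(J r + I(t))} by forward Euler
#' (default) or classical RK4 on a uniform grid. The recurrent term is
#' evaluated through the low-rank factors. The default initial condition is
#' the zero-input baseline \eqn{r_i = \phi_i(0) = r^{max}_i/2}.
#'
#' @param net a \code{\link{lowrank_network}}.
#' @param spec an \code{\link{input_spec}}.
#' @param condition \code{"left"} or \code{"right"}.
#' @param span length-2 simulation interval in seconds relative to the go
#'   cue (default \code{c(-3, 0.4)}).
#' @param dt integration step in seconds; must satisfy \code{dt <= tau/4}.
#' @param init optional length-N initial rate vector.
#' @param go_shift go-cue shift in seconds; \code{Inf} withholds the go cue.
#' @param bias optional constant length-N input (e.g. a trial-specific bias).
#' @param perturbation optional \code{list(direction, g, window)} pulse
#'   added to the input inside \code{window}.
#' @param method \code{"euler"} (default) or \code{"rk4"}.
#' @return a \code{trajectory}: list with \code{time} (length T), \code{rates}
#'   (T x N, spikes/s) and \code{condition}.
#' @export
simulate_trial <- function(net, spec, condition, span = c(-3, 0.4),
                           dt = 0.005, init = NULL, go_shift = 0,
                           bias = NULL, perturbation = NULL,
                           method = c("euler", "rk4")) {
  method <- match.arg(method)
  if (dt > net$tau / 4 + 1e-12)
    stop("dt must be at most tau/4 for a stable integration")
  time <- seq(span[1], span[2], by = dt)
  if (is.null(init)) init <- net$rmax / 2
  Ifull <- build_input_matrix(time, condition, spec, net$U,
                              go_shift = go_shift, bias = bias,
                              perturbation = perturbation)
  alpha <- dt / net$tau
  if (method == "euler") {
    out <- lr_forward_cpp(net$U, net$A, net$rmax, init, alpha, Ifull)
    rates <- out$rates
  } else {
    rates <- rk4_integrate(net, init, Ifull, dt)
  }
  if (!all(is.finite(rates)))
    stop("simulation diverged: non-finite rates encountered")
  structure(list(time = time, rates = rates, condition = condition),
            class = "trajectory")
}

# RK4 integrator; the input is held at its grid value over each step, so the
# scheme is formally O(dt) at window edges but O(dt^4) in smooth stretches.
rk4_integrate <- function(net, init, Ifull, dt) {
  Tn <- nrow(Ifull)
  rates <- matrix(0, Tn, net$N)
  rates[1, ] <- init
  f <- function(r, I) (-r + transfer(net$U %*% (net$A %*% crossprod(net$U, r)) + I,
                                     net$rmax)) / net$tau
  r <- init
  for (t in seq_len(Tn - 1)) {
    I <- Ifull[t, ]
    k1 <- f(r, I)
    k2 <- f(r + dt / 2 * k1, I)
    k3 <- f(r + dt / 2 * k2, I)
    k4 <- f(r + dt * k3, I)
    r <- r + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    rates[t + 1, ] <- r
  }
  rates
}

#' Project a trajectory onto the low-rank basis
#'
#' Returns the latent variables \eqn{m_l(t) = \sum_i u_i^l r_i(t)}, i.e. the
#' projections of the population rate vector onto the columns of \eqn{U}.
#'
#' @param traj a \code{trajectory} from \code{\link{simulate_trial}}.
#' @param U N x P basis matrix.
#' @return a \code{latent_trajectory}: list with \code{time} and \code{m}
#'   (T x P).
#' @export
project_latent <- function(traj, U) {
  m <- traj$rates %*% U
  structure(list(time = traj$time, m = m), class = "latent_trajectory")
}

#' Integrate the latent dynamics directly in P dimensions
#'
#' The projection \eqn{m = U^\top r} obeys the closed P-dimensional equation
#' \deqn{\tau \dot m = -m + U^\top \phi(U A m + I(t)),}
#' because the recurrent input \eqn{J r = U A m} depends on the state only
#' through its projection. The per-neuron nonlinearities are evaluated
#' exactly (the sum over all N neurons is kept), so heterogeneous maximum
#' rates are respected.
#'
#' @inheritParams simulate_trial
#' @param init_m optional length-P initial latent state (default: the
#'   projection of the baseline rates).
#' @return a \code{latent_trajectory} with \code{time} and \code{m} (T x P).
#' @export
simulate_latent <- function(net, spec, condition, span = c(-3, 0.4),
                            dt = 0.005, init_m = NULL, go_shift = 0,
                            bias = NULL, perturbation = NULL) {
  if (dt > net$tau / 4 + 1e-12)
    stop("dt must be at most tau/4 for a stable integration")
  time <- seq(span[1], span[2], by = dt)
  if (is.null(init_m)) init_m <- as.numeric(crossprod(net$U, net$rmax / 2))
  Ifull <- build_input_matrix(time, condition, spec, net$U,
                              go_shift = go_shift, bias = bias,
                              perturbation = perturbation)
  alpha <- dt / net$tau
  Tn <- length(time)
  M <- matrix(0, Tn, net$P)
  M[1, ] <- init_m
  m <- init_m
  for (t in seq_len(Tn - 1)) {
    phi <- transfer(net$U %*% (net$A %*% m) + Ifull[t, ], net$rmax)
    m <- (1 - alpha) * m + alpha * as.numeric(crossprod(net$U, phi))
    M[t + 1, ] <- m
  }
  structure(list(time = time, m = M), class = "latent_trajectory")
}
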