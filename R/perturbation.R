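#' Perturb a latent dimension during the delay
#'
#' Runs the network with a pulse input \eqn{I_{pert} = g\, u_l} added during
#' \code{window}, where \eqn{u_l} is a column of the low-rank basis (or any
#' explicit unit direction in neural space). Following the in-silico
#' perturbation protocol, the go cue is withheld (together with the lick
#' input tied to it) and the simulation continues 0.9 s past the nominal go
#' time so the network settles towards a condition-specific attractor.
#'
#' @param net a \code{\link{lowrank_network}}.
#' @param spec an \code{\link{input_spec}}.
#' @param condition \code{"left"} or \code{"right"}.
#' @param dim_index column of \code{U} to perturb (ignored if
#'   \code{direction} is given).
#' @param direction optional explicit length-N perturbation direction.
#' @param g perturbation magnitude.
#' @param window length-2 pulse interval in seconds (default 100 ms at the
#'   start of the delay, \code{c(-1.2, -1.1)}).
#' @param span simulation interval; default runs 0.9 s past the nominal go.
#' @param dt integration step.
#' @param withhold_go withhold the go cue (default TRUE, the protocol).
#' @param bias optional constant length-N input added throughout.
#' @return a \code{trajectory}.
#' @export
perturb_dimension <- function(net, spec, condition, dim_index = NULL,
                              direction = NULL, g = 0,
                              window = c(-1.2, -1.1), span = c(-3, 0.9),
                              dt = 0.005, withhold_go = TRUE, bias = NULL) {
  if (is.null(direction)) {
    if (is.null(dim_index)) stop("give either dim_index or direction")
    direction <- net$U[, dim_index]
  }
  direction <- as.numeric(direction)
  if (length(direction) != net$N) stop("direction must have length N")
  simulate_trial(net, spec, condition, span = span, dt = dt,
                 go_shift = if (withhold_go) Inf else 0, bias = bias,
                 perturbation = list(direction = direction, g = g,
                                     window = window))
}

#' Random perturbation orthogonal to the low-rank subspace
#'
#' Draws a unit direction inside the orthogonal complement of the columns of
#' \code{U} (obtained via the full QR decomposition of \code{U}) and applies
#' it as a pulse like \code{\link{perturb_dimension}}. Because the recurrent
#' input depends on the state only through its projection onto \code{U},
#' such perturbations influence the latent dynamics only through the
#' nonlinear gain modulation they induce.
#'
#' @inheritParams perturb_dimension
#' @param seed integer seed for the random direction.
#' @return a \code{trajectory} with attribute \code{"direction"}.
#' @export
random_orthogonal_perturbation <- function(net, spec, condition, g,
                                           window = c(-1.2, -1.1),
                                           span = c(-3, 0.9), dt = 0.005,
                                           seed = 1L, withhold_go = TRUE) {
  if (net$P >= net$N) stop("orthogonal complement is empty when P >= N")
  direction <- orthocomplement_direction(net$U, seed)
  traj <- perturb_dimension(net, spec, condition, direction = direction,
                            g = g, window = window, span = span, dt = dt,
                            withhold_go = withhold_go)
  attr(traj, "direction") <- direction
  traj
}

#' Unit direction in the orthogonal complement of U
#' @param U N x P matrix with orthonormal columns.
#' @param seed integer seed.
#' @return unit-norm length-N vector orthogonal to every column of U.
#' @export
orthocomplement_direction <- function(U, seed = 1L) {
  N <- nrow(U); P <- ncol(U)
  Qfull <- qr.Q(qr(U), complete = TRUE)
  Uperp <- Qfull[, (P + 1):N, drop = FALSE]
  set.seed(as.integer(seed))
  z <- Uperp %*% rnorm(N - P)
  as.numeric(z / sqrt(sum(z^2)))
}

#' Choice-flip counting with the symmetric margin rule
#'
#' Given the unperturbed endpoints \eqn{x_L, x_R} of the left and right
#' trajectories on the choice projection and the perturbed endpoints
#' \eqn{\hat x_L, \hat x_R}, defines the margin
#' \eqn{\epsilon = 0.25 (x_R - x_L)} and counts a flip toward right when
#' \eqn{|\hat x_L - x_R| < |\epsilon|} and a flip toward left when
#' \eqn{|\hat x_R - x_L| < |\epsilon|}. The rate is the flip count over the
#' total number of perturbed trials supplied.
#'
#' @param x_L,x_R unperturbed endpoints (scalars, must differ).
#' @param xhat_L perturbed endpoints of left trials (numeric vector, may be
#'   empty).
#' @param xhat_R perturbed endpoints of right trials.
#' @return a \code{flip_result}: list with \code{epsilon}, \code{x_L},
#'   \code{x_R}, \code{flips_to_right}, \code{flips_to_left}, \code{n_trials},
#'   \code{rate}.
#' @export
flip_rate <- function(x_L, x_R, xhat_L = numeric(0), xhat_R = numeric(0)) {
  if (x_L == x_R) stop("degenerate endpoints: x_L equals x_R")
  eps <- 0.25 * (x_R - x_L)
  to_right <- sum(abs(xhat_L - x_R) < abs(eps))
  to_left <- sum(abs(xhat_R - x_L) < abs(eps))
  n <- length(xhat_L) + length(xhat_R)
  structure(list(epsilon = eps, x_L = x_L, x_R = x_R,
                 flips_to_right = to_right, flips_to_left = to_left,
                 n_trials = n, rate = if (n > 0) (to_right + to_left) / n else NA_real_),
            class = "flip_result")
}

#' Endpoint of a trajectory on the choice projection
#' @param traj a \code{trajectory}.
#' @param choice_axis length-N unit vector (e.g. column 2 of \code{U}).
#' @return scalar projection of the final state.
#' @export
choice_endpoint <- function(traj, choice_axis) {
  as.numeric(traj$rates[nrow(traj$rates), ] %*% choice_axis)
}

#' Flip-rate sweep over dimensions, delay windows and magnitudes
#'
#' Applies 100 ms pulses along every latent dimension at each of
#' \code{n_windows} evenly spaced onsets during the delay period, over a
#' grid of magnitudes, with the go cue withheld on all runs, and counts
#' choice flips by the margin rule. With a deterministic network and no
#' trial noise each (dimension, window, magnitude) cell is a single pair of
#' runs, so the cell rate is the fraction over the left and right perturbed
#' trials (0, 0.5 or 1); per-trial input biases can be supplied to emulate
#' trial variability.
#'
#' @param net,spec network and inputs.
#' @param delay length-2 delay period (default \code{c(-1.2, 0)}).
#' @param n_windows number of evenly spaced pulse onsets (default 12).
#' @param magnitudes numeric grid (default 31 points over [-15, 15]).
#' @param duration pulse duration in seconds (default 0.1).
#' @param dims latent dimensions to sweep (default all P).
#' @param span,dt simulation settings (go cue withheld throughout).
#' @param choice_axis projection axis (default column 2 of \code{U}).
#' @return array of flip rates with dimensions dim x window x magnitude and
#'   attributes \code{onsets}, \code{magnitudes}, \code{dims}.
#' @export
flip_rate_sweep <- function(net, spec, delay = c(-1.2, 0), n_windows = 12,
                            magnitudes = seq(-15, 15, length.out = 31),
                            duration = 0.1, dims = seq_len(net$P),
                            span = c(-3, 0.9), dt = 0.005,
                            choice_axis = net$U[, 2]) {
  onsets <- seq(delay[1], delay[2] - duration, length.out = n_windows)
  base_L <- simulate_trial(net, spec, "left", span = span, dt = dt,
                           go_shift = Inf)
  base_R <- simulate_trial(net, spec, "right", span = span, dt = dt,
                           go_shift = Inf)
  x_L <- choice_endpoint(base_L, choice_axis)
  x_R <- choice_endpoint(base_R, choice_axis)
  out <- array(NA_real_,
               dim = c(length(dims), n_windows, length(magnitudes)),
               dimnames = list(dim = paste0("u", dims), window = NULL,
                               magnitude = NULL))
  for (di in seq_along(dims)) {
    for (wi in seq_len(n_windows)) {
      win <- c(onsets[wi], onsets[wi] + duration)
      for (gi in seq_along(magnitudes)) {
        g <- magnitudes[gi]
        if (g == 0) { out[di, wi, gi] <- 0; next }
        pL <- perturb_dimension(net, spec, "left", dim_index = dims[di],
                                g = g, window = win, span = span, dt = dt)
        pR <- perturb_dimension(net, spec, "right", dim_index = dims[di],
                                g = g, window = win, span = span, dt = dt)
        fr <- flip_rate(x_L, x_R, choice_endpoint(pL, choice_axis),
                        choice_endpoint(pR, choice_axis))
        out[di, wi, gi] <- fr$rate
      }
    }
  }
  attr(out, "onsets") <- onsets
  attr(out, "magnitudes") <- magnitudes
  attr(out, "dims") <- dims
  out
}

#' Rank neurons by their loading on a network dimension
#'
#' Orders neurons by decreasing absolute loading on the named column of
#' \code{U} (choice = column 2 by convention; residual dimensions by index).
#' Ties are broken by lower neuron index.
#'
#' @param U N x P basis matrix.
#' @param class \code{"choice"} or a residual dimension index (integer).
#' @return integer vector of neuron indices, most selective first.
#' @export
rank_neurons <- function(U, class = "choice") {
  col <- if (identical(class, "choice")) 2L else as.integer(class)
  loadings <- abs(U[, col])
  order(-loadings, seq_len(nrow(U)))
}

#' Perturb the top-K neurons of a selectivity ranking
#'
#' Delivers a K-hot input of per-neuron amplitude \eqn{\alpha/K} to the K
#' most selective neurons during the first 100 ms of the delay period, with
#' the go cue intact, and reports the separation metric: the absolute
#' left-right difference of the choice projection averaged over the 100 ms
#' preceding the go cue.
#'
#' @param net,spec network and inputs.
#' @param ranked integer vector from \code{\link{rank_neurons}}.
#' @param K number of targeted neurons (1..N).
#' @param alpha total input amplitude (the protocol uses 10, 20, 30).
#' @param window pulse interval (default first 100 ms of the delay).
#' @param span,dt simulation settings.
#' @param choice_axis projection axis (default column 2 of \code{U}).
#' @return list with \code{left}, \code{right} (trajectories),
#'   \code{input} (the K-hot vector) and \code{separation}.
#' @export
perturb_topk_neurons <- function(net, spec, ranked, K, alpha,
                                 window = c(-1.2, -1.1), span = c(-3, 0.4),
                                 dt = 0.005, choice_axis = net$U[, 2]) {
  if (K > net$N) stop("K cannot exceed the number of neurons")
  input <- numeric(net$N)
  input[ranked[seq_len(K)]] <- alpha / K
  trajs <- lapply(c(left = "left", right = "right"), function(cond)
    simulate_trial(net, spec, cond, span = span, dt = dt,
                   perturbation = list(direction = input, g = 1,
                                       window = window)))
  go <- spec$go_window[1]
  idx <- trajs$left$time >= go - 0.1 & trajs$left$time < go
  sep <- abs(mean((trajs$left$rates[idx, , drop = FALSE] -
                     trajs$right$rates[idx, , drop = FALSE]) %*% choice_axis))
  list(left = trajs$left, right = trajs$right, input = input,
       separation = sep)
}
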