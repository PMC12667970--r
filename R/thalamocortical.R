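#' Two-area cortex-thalamus network with communication bottlenecks
#'
#' Couples a recurrent low-rank cortical (ALM) network to a non-recurrent
#' thalamic population through rank-limited reciprocal projections. Each
#' inter-area matrix is a product of a readout from the presynaptic latent
#' subspace, a bottleneck mixing matrix, and a projection into the
#' postsynaptic subspace:
#' \deqn{J^{ct} = U^{ALM} J^{ct,post} B^{ct} J^{ct,pre} (U^{th})^\top,}
#' and analogously for the corticothalamic direction, so at most
#' \eqn{P_{ct}} (resp. \eqn{P_{tc}}) activity patterns are transmitted.
#' The thalamic time constant is one third of the cortical one, and the
#' thalamus has no recurrent connectivity. The sample stimulus is routed to
#' cortex and the go cue to thalamus.
#'
#' @param cortex a \code{\link{lowrank_network}} (the recurrent ALM model).
#' @param U_th N_th x P_th orthonormal thalamic basis.
#' @param rmax_th length-N_th thalamic maximum rates.
#' @param ct,tc bottleneck specifications: lists with \code{pre}
#'   (P_b x P_pre), \code{B} (P_b x P_b), \code{post} (P_post x P_b).
#' @param spec_cortex an \code{\link{input_spec}} for the cortical area
#'   (tone inputs used; its go input is ignored).
#' @param spec_thal an \code{\link{input_spec}} for the thalamus (go input
#'   used; its tone inputs are ignored).
#' @param tau_cortex cortical time constant (s).
#' @return a \code{two_area_network}.
#' @export
two_area_network <- function(cortex, U_th, rmax_th, ct, tc,
                             spec_cortex, spec_thal, tau_cortex = cortex$tau) {
  U_th <- as.matrix(U_th)
  N_th <- nrow(U_th); P_th <- ncol(U_th)
  stopifnot(length(rmax_th) == N_th, all(rmax_th > 0))
  P_alm <- cortex$P
  chk <- function(b, P_pre, P_post, nm) {
    Pb <- nrow(b$B)
    if (ncol(b$B) != Pb) stop(nm, ": bottleneck B must be square")
    if (Pb > min(P_pre, P_post))
      stop(nm, ": bottleneck dimension exceeds min(P_pre, P_post)")
    if (!all(dim(b$pre) == c(Pb, P_pre)))
      stop(nm, ": pre map must be ", Pb, " x ", P_pre)
    if (!all(dim(b$post) == c(P_post, Pb)))
      stop(nm, ": post map must be ", P_post, " x ", Pb)
    Pb
  }
  P_ct <- chk(ct, P_th, P_alm, "ct")   # thalamus -> cortex
  P_tc <- chk(tc, P_alm, P_th, "tc")   # cortex -> thalamus
  structure(list(cortex = cortex, U_th = U_th, rmax_th = as.numeric(rmax_th),
                 tau_th = tau_cortex / 3, ct = ct, tc = tc,
                 spec_cortex = spec_cortex, spec_thal = spec_thal,
                 P_ct = P_ct, P_tc = P_tc, N_th = N_th, P_th = P_th),
            class = "two_area_network")
}

#' @export
print.two_area_network <- function(x, ...) {
  cat(sprintf("<two_area_network> cortex N = %d (P = %d), thalamus N = %d (P = %d), bottlenecks P_ct = %d, P_tc = %d\n",
              x$cortex$N, x$cortex$P, x$N_th, x$P_th, x$P_ct, x$P_tc))
  invisible(x)
}

#' Materialise an inter-area connectivity matrix
#'
#' \eqn{J = U_{post} \cdot post \cdot B \cdot pre \cdot U_{pre}^\top}; its
#' rank is at most the bottleneck dimension (the size of \eqn{B}).
#'
#' @param U_post postsynaptic basis (N_post x P_post).
#' @param post P_post x P_b projection into the postsynaptic subspace.
#' @param B P_b x P_b bottleneck mixing matrix.
#' @param pre P_b x P_pre readout from the presynaptic subspace.
#' @param U_pre presynaptic basis (N_pre x P_pre).
#' @return N_post x N_pre matrix.
#' @export
bottleneck_connectivity <- function(U_post, post, B, pre, U_pre) {
  if (ncol(U_post) != nrow(post) || ncol(post) != nrow(B) ||
      ncol(B) != nrow(pre) || ncol(pre) != ncol(U_pre))
    stop("shape mismatch in bottleneck factors")
  U_post %*% post %*% B %*% pre %*% t(U_pre)
}

#' Simulate the coupled cortex-thalamus loop
#'
#' Joint forward-Euler integration of the two areas with their distinct
#' time constants. All recurrent and inter-area terms are evaluated through
#' their low-rank factors. The sample stimulus is delivered to cortex and
#' the go cue to thalamus; lick inputs (if any) follow each area's spec.
#'
#' @param net a \code{\link{two_area_network}}.
#' @param condition \code{"left"} or \code{"right"}.
#' @param span simulation interval (default \code{c(-3, 0.4)}).
#' @param dt step size; must satisfy \code{dt <= tau_th/4}.
#' @param go_shift go-cue shift (\code{Inf} withholds it).
#' @param perturb_thal optional \code{list(direction, g, window)} pulse
#'   applied to the thalamus.
#' @param init_cortex,init_thal optional initial rate vectors.
#' @return list of two \code{trajectory} objects, \code{cortex} and
#'   \code{thalamus}.
#' @export
simulate_loop <- function(net, condition, span = c(-3, 0.4), dt = 0.003,
                          go_shift = 0, perturb_thal = NULL,
                          init_cortex = NULL, init_thal = NULL) {
  if (dt > net$tau_th / 4 + 1e-12)
    stop("dt must be at most tau_th/4 = ", net$tau_th / 4, " s")
  cx <- net$cortex
  time <- seq(span[1], span[2], by = dt)
  Tn <- length(time)
  # cortical spec without its go input (the go cue is routed to thalamus);
  # thalamic spec without tone inputs (stimulus routed to cortex)
  spec_cx <- net$spec_cortex
  spec_cx$i_go <- numeric(cx$P)
  spec_th <- net$spec_thal
  spec_th$i_low <- spec_th$i_high <- numeric(net$P_th)
  I_cx <- build_input_matrix(time, condition, spec_cx, cx$U,
                             go_shift = go_shift)
  I_th <- build_input_matrix(time, condition, spec_th, net$U_th,
                             go_shift = go_shift,
                             perturbation = perturb_thal)
  a_cx <- dt / cx$tau
  a_th <- dt / net$tau_th
  r_cx <- if (is.null(init_cortex)) cx$rmax / 2 else init_cortex
  r_th <- if (is.null(init_thal)) net$rmax_th / 2 else init_thal
  R_cx <- matrix(0, Tn, cx$N); R_th <- matrix(0, Tn, net$N_th)
  R_cx[1, ] <- r_cx; R_th[1, ] <- r_th
  ct <- net$ct; tc <- net$tc
  for (t in seq_len(Tn - 1)) {
    m_cx <- crossprod(cx$U, r_cx)        # P_alm
    m_th <- crossprod(net$U_th, r_th)    # P_th
    h_cx <- cx$U %*% (cx$A %*% m_cx) +
      cx$U %*% (ct$post %*% (ct$B %*% (ct$pre %*% m_th))) + I_cx[t, ]
    h_th <- net$U_th %*% (tc$post %*% (tc$B %*% (tc$pre %*% m_cx))) + I_th[t, ]
    r_cx <- (1 - a_cx) * r_cx + a_cx * transfer(as.numeric(h_cx), cx$rmax)
    r_th <- (1 - a_th) * r_th + a_th * transfer(as.numeric(h_th), net$rmax_th)
    R_cx[t + 1, ] <- r_cx; R_th[t + 1, ] <- r_th
  }
  if (!all(is.finite(R_cx)) || !all(is.finite(R_th)))
    stop("two-area simulation diverged: non-finite rates")
  list(cortex = structure(list(time = time, rates = R_cx,
                               condition = condition), class = "trajectory"),
       thalamus = structure(list(time = time, rates = R_th,
                                 condition = condition), class = "trajectory"))
}

#' Disconnect one inter-area projection
#'
#' Zeroes the thalamocortical (\code{"ct"}) or corticothalamic (\code{"tc"})
#' bottleneck, simulates both the intact and the disconnected loop, and
#' reports the per-area activity-reduction metric: the ratio of the mean
#' delay-period deviation of rates from baseline (disconnected over intact),
#' averaged over both conditions.
#'
#' @param net a \code{\link{two_area_network}}.
#' @param which \code{"ct"} or \code{"tc"}.
#' @param span,dt simulation settings.
#' @param delay delay-period window used for the metric.
#' @return list with \code{network} (the disconnected network),
#'   \code{ratio} (named vector cortex/thalamus) and the simulated
#'   trajectories.
#' @export
disconnect <- function(net, which = c("ct", "tc"), span = c(-3, 0.4),
                       dt = 0.003, delay = c(-1.2, 0)) {
  which <- match.arg(which)
  cut <- net
  cut[[which]]$B <- matrix(0, nrow(net[[which]]$B), ncol(net[[which]]$B))
  base_cx <- net$cortex$rmax / 2
  base_th <- net$rmax_th / 2
  act <- function(nw) {
    dev_cx <- 0; dev_th <- 0
    for (cond in c("left", "right")) {
      tr <- simulate_loop(nw, cond, span = span, dt = dt)
      idx <- tr$cortex$time >= delay[1] & tr$cortex$time < delay[2]
      dev_cx <- dev_cx +
        mean(abs(sweep(tr$cortex$rates[idx, , drop = FALSE], 2, base_cx)))
      dev_th <- dev_th +
        mean(abs(sweep(tr$thalamus$rates[idx, , drop = FALSE], 2, base_th)))
    }
    c(cortex = dev_cx, thalamus = dev_th) / 2
  }
  a_int <- act(net); a_cut <- act(cut)
  list(network = cut, ratio = a_cut / a_int, intact_activity = a_int,
       disconnected_activity = a_cut)
}

#' Sweep of thalamic perturbations along choice versus residual directions
#'
#' Applies constant-magnitude input pulses to the thalamus either along a
#' supplied choice axis or along random unit directions drawn inside the
#' thalamic residual subspace, for a grid of magnitudes, and reports the
#' mean squared deviation of perturbed from unperturbed condition-averaged
#' activity in each area.
#'
#' @param net a \code{\link{two_area_network}}.
#' @param choice_axis_th length-N_th unit vector (thalamic choice axis).
#' @param residual_basis_th N_th x R matrix spanning the thalamic residual
#'   subspace (orthonormal columns).
#' @param magnitudes perturbation magnitudes (default 40 values in [1, 6]).
#' @param n_directions number of random residual directions (default 120).
#' @param window pulse window (default the first 100 ms of the delay).
#' @param span,dt simulation settings.
#' @param seed integer seed for the random directions.
#' @return data frame with columns \code{mode}, \code{direction},
#'   \code{magnitude}, \code{mse_cortex}, \code{mse_thalamus}.
#' @export
thalamic_perturbation_sweep <- function(net, choice_axis_th,
                                        residual_basis_th,
                                        magnitudes = seq(1, 6, length.out = 40),
                                        n_directions = 120,
                                        window = c(-1.2, -1.1),
                                        span = c(-3, 0.4), dt = 0.003,
                                        seed = 1L) {
  set.seed(as.integer(seed))
  R <- ncol(residual_basis_th)
  dirs <- list()
  dirs[["choice"]] <- as.numeric(choice_axis_th) /
    sqrt(sum(choice_axis_th^2))
  for (d in seq_len(n_directions)) {
    z <- residual_basis_th %*% rnorm(R)
    dirs[[paste0("residual", d)]] <- as.numeric(z / sqrt(sum(z^2)))
  }
  base <- lapply(c(left = "left", right = "right"), function(cond)
    simulate_loop(net, cond, span = span, dt = dt))
  rows <- list()
  for (nm in names(dirs)) {
    mode <- if (nm == "choice") "choice" else "residual"
    for (g in magnitudes) {
      mse_cx <- 0; mse_th <- 0
      for (cond in c("left", "right")) {
        pert <- simulate_loop(net, cond, span = span, dt = dt,
                              perturb_thal = list(direction = dirs[[nm]],
                                                  g = g, window = window))
        mse_cx <- mse_cx +
          mean((pert$cortex$rates - base[[cond]]$cortex$rates)^2)
        mse_th <- mse_th +
          mean((pert$thalamus$rates - base[[cond]]$thalamus$rates)^2)
      }
      rows[[length(rows) + 1]] <-
        data.frame(mode = mode, direction = nm, magnitude = g,
                   mse_cortex = mse_cx / 2, mse_thalamus = mse_th / 2)
    }
  }
  do.call(rbind, rows)
}
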