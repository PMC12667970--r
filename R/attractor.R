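#' Locate a condition-specific fixed point under a withheld go cue
#'
#' Simulates the network with the go cue withheld until 1.05 s past the
#' nominal go time (by default) and reports the final state together with
#' the residual of the autonomous flow, \eqn{\|-r + \phi(J r)\|}. The
#' residual is normalised by the mean maximum rate so the convergence
#' tolerance is scale-free. Optionally the state is polished by Newton
#' iterations on the flow field.
#'
#' @param net a \code{\link{lowrank_network}}.
#' @param spec an \code{\link{input_spec}}.
#' @param condition \code{"left"} or \code{"right"}.
#' @param t_extract extraction time in seconds after the nominal go cue
#'   (default 1.05).
#' @param dt integration step.
#' @param span_start start of the simulated interval (default -3 s).
#' @param tol normalised residual below which the state counts as converged.
#' @param polish run Newton refinement from the simulated endpoint
#'   (default FALSE).
#' @param bias optional constant input held during the run (and included in
#'   the flow whose fixed point is sought).
#' @return a \code{fixed_point_report}: list with \code{state} (length-N
#'   rates), \code{condition}, \code{residual} (normalised), \code{converged},
#'   \code{gains} (diagonal of D at the state), \code{t_extract}.
#' @export
find_fixed_point <- function(net, spec, condition, t_extract = 1.05,
                             dt = 0.005, span_start = -3, tol = 1e-6,
                             polish = FALSE, bias = NULL) {
  traj <- simulate_trial(net, spec, condition, span = c(span_start, t_extract),
                         dt = dt, go_shift = Inf, bias = bias)
  r <- traj$rates[nrow(traj$rates), ]
  J <- build_connectivity(net$U, net$A)
  I0 <- if (is.null(bias)) numeric(net$N) else as.numeric(bias)
  flow <- function(r) -r + transfer(J %*% r + I0, net$rmax)
  if (polish) {
    for (it in 1:50) {
      F <- as.numeric(flow(r))
      if (sqrt(mean(F^2)) / mean(net$rmax) < 1e-12) break
      h <- as.numeric(J %*% r + I0)
      D <- transfer_gain(h, net$rmax)
      M <- -diag(net$N) + D * J
      r <- r - solve(M, F)
    }
  }
  F <- as.numeric(flow(r))
  residual <- sqrt(mean(F^2)) / mean(net$rmax)
  h <- as.numeric(J %*% r + I0)
  structure(list(state = as.numeric(r), condition = condition,
                 residual = residual, converged = residual < tol,
                 gains = transfer_gain(h, net$rmax),
                 t_extract = t_extract, bias = I0),
            class = "fixed_point_report")
}

#' @export
print.fixed_point_report <- function(x, ...) {
  cat(sprintf("<fixed_point_report> condition %s, residual %.3g (%s)\n",
              x$condition, x$residual,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Jacobian of the rate dynamics at a state
#'
#' Linearising \eqn{\tau \dot{\delta r} = -\delta r + D J \delta r} around a
#' state gives the Jacobian \eqn{M = -I + D J}, where \eqn{J = U A U^\top}
#' and \eqn{D} is the diagonal matrix of transfer-function gains
#' \eqn{D_{ii} = r^{max}_i/2 \, (1 - \tanh^2 h_i)} evaluated at the local
#' input current \eqn{h_i = \sum_j J_{ij} r_j + I_i}. Eigenvalues are in
#' units of \eqn{1/\tau}.
#'
#' @param net a \code{\link{lowrank_network}}.
#' @param state length-N rate vector.
#' @param input length-N external input held at the state (default zero).
#' @return N x N Jacobian matrix.
#' @export
network_jacobian <- function(net, state, input = numeric(net$N)) {
  J <- build_connectivity(net$U, net$A)
  h <- as.numeric(J %*% state + input)
  D <- transfer_gain(h, net$rmax)
  -diag(net$N) + D * J
}

#' Stability spectrum of a fixed point
#'
#' Eigenvalues of the Jacobian \eqn{M = -I + DJ} at the reported state. The
#' fixed point is classified stable when the largest real part is below
#' \code{-tol}, marginal within \code{[-tol, tol]}, and unstable above.
#' Although \eqn{M} is N x N, its spectrum is \eqn{\{-1\}} plus at most P
#' nontrivial eigenvalues inherited from the rank-P connectivity.
#'
#' @param net a \code{\link{lowrank_network}}.
#' @param report a \code{fixed_point_report} (or a raw state vector).
#' @param tol width of the marginal band (default 1e-4).
#' @return list with \code{eigenvalues} (complex), \code{max_real},
#'   \code{verdict} (\code{"stable"}, \code{"marginal"}, \code{"unstable"}).
#' @export
stability_spectrum <- function(net, report, tol = 1e-4) {
  state <- if (inherits(report, "fixed_point_report")) report$state else report
  input <- if (inherits(report, "fixed_point_report")) report$bias else numeric(net$N)
  M <- network_jacobian(net, state, input)
  ev <- eigen(M, only.values = TRUE)$values
  mx <- max(Re(ev))
  verdict <- if (mx < -tol) "stable" else if (mx > tol) "unstable" else "marginal"
  list(eigenvalues = ev, max_real = mx, verdict = verdict)
}

#' Simulate a catch trial with a delayed (or withheld) go cue
#'
#' Runs the standard trial with the go cue moved to
#' \code{[go_time, go_time + 0.1)}; \code{go_time = Inf} withholds it
#' entirely. Returns the trajectory together with its projection onto the
#' choice axis over time, which reveals whether the delay activity has
#' settled into a condition-specific attractor (a plateau that survives the
#' extended delay).
#'
#' @param net,spec network and inputs.
#' @param condition \code{"left"} or \code{"right"}.
#' @param go_time go-cue onset in seconds (>= the nominal onset).
#' @param span simulation interval (default extends 0.4 s past the cue, or
#'   1.1 s past nominal when withheld).
#' @param dt integration step.
#' @param choice_axis projection axis (default column 2 of \code{U}).
#' @return list with \code{trajectory} and \code{choice_projection}
#'   (data frame time/projection).
#' @export
catch_trial <- function(net, spec, condition, go_time = 0.6, span = NULL,
                        dt = 0.005, choice_axis = net$U[, 2]) {
  nominal <- spec$go_window[1]
  if (go_time < nominal) stop("go_time must not precede the nominal go cue")
  if (is.null(span))
    span <- c(-3, if (is.finite(go_time)) go_time + 0.4 else nominal + 1.1)
  traj <- simulate_trial(net, spec, condition, span = span, dt = dt,
                         go_shift = if (is.finite(go_time)) go_time - nominal else Inf)
  proj <- as.numeric(traj$rates %*% choice_axis)
  list(trajectory = traj,
       choice_projection = data.frame(time = traj$time, projection = proj))
}
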