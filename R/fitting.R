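#' Loss weights for condition-averaged training
#'
#' Defaults follow the composite objective used for fitting the network to
#' condition-averaged activity: reconstruction 0.7, coding alignment 0.5,
#' orthogonality 500, with the choice-axis cosine term weighted twice as
#' heavily as the sample and response terms.
#'
#' @param lambda_recon,lambda_align,lambda_orth nonnegative loss weights.
#' @param choice_align_weight multiplier on the choice-axis cosine term.
#' @return a \code{loss_weights} list.
#' @export
loss_weights <- function(lambda_recon = 0.7, lambda_align = 0.5,
                         lambda_orth = 500, choice_align_weight = 2) {
  w <- list(lambda_recon = lambda_recon, lambda_align = lambda_align,
            lambda_orth = lambda_orth,
            choice_align_weight = choice_align_weight)
  if (any(unlist(w) < 0)) stop("loss weights must be nonnegative")
  structure(w, class = "loss_weights")
}

#' Optimiser configuration
#'
#' Adam with learning rate 5e-4 and global gradient-norm clipping.
#' Optimisation stops at \code{max_iterations} or when the relative change
#' of the total loss over \code{tol_window} iterations falls below
#' \code{tol_rel}.
#'
#' @param learning_rate Adam step size (> 0).
#' @param max_iterations iteration cap (the reference protocol allows up to
#'   4e5; desk-scale fits converge much earlier).
#' @param gradient_clip_norm global gradient-norm clip (default 1).
#' @param seed integer seed controlling initialisation.
#' @param checkpoint_every iterations between log records.
#' @param tol_rel,tol_window convergence test parameters.
#' @param decay_at,decay_factor step-decay schedule: at each fraction of
#'   \code{max_iterations} in \code{decay_at} the learning rate is
#'   multiplied by \code{decay_factor}. At desk-scale iteration budgets the
#'   annealing lets the jagged late-phase landscape settle; set
#'   \code{decay_at = numeric(0)} for a constant rate.
#' @return an \code{optimizer_config} list.
#' @export
optimizer_config <- function(learning_rate = 5e-4, max_iterations = 5000,
                             gradient_clip_norm = 1, seed = 1L,
                             checkpoint_every = 50, tol_rel = 1e-7,
                             tol_window = 1000, decay_at = c(0.6, 0.85),
                             decay_factor = 0.2) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 gradient_clip_norm = gradient_clip_norm,
                 seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 tol_rel = tol_rel, tol_window = as.integer(tol_window),
                 decay_at = decay_at, decay_factor = decay_factor),
            class = "optimizer_config")
}

# learning rate at a given iteration under the step-decay schedule
current_lr <- function(opt, iter) {
  lr <- opt$learning_rate
  if (length(opt$decay_at))
    lr <- lr * opt$decay_factor^sum(iter > opt$decay_at * opt$max_iterations)
  lr
}

#' Reconstruction loss
#'
#' Summed squared error between predicted and observed rates over time bins,
#' neurons and both conditions:
#' \eqn{\|r_L - \bar y_L\|_2^2 + \|r_R - \bar y_R\|_2^2}.
#'
#' @param pred_L,pred_R,data_L,data_R T x N rate matrices.
#' @return scalar loss.
#' @export
reconstruction_loss <- function(pred_L, pred_R, data_L, data_R) {
  if (!all(dim(pred_L) == dim(data_L)) || !all(dim(pred_R) == dim(data_R)))
    stop("shape mismatch between predictions and data")
  sum((pred_L - data_L)^2) + sum((pred_R - data_R)^2)
}

#' Coding alignment loss
#'
#' Cosine-similarity penalty tying the first three network dimensions to the
#' data-derived coding axes:
#' \eqn{4 - \cos(u_1, v_{sample}) - 2\cos(u_2, v_{choice}) -
#' \cos(u_3, v_{response})}. The choice term is doubled because the choice
#' axis is the network's primary readout.
#'
#' @param model_dims N x 3 matrix (first three columns of \code{U}).
#' @param target_dims N x 3 matrix of data-derived coding axes.
#' @param choice_weight weight on the choice cosine (default 2).
#' @return scalar loss (0 at perfect alignment).
#' @export
alignment_loss <- function(model_dims, target_dims, choice_weight = 2) {
  stopifnot(ncol(model_dims) == 3, ncol(target_dims) == 3)
  w <- c(1, choice_weight, 1)
  total <- 1 + choice_weight + 1
  cs <- vapply(1:3, function(j) {
    nu <- sqrt(sum(model_dims[, j]^2)); nv <- sqrt(sum(target_dims[, j]^2))
    if (nu == 0 || nv == 0) stop("zero-norm column in alignment loss")
    sum(model_dims[, j] * target_dims[, j]) / (nu * nv)
  }, numeric(1))
  total - sum(w * cs)
}

#' Orthogonality loss
#'
#' Squared Frobenius deviation of the low-rank basis from orthonormality,
#' \eqn{\|I - U^\top U\|_F^2}.
#'
#' @param U N x P matrix.
#' @return scalar loss.
#' @export
orthogonality_loss <- function(U) {
  D <- diag(ncol(U)) - crossprod(U)
  sum(D^2)
}

#' Pooled explained variance
#'
#' \eqn{1 - SSE/SS_{tot}} with both sums pooled over neurons, time bins and
#' conditions; \eqn{SS_{tot}} uses the pooled grand mean.
#'
#' @param pred,obs lists of T x N matrices (one entry per condition), or
#'   single matrices.
#' @return fraction of variance explained (can be negative for bad fits).
#' @export
explained_variance <- function(pred, obs) {
  if (is.matrix(pred)) { pred <- list(pred); obs <- list(obs) }
  p <- unlist(pred); o <- unlist(obs)
  1 - sum((p - o)^2) / sum((o - mean(o))^2)
}

# ---- internal optimisation machinery ---------------------------------------

# flat parameter vector layout for the condition-averaged model
pack_params <- function(th) {
  c(as.numeric(th$U), as.numeric(th$A), log(th$rmax),
    th$i_low, th$i_high, th$i_go, th$lick_left, th$lick_right)
}

unpack_params <- function(x, N, P) {
  i <- 0
  take <- function(n) { v <- x[(i + 1):(i + n)]; i <<- i + n; v }
  th <- list(U = matrix(take(N * P), N, P), A = matrix(take(P * P), P, P),
             rmax = exp(take(N)), i_low = take(P), i_high = take(P),
             i_go = take(P), lick_left = take(N), lick_right = take(N))
  th
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0)

adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$step <- lr * mhat / (sqrt(vhat) + eps)
  state
}

clip_global_norm <- function(g, max_norm) {
  nrm <- sqrt(sum(g^2))
  if (is.finite(max_norm) && nrm > max_norm) g <- g * (max_norm / nrm)
  g
}

# gradient of -cos(u, v) with respect to u, times weight w
neg_cos_grad <- function(u, v, w) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  cu <- sum(u * v) / (nu * nv)
  -w * (v / (nu * nv) - cu * u / nu^2)
}

# time-bin masks for the task input schedule
input_masks <- function(time, tone_windows, go_window, go_shift = 0) {
  tone <- rep(FALSE, length(time))
  for (k in seq_len(nrow(tone_windows)))
    tone <- tone | (time >= tone_windows[k, 1] & time < tone_windows[k, 2])
  if (is.finite(go_shift)) {
    gw <- go_window + go_shift
    go <- time >= gw[1] & time < gw[2]
    lick <- time > gw[1]
  } else {
    go <- lick <- rep(FALSE, length(time))
  }
  list(tone = tone, go = go, lick = lick)
}

# T x N input matrix from parameters + masks (+ optional constant latent bias)
param_input_matrix <- function(th, masks, condition, lick_rate_t,
                               bias_latent = NULL) {
  Tn <- length(masks$tone); N <- nrow(th$U)
  I <- matrix(0, Tn, N)
  i_samp <- if (condition == "left") th$i_low else th$i_high
  Usamp <- as.numeric(th$U %*% i_samp)
  Ugo <- as.numeric(th$U %*% th$i_go)
  if (any(masks$tone))
    I[masks$tone, ] <- I[masks$tone, ] +
      matrix(Usamp, sum(masks$tone), N, byrow = TRUE)
  if (any(masks$go))
    I[masks$go, ] <- I[masks$go, ] + matrix(Ugo, sum(masks$go), N, byrow = TRUE)
  if (any(masks$lick) && !is.null(lick_rate_t)) {
    lv <- if (condition == "left") th$lick_left else th$lick_right
    I[masks$lick, ] <- I[masks$lick, ] + outer(lick_rate_t[masks$lick], lv)
  }
  if (!is.null(bias_latent))
    I <- sweep(I, 2, as.numeric(th$U %*% bias_latent), `+`)
  I
}

# map dL/dI (T x N) back to parameter gradients; returns a list of increments
input_grad_increments <- function(gI, th, masks, condition, lick_rate_t,
                                  bias_latent = NULL) {
  inc <- list(U = matrix(0, nrow(th$U), ncol(th$U)),
              i_low = numeric(ncol(th$U)), i_high = numeric(ncol(th$U)),
              i_go = numeric(ncol(th$U)),
              lick_left = numeric(nrow(th$U)),
              lick_right = numeric(nrow(th$U)),
              bias = numeric(ncol(th$U)))
  i_samp_name <- if (condition == "left") "i_low" else "i_high"
  i_samp <- th[[i_samp_name]]
  if (any(masks$tone)) {
    s <- colSums(gI[masks$tone, , drop = FALSE])
    inc[[i_samp_name]] <- inc[[i_samp_name]] + as.numeric(crossprod(th$U, s))
    inc$U <- inc$U + outer(s, i_samp)
  }
  if (any(masks$go)) {
    s <- colSums(gI[masks$go, , drop = FALSE])
    inc$i_go <- inc$i_go + as.numeric(crossprod(th$U, s))
    inc$U <- inc$U + outer(s, th$i_go)
  }
  if (any(masks$lick) && !is.null(lick_rate_t)) {
    lname <- if (condition == "left") "lick_left" else "lick_right"
    inc[[lname]] <- inc[[lname]] +
      colSums(gI[masks$lick, , drop = FALSE] * lick_rate_t[masks$lick])
  }
  if (!is.null(bias_latent)) {
    s <- colSums(gI)
    inc$bias <- as.numeric(crossprod(th$U, s))
    inc$U <- inc$U + outer(s, as.numeric(bias_latent))
  }
  inc
}

# ---- condition-averaged training -------------------------------------------

#' Train the low-rank network on condition-averaged activity
#'
#' Jointly optimises the low-rank basis \code{U} (N x P), the interaction
#' matrix \code{A} (P x P), the per-neuron maximum rates, the three latent
#' task-input vectors and the two lick-input vectors by Adam on the weighted
#' sum of the reconstruction, coding-alignment and orthogonality losses.
#' Gradients are computed by exact reverse-mode differentiation through the
#' Euler-integrated dynamics. Maximum rates are optimised on a log scale to
#' keep them positive; the initial condition of every simulated trial is the
#' baseline \eqn{r^{max}/2}.
#'
#' @param data an \code{activity_tensor} containing hit trials of both
#'   conditions.
#' @param basis a \code{coding_basis} with the three data-derived axes.
#' @param P total latent dimensionality (>= 3).
#' @param weights a \code{\link{loss_weights}}.
#' @param opt an \code{\link{optimizer_config}}.
#' @param init optional warm start: a list with elements \code{network}
#'   (a \code{lowrank_network}) and \code{spec} (an \code{input_spec}).
#' @param fix_U if TRUE, the coding columns are hard-fixed to \code{basis}
#'   and only completed residual columns (plus all other parameters) are
#'   trained ("fixed coding dimensions" control).
#' @param measurement_filter if TRUE (default), the model's predicted rates
#'   are passed through the same 50 ms causal exponential filter that the
#'   recorded rates received before the reconstruction loss is evaluated
#'   (an observation model: smoothed spikes are filtered rates, so the
#'   model should be compared on the filtered scale). Disable when fitting
#'   unfiltered rates.
#' @param verbose print checkpoint losses.
#' @return a \code{lowrank_fit}: list with \code{network}, \code{spec},
#'   \code{log} (data frame of per-checkpoint loss terms), \code{basis},
#'   \code{converged}, \code{iterations}.
#' @export
train_condition_averaged <- function(data, basis, P, weights = loss_weights(),
                                     opt = optimizer_config(), init = NULL,
                                     fix_U = FALSE, measurement_filter = TRUE,
                                     verbose = FALSE) {
  P <- as.integer(P)
  C <- ncol(basis$vectors)
  if (P < C) stop("P must be at least the number of coding dimensions (", C, ")")
  avg <- condition_average(data)
  Y <- list(left = avg$left, right = avg$right)
  time <- data$time
  N <- ncol(Y$left)
  dt <- data$dt
  tau <- 0.040
  alpha <- dt / tau
  masks <- input_masks(time, data$tone_windows, data$go_window)
  lick_rate_t <- if (!is.null(data$lick_rate)) data$lick_rate else numeric(length(time))

  set.seed(opt$seed)
  if (is.null(init)) {
    rmax0 <- pmax(2 * colMeans(rbind(Y$left, Y$right)), 0.5)
    ri <- regression_init(Y, basis, P, rmax0, masks, dt,
                          lick_rate_t = lick_rate_t)
    th <- list(U = ri$U, A = ri$A, rmax = rmax0,
               i_low = ri$i_low, i_high = ri$i_high, i_go = ri$i_go,
               lick_left = ri$lick_left, lick_right = ri$lick_right)
  } else {
    th <- list(U = init$network$U, A = init$network$A,
               rmax = init$network$rmax,
               i_low = init$spec$i_low, i_high = init$spec$i_high,
               i_go = init$spec$i_go,
               lick_left = init$spec$lick_left,
               lick_right = init$spec$lick_right)
    if (ncol(th$U) != P) stop("warm start has P = ", ncol(th$U),
                              " but P = ", P, " was requested")
  }

  x <- pack_params(th)
  ad <- adam_init(length(x))
  log_rows <- list()
  prev_ckpt_loss <- Inf
  converged <- FALSE
  iter_done <- 0L

  for (iter in seq_len(opt$max_iterations)) {
    th <- unpack_params(x, N, P)
    if (fix_U) th$U[, seq_len(C)] <- basis$vectors
    terms <- ca_loss_and_grad(th, Y, masks, lick_rate_t, alpha, basis,
                              weights,
                              filter_dt = if (measurement_filter) dt else NULL)
    if (!is.finite(terms$total))
      stop("training diverged (non-finite loss) at iteration ", iter)
    g <- terms$grad
    # stationary point: Adam would otherwise amplify numerically-negligible
    # gradients into full-size steps
    if (sqrt(sum(g^2)) < 1e-4 * max(1, abs(terms$total))) {
      converged <- TRUE
      log_rows[[length(log_rows) + 1]] <-
        data.frame(iteration = iter, total = terms$total,
                   recon = terms$recon, align = terms$align,
                   orth = terms$orth)
      iter_done <- iter
      break
    }
    if (fix_U) {
      gU <- matrix(g[seq_len(N * P)], N, P)
      gU[, seq_len(C)] <- 0
      g[seq_len(N * P)] <- as.numeric(gU)
    }
    g <- clip_global_norm(g, opt$gradient_clip_norm)
    ad <- adam_step(ad, g, current_lr(opt, iter))
    x <- x - ad$step
    iter_done <- iter
    if (iter %% opt$checkpoint_every == 0 || iter == 1) {
      log_rows[[length(log_rows) + 1]] <-
        data.frame(iteration = iter, total = terms$total,
                   recon = terms$recon, align = terms$align,
                   orth = terms$orth)
      if (verbose)
        message(sprintf("iter %6d  total %.6g  recon %.6g  align %.4g  orth %.4g",
                        iter, terms$total, terms$recon, terms$align, terms$orth))
    }
    if (iter %% opt$tol_window == 0) {
      if (abs(prev_ckpt_loss - terms$total) <
          opt$tol_rel * max(abs(prev_ckpt_loss), 1e-12)) {
        converged <- TRUE
        break
      }
      prev_ckpt_loss <- terms$total
    }
  }

  th <- unpack_params(x, N, P)
  if (fix_U) th$U[, seq_len(C)] <- basis$vectors
  net <- lowrank_network(th$U, th$A, th$rmax, tau = tau, C = C,
                         orth_tol = Inf)
  spec <- input_spec(P, N, i_low = th$i_low, i_high = th$i_high,
                     i_go = th$i_go, lick_left = th$lick_left,
                     lick_right = th$lick_right,
                     tone_windows = data$tone_windows,
                     go_window = data$go_window)
  structure(list(network = net, spec = spec,
                 log = do.call(rbind, log_rows), basis = basis,
                 converged = converged, iterations = iter_done,
                 span = range(time), dt = dt,
                 measurement_filter = measurement_filter),
            class = "lowrank_fit")
}

# total loss + flat gradient for the condition-averaged objective;
# filter_dt non-NULL applies the 50 ms observation filter to predictions
ca_loss_and_grad <- function(th, Y, masks, lick_rate_t, alpha, basis,
                             weights, filter_dt = NULL) {
  N <- nrow(th$U); P <- ncol(th$U)
  r0 <- th$rmax / 2
  recon <- 0
  gU <- matrix(0, N, P); gA <- matrix(0, P, P); grmax <- numeric(N)
  gi <- list(i_low = numeric(P), i_high = numeric(P), i_go = numeric(P),
             lick_left = numeric(N), lick_right = numeric(N))
  for (cond in c("left", "right")) {
    I <- param_input_matrix(th, masks, cond, lick_rate_t)
    fw <- lr_forward_cpp(th$U, th$A, th$rmax, r0, alpha, I)
    pred <- if (is.null(filter_dt)) fw$rates else exp_smooth(fw$rates, filter_dt)
    resid <- pred - Y[[cond]]
    recon <- recon + sum(resid^2)
    Gr <- 2 * weights$lambda_recon * resid
    if (!is.null(filter_dt)) Gr <- exp_smooth_adjoint(Gr, filter_dt)
    bw <- lr_backward_cpp(th$U, th$A, th$rmax, alpha, fw$rates, fw$th, Gr)
    gU <- gU + bw$gU; gA <- gA + bw$gA
    grmax <- grmax + bw$grmax + bw$gr0 / 2
    inc <- input_grad_increments(bw$gI, th, masks, cond, lick_rate_t)
    gU <- gU + inc$U
    for (nm in names(gi)) gi[[nm]] <- gi[[nm]] + inc[[nm]]
  }

  C <- ncol(basis$vectors)
  align <- alignment_loss(th$U[, seq_len(C), drop = FALSE], basis$vectors,
                          weights$choice_align_weight)
  wal <- c(1, weights$choice_align_weight, 1)
  for (j in seq_len(C))
    gU[, j] <- gU[, j] + weights$lambda_align *
      neg_cos_grad(th$U[, j], basis$vectors[, j], wal[j])

  orth <- orthogonality_loss(th$U)
  gU <- gU + weights$lambda_orth * (-4) * th$U %*% (diag(P) - crossprod(th$U))

  total <- weights$lambda_recon * recon + weights$lambda_align * align +
    weights$lambda_orth * orth
  grad <- c(as.numeric(gU), as.numeric(gA), grmax * th$rmax,
            gi$i_low, gi$i_high, gi$i_go, gi$lick_left, gi$lick_right)
  list(total = total, recon = recon, align = align, orth = orth, grad = grad)
}

# complete the coding axes to a random orthonormal N x P basis
random_orthonormal_completion <- function(V, P) {
  N <- nrow(V); C <- ncol(V)
  if (P == C) return(V)
  X <- matrix(rnorm(N * (P - C)), N, P - C)
  X <- X - V %*% crossprod(V, X)
  cbind(V, qr.Q(qr(X)))
}

# Data-driven initialisation: residual columns from the principal components
# of the condition averages outside the coding subspace, and A plus the
# latent input vectors from a least-squares fit of the latent dynamics
# linearised around the baseline gain.
regression_init <- function(Y, basis, P, rmax0, masks, dt, tau = 0.040,
                            lick_rate_t = NULL) {
  V <- basis$vectors
  N <- nrow(V); C <- ncol(V)
  stacked <- rbind(Y$left, Y$right)
  if (P > C) {
    resid <- stacked - stacked %*% V %*% t(V)
    resid <- sweep(resid, 2, colMeans(resid))
    pc <- svd(resid, nu = 0, nv = P - C)$v
    pc <- pc - V %*% crossprod(V, pc)
    U0 <- cbind(V, qr.Q(qr(pc)))
  } else U0 <- V
  phi0 <- rmax0 / 2
  base <- as.numeric(crossprod(U0, phi0))
  # baseline gain matrix G = U' diag(rmax/2) U
  G <- crossprod(U0, U0 * (rmax0 / 2))
  rows_z <- list(); rows_x <- list()
  for (cond in c("left", "right")) {
    m <- Y[[cond]] %*% U0
    Tn <- nrow(m)
    dm <- (m[2:Tn, , drop = FALSE] - m[1:(Tn - 1), , drop = FALSE]) / dt
    z <- tau * dm + m[1:(Tn - 1), , drop = FALSE] -
      matrix(base, Tn - 1, ncol(U0), byrow = TRUE)
    tone <- as.numeric(masks$tone[1:(Tn - 1)])
    go <- as.numeric(masks$go[1:(Tn - 1)])
    X <- cbind(m[1:(Tn - 1), , drop = FALSE],
               tone * (cond == "left"), tone * (cond == "right"), go)
    rows_z[[cond]] <- z; rows_x[[cond]] <- X
  }
  Z <- rbind(rows_z$left, rows_z$right)
  X <- rbind(rows_x$left, rows_x$right)
  coefs <- tryCatch(qr.solve(X, Z), error = function(e) NULL)
  Pq <- ncol(U0)
  if (is.null(coefs)) {
    A0 <- matrix(rnorm(Pq * Pq, sd = 0.02), Pq, Pq)
    iL <- iH <- iG <- rnorm(Pq, sd = 0.1)
  } else {
    Ginv <- tryCatch(solve(G), error = function(e) diag(Pq) / mean(diag(G)))
    A0 <- Ginv %*% t(coefs[1:Pq, , drop = FALSE])
    iL <- as.numeric(Ginv %*% coefs[Pq + 1, ])
    iH <- as.numeric(Ginv %*% coefs[Pq + 2, ])
    iG <- as.numeric(Ginv %*% coefs[Pq + 3, ])
  }
  # lick vectors: project the post-go residual of the baseline-linearised
  # prediction onto the lick-rate regressor, per condition
  lick <- list(left = numeric(N), right = numeric(N))
  if (!is.null(lick_rate_t) && any(masks$lick) && any(lick_rate_t != 0)) {
    idx <- which(masks$lick)
    lr <- lick_rate_t[idx]
    if (sum(lr^2) > 0) {
      for (cond in c("left", "right")) {
        Rres <- Y[[cond]][idx, , drop = FALSE] -
          matrix(phi0, length(idx), N, byrow = TRUE) -
          (Y[[cond]][idx, , drop = FALSE] %*% U0 -
             matrix(base, length(idx), ncol(U0), byrow = TRUE)) %*% t(U0)
        lick[[cond]] <- as.numeric(crossprod(Rres, lr)) /
          (sum(lr^2) * pmax(rmax0 / 2, 0.5))
      }
    }
  }
  list(U = U0, A = A0, i_low = iL, i_high = iH, i_go = iG,
       lick_left = lick$left, lick_right = lick$right)
}

#' Predict condition-averaged rates from a fit
#'
#' Simulates the fitted network with its fitted inputs on the data grid,
#' applying the observation filter when the fit used one.
#'
#' @param fit a \code{lowrank_fit} (or list with \code{network}, \code{spec},
#'   \code{span}, \code{dt}).
#' @return list with \code{left} and \code{right} T x N rate matrices.
#' @export
predict_condition_averages <- function(fit) {
  lapply(c(left = "left", right = "right"), function(cond) {
    r <- simulate_trial(fit$network, fit$spec, cond, span = fit$span,
                        dt = fit$dt)$rates
    if (isTRUE(fit$measurement_filter)) r <- exp_smooth(r, fit$dt)
    r
  })
}

#' @export
print.lowrank_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf("<lowrank_fit> P = %d, %d iterations (%s), final losses: recon %.4g, align %.4g, orth %.4g\n",
              x$network$P, x$iterations,
              if (x$converged) "converged" else "iteration cap", last$recon,
              last$align, last$orth))
  invisible(x)
}

#' Trial-level cross-validation over latent dimensionality
#'
#' For each fold, 80% of trials per condition are sampled to form training
#' condition averages (and training-set LDA coding axes); a network is
#' trained per candidate \code{P}; performance is the mean squared error of
#' its predictions against the held-out-trial condition averages, together
#' with the mean cosine similarity between the fitted coding columns and the
#' training-set LDA axes.
#'
#' @param data an \code{activity_tensor}.
#' @param P_grid integer vector of candidate latent dimensionalities.
#' @param n_folds number of random splits (default 5).
#' @param train_frac fraction of trials used for training (default 0.8).
#' @param weights,opt training settings applied to every fit.
#' @param shrinkage LDA shrinkage for the per-fold coding axes.
#' @param seed integer; fold assignments are deterministic given it.
#' @return data frame with columns \code{P}, \code{fold}, \code{test_mse},
#'   \code{train_mse}, \code{mean_cos}.
#' @export
cross_validate <- function(data, P_grid, n_folds = 5, train_frac = 0.8,
                           weights = loss_weights(),
                           opt = optimizer_config(), shrinkage = 0.1,
                           seed = 1L) {
  K <- dim(data$rates)[1]
  splits <- cv_splits(data, n_folds, train_frac, seed)
  rows <- list()
  for (f in seq_len(n_folds)) {
    tr <- subset_tensor(data, splits[[f]]$train)
    te <- subset_tensor(data, splits[[f]]$test)
    basis <- estimate_coding_basis(tr, shrinkage = shrinkage)
    avg_te <- condition_average(te)
    avg_tr <- condition_average(tr)
    for (P in P_grid) {
      o <- opt; o$seed <- opt$seed + 1000L * f + P
      fit <- train_condition_averaged(tr, basis, P, weights = weights,
                                      opt = o)
      pred <- predict_condition_averages(fit)
      test_mse <- mean((pred$left - avg_te$left)^2 +
                         (pred$right - avg_te$right)^2) / 2
      train_mse <- mean((pred$left - avg_tr$left)^2 +
                          (pred$right - avg_tr$right)^2) / 2
      cs <- mean(vapply(1:3, function(j) {
        u <- fit$network$U[, j]; v <- basis$vectors[, j]
        sum(u * v) / sqrt(sum(u^2) * sum(v^2))
      }, numeric(1)))
      rows[[length(rows) + 1]] <-
        data.frame(P = P, fold = f, test_mse = test_mse,
                   train_mse = train_mse, mean_cos = cs)
    }
  }
  do.call(rbind, rows)
}

# deterministic stratified trial splits
cv_splits <- function(data, n_folds, train_frac, seed) {
  set.seed(as.integer(seed))
  lapply(seq_len(n_folds), function(f) {
    train <- integer(0)
    for (cond in levels(data$condition)) {
      idx <- which(data$condition == cond & data$outcome == 1L)
      if (length(idx) < 2) stop("not enough trials of condition ", cond,
                                " for a split")
      n_tr <- max(1, round(train_frac * length(idx)))
      train <- c(train, sample(idx, n_tr))
    }
    list(train = sort(train),
         test = setdiff(which(data$outcome == 1L), train))
  })
}

#' Subset an activity tensor by trial index
#' @param tensor an \code{activity_tensor}.
#' @param idx trial indices to keep.
#' @return an \code{activity_tensor} with the selected trials.
#' @export
subset_tensor <- function(tensor, idx) {
  out <- tensor
  out$rates <- tensor$rates[idx, , , drop = FALSE]
  out$condition <- tensor$condition[idx]
  out$outcome <- tensor$outcome[idx]
  if (!is.null(tensor$bias)) out$bias <- tensor$bias[, idx, drop = FALSE]
  out
}

#' Summarise a cross-validation table
#'
#' Mean and standard error over folds per \code{P}, optionally smoothed with
#' a centred five-point moving average over the \code{P} grid.
#'
#' @param cv_table output of \code{\link{cross_validate}}.
#' @param smooth apply the moving average (default FALSE).
#' @return data frame with \code{P}, \code{test_mse}, \code{se},
#'   \code{mean_cos}.
#' @export
summarize_cv <- function(cv_table, smooth = FALSE) {
  Ps <- sort(unique(cv_table$P))
  agg <- do.call(rbind, lapply(Ps, function(p) {
    sub <- cv_table[cv_table$P == p, ]
    data.frame(P = p, test_mse = mean(sub$test_mse),
               se = stats::sd(sub$test_mse) / sqrt(nrow(sub)),
               mean_cos = mean(sub$mean_cos))
  }))
  if (smooth && nrow(agg) >= 2) {
    ma <- function(v) {
      n <- length(v)
      vapply(seq_len(n), function(i) {
        w <- max(1, i - 2):min(n, i + 2)
        mean(v[w])
      }, numeric(1))
    }
    agg$test_mse <- ma(agg$test_mse)
    agg$mean_cos <- ma(agg$mean_cos)
  }
  agg
}
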