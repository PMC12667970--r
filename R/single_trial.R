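#' Loss weights for single-trial training
#'
#' Defaults for the six-term objective used when fitting trial-specific
#' input biases jointly with the network: trial-averaged reconstruction
#' 0.65, epoch-average 0.1666, coding-projection 0.02, alignment 0.5,
#' orthogonality 500, input regularisation 0.1.
#'
#' @param c_recon,c_epoch,c_proj,c_align,c_orth,c_reg nonnegative weights.
#' @param choice_align_weight multiplier on the choice cosine term.
#' @return a \code{single_trial_loss_weights} list.
#' @export
single_trial_loss_weights <- function(c_recon = 0.65, c_epoch = 0.1666,
                                      c_proj = 0.02, c_align = 0.5,
                                      c_orth = 500, c_reg = 0.1,
                                      choice_align_weight = 2) {
  w <- list(c_recon = c_recon, c_epoch = c_epoch, c_proj = c_proj,
            c_align = c_align, c_orth = c_orth, c_reg = c_reg,
            choice_align_weight = choice_align_weight)
  if (any(unlist(w) < 0)) stop("loss weights must be nonnegative")
  structure(w, class = "single_trial_loss_weights")
}

#' Trial-specific bias input in neural space
#'
#' \eqn{I^{(k)}_i = \sum_l u_i^l T_{lk}}: the constant input offset applied
#' to neuron i on trial k, obtained by mapping the trial's latent bias
#' coefficients (column k of \code{T_matrix}) through the low-rank basis.
#' The bias is constant within a trial and varies across trials.
#'
#' @param T_matrix P x K matrix of per-trial latent bias coefficients.
#' @param k trial index.
#' @param U N x P basis matrix.
#' @return length-N input vector.
#' @export
trial_bias_input <- function(T_matrix, k, U) {
  if (k < 1 || k > ncol(T_matrix)) stop("trial index out of range")
  as.numeric(U %*% T_matrix[, k])
}

#' Container for per-trial input biases
#'
#' @param T_matrix P x K matrix (rows = latent input directions, columns =
#'   trials).
#' @param condition per-trial condition labels (factor left/right).
#' @param outcome per-trial outcomes (1 = hit, 0 = miss).
#' @return a \code{trial_bias} object.
#' @export
trial_bias <- function(T_matrix, condition, outcome) {
  T_matrix <- as.matrix(T_matrix)
  if (!all(is.finite(T_matrix))) stop("bias coefficients must be finite")
  K <- ncol(T_matrix)
  stopifnot(length(condition) == K, length(outcome) == K)
  structure(list(T_matrix = T_matrix, condition = condition,
                 outcome = as.integer(outcome)),
            class = "trial_bias")
}

#' Epoch-averaged reconstruction loss
#'
#' \eqn{\sum_e \sum_{k,i} (\bar y_{ki}(e) - \bar r_{ki}(e))^2}, where the
#' bars denote averages over the time bins within epoch e. Matching only
#' epoch averages (rather than every bin) captures the slow trial-specific
#' offsets without penalising fast within-epoch fluctuations.
#'
#' @param model,data trials x time x neurons arrays on the same grid.
#' @param time length-T grid.
#' @param epochs named list of half-open intervals (e.g.
#'   \code{\link{default_epochs}}).
#' @return scalar loss.
#' @export
epoch_average_loss <- function(model, data, time, epochs) {
  stopifnot(all(dim(model) == dim(data)))
  total <- 0
  for (e in epochs) {
    idx <- which(time >= e[1] & time < e[2])
    if (!length(idx)) stop("empty epoch [", e[1], ", ", e[2], ")")
    mbar <- apply(model[, idx, , drop = FALSE], c(1, 3), mean)
    dbar <- apply(data[, idx, , drop = FALSE], c(1, 3), mean)
    total <- total + sum((mbar - dbar)^2)
  }
  total
}

#' Coding-projection loss
#'
#' Squared error between the model's projections onto its coding dimensions
#' and the data's projections onto the LDA axes, summed over trials, time
#' bins and the three coding dimensions:
#' \eqn{\sum_{k,t}\sum_l (r_{kt}^\top u_l - y_{kt}^\top v_l)^2}.
#'
#' @param model_rates trials x time x neurons array of model rates.
#' @param data_rates trials x time x neurons array of observed rates.
#' @param model_dims N x 3 model coding columns.
#' @param data_dims N x 3 LDA coding axes.
#' @return scalar loss.
#' @export
projection_loss <- function(model_rates, data_rates, model_dims, data_dims) {
  stopifnot(ncol(model_dims) == 3, ncol(data_dims) == 3)
  total <- 0
  K <- dim(model_rates)[1]
  for (k in seq_len(K)) {
    mp <- model_rates[k, , ] %*% model_dims
    dp <- data_rates[k, , ] %*% data_dims
    total <- total + sum((mp - dp)^2)
  }
  total
}

#' Jittered trial start times
#'
#' Draws i.i.d. uniform start offsets \eqn{t^{(k)}_{start} \sim
#' \mathcal U(-4.35, -2.35)} s relative to the go cue, one per trial.
#' Jittering the onset during training prevents the model from exploiting
#' the trial-specific bias to produce a stereotyped time-locked response
#' instead of integrating the stimulus.
#'
#' @param n_trials number of draws.
#' @param seed integer seed.
#' @param range length-2 interval (default \code{c(-4.35, -2.35)}).
#' @return numeric vector of start times.
#' @export
jittered_start <- function(n_trials, seed = 1L, range = c(-4.35, -2.35)) {
  set.seed(as.integer(seed))
  runif(n_trials, range[1], range[2])
}

# ---- single-trial training --------------------------------------------------

#' Jointly fit the network and per-trial input biases
#'
#' Optimises the network parameters (as in
#' \code{\link{train_condition_averaged}}) together with a P x K matrix of
#' trial-specific latent input biases, by Adam on the weighted sum of the
#' trial-averaged reconstruction, epoch-average, coding-projection,
#' alignment, orthogonality and bias-regularisation losses. To stabilise
#' training, the epoch/projection/regularisation terms are activated only
#' once the trial-averaged loss has fallen below a fraction
#' \code{activation_frac} of its initial value. When \code{jitter} is TRUE
#' each iteration redraws uniform trial start times in [-4.35, -2.35] s and
#' simulates each trial from its own onset (losses are always evaluated on
#' the data grid).
#'
#' @param data an \code{activity_tensor} (one simultaneously recorded
#'   session).
#' @param basis a \code{coding_basis}.
#' @param P latent dimensionality.
#' @param weights a \code{\link{single_trial_loss_weights}}.
#' @param opt an \code{\link{optimizer_config}}.
#' @param init optional warm start (list with \code{network}, \code{spec},
#'   optionally \code{T_matrix}).
#' @param jitter redraw trial start times each iteration (default TRUE).
#' @param activation_frac threshold fraction for activating the full loss
#'   set (default 0.1).
#' @param epochs epoch definitions (default: the tensor's).
#' @param measurement_filter pass model rates through the 50 ms observation
#'   filter before all data-facing losses (default TRUE; see
#'   \code{\link{train_condition_averaged}}).
#' @param verbose print checkpoint losses.
#' @return a \code{single_trial_fit}: list with \code{network}, \code{spec},
#'   \code{trial_bias}, \code{log}, \code{basis}.
#' @export
train_single_trial <- function(data, basis, P,
                               weights = single_trial_loss_weights(),
                               opt = optimizer_config(), init = NULL,
                               jitter = TRUE, activation_frac = 0.1,
                               epochs = NULL, measurement_filter = TRUE,
                               verbose = FALSE) {
  P <- as.integer(P)
  C <- ncol(basis$vectors)
  K <- dim(data$rates)[1]
  time <- data$time
  Tn <- length(time); N <- dim(data$rates)[3]
  dt <- data$dt; tau <- 0.040; alpha <- dt / tau
  if (is.null(epochs)) epochs <- data$epochs
  masks <- input_masks(time, data$tone_windows, data$go_window)
  lick_rate_t <- if (!is.null(data$lick_rate)) data$lick_rate else numeric(Tn)
  avg <- condition_average(data, hit_only = FALSE)
  cond_chr <- as.character(data$condition)
  Kc <- table(factor(cond_chr, levels = c("left", "right")))
  # data-side projections onto the LDA axes
  proj_data <- array(0, dim = c(K, Tn, C))
  for (k in seq_len(K)) proj_data[k, , ] <- data$rates[k, , ] %*% basis$vectors
  # epoch membership
  ep_idx <- lapply(epochs, function(e) which(time >= e[1] & time < e[2]))
  ep_idx <- ep_idx[vapply(ep_idx, length, 1L) > 0]

  set.seed(opt$seed)
  if (is.null(init)) {
    rmax0 <- pmax(2 * colMeans(rbind(avg$left, avg$right)), 0.5)
    ri <- regression_init(avg, basis, P, rmax0, masks, dt,
                          lick_rate_t = lick_rate_t)
    th <- list(U = ri$U, A = ri$A, rmax = rmax0,
               i_low = ri$i_low, i_high = ri$i_high, i_go = ri$i_go,
               lick_left = ri$lick_left, lick_right = ri$lick_right)
    Tmat <- matrix(0, P, K)
  } else {
    th <- list(U = init$network$U, A = init$network$A,
               rmax = init$network$rmax, i_low = init$spec$i_low,
               i_high = init$spec$i_high, i_go = init$spec$i_go,
               lick_left = init$spec$lick_left,
               lick_right = init$spec$lick_right)
    Tmat <- if (!is.null(init$T_matrix)) init$T_matrix else matrix(0, P, K)
  }

  x <- c(pack_params(th), as.numeric(Tmat))
  nb <- length(pack_params(th))
  ad <- adam_init(length(x))
  log_rows <- list()
  init_recon <- NA_real_
  full_on <- FALSE

  for (iter in seq_len(opt$max_iterations)) {
    th <- unpack_params(x[seq_len(nb)], N, P)
    Tmat <- matrix(x[(nb + 1):length(x)], P, K)
    starts <- if (jitter) jittered_start(K, seed = opt$seed + iter) else rep(time[1], K)
    terms <- st_loss_and_grad(th, Tmat, data, basis, weights, masks,
                              lick_rate_t, alpha, avg, Kc, proj_data,
                              ep_idx, starts, full_on,
                              filter_dt = if (measurement_filter) dt else NULL)
    if (!is.finite(terms$total))
      stop("single-trial training diverged at iteration ", iter)
    if (is.na(init_recon)) init_recon <- terms$recon
    if (!full_on && terms$recon < activation_frac * init_recon) full_on <- TRUE
    g <- clip_global_norm(terms$grad, opt$gradient_clip_norm)
    ad <- adam_step(ad, g, current_lr(opt, iter))
    x <- x - ad$step
    if (iter %% opt$checkpoint_every == 0 || iter == 1) {
      log_rows[[length(log_rows) + 1]] <-
        data.frame(iteration = iter, total = terms$total,
                   recon = terms$recon, epoch = terms$epoch,
                   proj = terms$proj, align = terms$align,
                   orth = terms$orth, reg = terms$reg,
                   full_losses = full_on)
      if (verbose)
        message(sprintf("iter %5d total %.5g recon %.5g epoch %.4g proj %.4g reg %.4g",
                        iter, terms$total, terms$recon, terms$epoch,
                        terms$proj, terms$reg))
    }
  }

  th <- unpack_params(x[seq_len(nb)], N, P)
  Tmat <- matrix(x[(nb + 1):length(x)], P, K)
  net <- lowrank_network(th$U, th$A, th$rmax, tau = tau, C = C, orth_tol = Inf)
  spec <- input_spec(P, N, i_low = th$i_low, i_high = th$i_high,
                     i_go = th$i_go, lick_left = th$lick_left,
                     lick_right = th$lick_right,
                     tone_windows = data$tone_windows,
                     go_window = data$go_window)
  structure(list(network = net, spec = spec,
                 trial_bias = trial_bias(Tmat, data$condition, data$outcome),
                 log = do.call(rbind, log_rows), basis = basis,
                 span = range(time), dt = dt),
            class = "single_trial_fit")
}

# loss + gradient for the single-trial objective; trials are simulated from
# their own (possibly jittered) start times, losses evaluated on the data
# grid only
st_loss_and_grad <- function(th, Tmat, data, basis, weights, masks,
                             lick_rate_t, alpha, avg, Kc, proj_data, ep_idx,
                             starts, full_on, filter_dt = NULL) {
  time <- data$time; Tn <- length(time)
  N <- nrow(th$U); P <- ncol(th$U); K <- ncol(Tmat)
  C <- ncol(basis$vectors)
  dt <- data$dt
  r0 <- th$rmax / 2
  cond_chr <- as.character(data$condition)

  rates <- array(0, dim = c(K, Tn, N))
  fw_store <- vector("list", K)
  pre_masks <- vector("list", K)
  for (k in seq_len(K)) {
    n_pre <- max(0L, as.integer(round((time[1] - starts[k]) / dt)))
    t_ext <- if (n_pre > 0) c(time[1] - (n_pre:1) * dt, time) else time
    mk <- input_masks(t_ext, data$tone_windows, data$go_window)
    lr_ext <- c(numeric(n_pre), lick_rate_t)
    I <- param_input_matrix(th, mk, cond_chr[k], lr_ext,
                            bias_latent = Tmat[, k])
    fw <- lr_forward_cpp(th$U, th$A, th$rmax, r0, alpha, I)
    pred <- if (is.null(filter_dt)) fw$rates
            else exp_smooth(fw$rates, filter_dt)
    rates[k, , ] <- pred[(n_pre + 1):(n_pre + Tn), ]
    fw_store[[k]] <- list(fw = fw, masks = mk, n_pre = n_pre, I = I,
                          lick = lr_ext)
    pre_masks[[k]] <- mk
  }

  # --- loss terms and dL/drates (on the data grid) ---
  Gr_data <- array(0, dim = c(K, Tn, N))
  rbar <- list(left = apply(rates[cond_chr == "left", , , drop = FALSE],
                            c(2, 3), mean),
               right = apply(rates[cond_chr == "right", , , drop = FALSE],
                             c(2, 3), mean))
  recon <- sum((rbar$left - avg$left)^2) + sum((rbar$right - avg$right)^2)
  for (k in seq_len(K)) {
    cc <- cond_chr[k]
    Gr_data[k, , ] <- Gr_data[k, , ] +
      2 * weights$c_recon * (rbar[[cc]] - avg[[cc]]) / Kc[[cc]]
  }

  epoch_l <- 0; proj_l <- 0
  if (full_on) {
    for (e in ep_idx) {
      mbar <- apply(rates[, e, , drop = FALSE], c(1, 3), mean)
      dbar <- apply(data$rates[, e, , drop = FALSE], c(1, 3), mean)
      dd <- mbar - dbar
      epoch_l <- epoch_l + sum(dd^2)
      for (k in seq_len(nrow(dd)))
        Gr_data[k, e, ] <- Gr_data[k, e, ] +
          matrix(2 * weights$c_epoch * dd[k, ] / length(e),
                 length(e), ncol(dd), byrow = TRUE)
    }
    Udims <- th$U[, seq_len(C), drop = FALSE]
    for (k in seq_len(K)) {
      dd <- rates[k, , ] %*% Udims - proj_data[k, , ]
      proj_l <- proj_l + sum(dd^2)
      Gr_data[k, , ] <- Gr_data[k, , ] +
        2 * weights$c_proj * dd %*% t(Udims)
    }
  }

  # --- backprop through each trial ---
  gU <- matrix(0, N, P); gA <- matrix(0, P, P); grmax <- numeric(N)
  gi <- list(i_low = numeric(P), i_high = numeric(P), i_go = numeric(P),
             lick_left = numeric(N), lick_right = numeric(N))
  gT <- matrix(0, P, K)
  for (k in seq_len(K)) {
    st <- fw_store[[k]]
    Tk_ext <- st$n_pre + Tn
    Gr <- matrix(0, Tk_ext, N)
    Gr[(st$n_pre + 1):Tk_ext, ] <- Gr_data[k, , ]
    if (!is.null(filter_dt)) Gr <- exp_smooth_adjoint(Gr, filter_dt)
    bw <- lr_backward_cpp(th$U, th$A, th$rmax, alpha, st$fw$rates,
                          st$fw$th, Gr)
    gU <- gU + bw$gU; gA <- gA + bw$gA
    grmax <- grmax + bw$grmax + bw$gr0 / 2
    inc <- input_grad_increments(bw$gI, th, st$masks, cond_chr[k], st$lick,
                                 bias_latent = Tmat[, k])
    gU <- gU + inc$U
    gT[, k] <- inc$bias
    for (nm in names(gi)) gi[[nm]] <- gi[[nm]] + inc[[nm]]
  }
  if (full_on) {
    gU[, seq_len(C)] <- gU[, seq_len(C)] + weights$c_proj *
      {
        Udims <- th$U[, seq_len(C), drop = FALSE]
        acc <- matrix(0, N, C)
        for (k in seq_len(K)) {
          mp <- rates[k, , ] %*% Udims
          acc <- acc + 2 * t(rates[k, , ]) %*% (mp - proj_data[k, , ])
        }
        acc
      }
  }

  align <- alignment_loss(th$U[, seq_len(C), drop = FALSE], basis$vectors,
                          weights$choice_align_weight)
  wal <- c(1, weights$choice_align_weight, 1)
  for (j in seq_len(C))
    gU[, j] <- gU[, j] + weights$c_align *
      neg_cos_grad(th$U[, j], basis$vectors[, j], wal[j])
  orth <- orthogonality_loss(th$U)
  gU <- gU + weights$c_orth * (-4) * th$U %*% (diag(P) - crossprod(th$U))
  reg <- sum(Tmat^2)
  gT <- gT + 2 * weights$c_reg * Tmat

  total <- weights$c_recon * recon + weights$c_epoch * epoch_l +
    weights$c_proj * proj_l + weights$c_align * align +
    weights$c_orth * orth + weights$c_reg * reg
  grad <- c(as.numeric(gU), as.numeric(gA), grmax * th$rmax,
            gi$i_low, gi$i_high, gi$i_go, gi$lick_left, gi$lick_right,
            as.numeric(gT))
  list(total = total, recon = recon, epoch = epoch_l, proj = proj_l,
       align = align, orth = orth, reg = reg, grad = grad)
}

#' Fit biases for held-out trials with a frozen network
#'
#' Optimises only the per-trial latent input biases of new (test) trials,
#' holding every network parameter fixed, by Adam on the per-trial squared
#' reconstruction error plus the bias regularisation. This is the
#' generalisation test of the single-trial model: the shared dynamics must
#' explain unseen trials through a P-dimensional shift of the operating
#' point alone.
#'
#' @param fit a \code{single_trial_fit} or list with \code{network} and
#'   \code{spec}.
#' @param data an \code{activity_tensor} of held-out trials.
#' @param c_reg bias regularisation weight (default 0.1).
#' @param opt an \code{\link{optimizer_config}} (a larger learning rate,
#'   e.g. 0.01, is appropriate for this convex-like subproblem).
#' @param measurement_filter pass model rates through the 50 ms observation
#'   filter before comparing to the recorded rates (default TRUE).
#' @return list with \code{trial_bias}, \code{explained_variance} (pooled
#'   over trials, time and neurons) and \code{per_trial_mse}.
#' @export
fit_test_trial_biases <- function(fit, data, c_reg = 0.1,
                                  opt = optimizer_config(learning_rate = 0.01,
                                                         max_iterations = 400),
                                  measurement_filter = TRUE) {
  net <- fit$network; spec <- fit$spec
  time <- data$time; Tn <- length(time)
  K <- dim(data$rates)[1]; N <- net$N; P <- net$P
  alpha <- data$dt / net$tau
  masks <- input_masks(time, data$tone_windows, data$go_window)
  lick_rate_t <- if (!is.null(data$lick_rate)) data$lick_rate else numeric(Tn)
  cond_chr <- as.character(data$condition)
  th <- list(U = net$U, A = net$A, rmax = net$rmax, i_low = spec$i_low,
             i_high = spec$i_high, i_go = spec$i_go,
             lick_left = spec$lick_left, lick_right = spec$lick_right)
  r0 <- net$rmax / 2
  Tmat <- matrix(0, P, K)
  ad <- adam_init(length(Tmat))
  for (iter in seq_len(opt$max_iterations)) {
    gT <- matrix(0, P, K)
    for (k in seq_len(K)) {
      I <- param_input_matrix(th, masks, cond_chr[k], lick_rate_t,
                              bias_latent = Tmat[, k])
      fw <- lr_forward_cpp(net$U, net$A, net$rmax, r0, alpha, I)
      pred <- if (measurement_filter) exp_smooth(fw$rates, data$dt) else fw$rates
      Gr <- 2 * (pred - data$rates[k, , ])
      if (measurement_filter) Gr <- exp_smooth_adjoint(Gr, data$dt)
      bw <- lr_backward_cpp(net$U, net$A, net$rmax, alpha, fw$rates, fw$th,
                            Gr)
      gT[, k] <- as.numeric(crossprod(net$U, colSums(bw$gI))) +
        2 * c_reg * Tmat[, k]
    }
    ad <- adam_step(ad, as.numeric(gT), opt$learning_rate)
    Tmat <- Tmat - matrix(ad$step, P, K)
  }
  # final predictions and fit quality
  pred <- array(0, dim = c(K, Tn, N))
  mse <- numeric(K)
  for (k in seq_len(K)) {
    I <- param_input_matrix(th, masks, cond_chr[k], lick_rate_t,
                            bias_latent = Tmat[, k])
    fw <- lr_forward_cpp(net$U, net$A, net$rmax, r0, alpha, I)
    pk <- if (measurement_filter) exp_smooth(fw$rates, data$dt) else fw$rates
    pred[k, , ] <- pk
    mse[k] <- mean((pk - data$rates[k, , ])^2)
  }
  ev <- explained_variance(list(pred), list(data$rates))
  list(trial_bias = trial_bias(Tmat, data$condition, data$outcome),
       explained_variance = ev, per_trial_mse = mse)
}

#' Estimate the error axes from trial biases
#'
#' For each choice side, trains a no-intercept L2-regularised logistic
#' decoder on the P-dimensional bias vectors to separate hit from miss
#' trials, using an 80/20 stratified split; the normalised decoder weights
#' are the error axis for that side. Standard deviations of the weights are
#' estimated by bootstrap refits on resamples of the training fraction.
#'
#' @param tb a \code{trial_bias} with both hits and misses per side.
#' @param lambda ridge penalty of the logistic decoder (default 1; near-
#'   separable bias sets blow up an unregularised no-intercept fit).
#' @param n_boot bootstrap iterations (default 1000).
#' @param train_frac training fraction of the stratified split (default 0.8).
#' @param seed integer seed for the split and the bootstrap.
#' @return an \code{error_axis} object: list with \code{weights} (P x 2,
#'   columns left/right, unit norm), \code{accuracy} (held-out, per side),
#'   \code{bootstrap_sd} (P x 2), \code{lambda}.
#' @export
estimate_error_axis <- function(tb, lambda = 1, n_boot = 1000,
                                train_frac = 0.8, seed = 1L) {
  P <- nrow(tb$T_matrix)
  out_w <- matrix(NA_real_, P, 2, dimnames = list(NULL, c("left", "right")))
  out_sd <- out_w
  acc <- c(left = NA_real_, right = NA_real_)
  set.seed(as.integer(seed))
  for (side in c("left", "right")) {
    idx <- which(tb$condition == side)
    y <- tb$outcome[idx]
    if (length(unique(y)) < 2)
      stop("need both hit and miss trials for side ", side)
    X <- t(tb$T_matrix[, idx, drop = FALSE])
    sp <- stratified_split(y, train_frac)
    w <- ridge_logistic(X[sp$train, , drop = FALSE], y[sp$train], lambda)
    pred <- as.numeric(X[sp$test, , drop = FALSE] %*% w) > 0
    acc[side] <- mean(pred == (y[sp$test] == 0))
    out_w[, side] <- w / sqrt(sum(w^2))
    if (n_boot > 0) {
      B <- matrix(NA_real_, P, n_boot)
      ntr <- length(sp$train)
      for (b in seq_len(n_boot)) {
        bs <- sample(seq_along(y), ntr, replace = TRUE)
        if (length(unique(y[bs])) < 2) next
        wb <- ridge_logistic(X[bs, , drop = FALSE], y[bs], lambda)
        B[, b] <- wb / sqrt(sum(wb^2))
      }
      out_sd[, side] <- apply(B, 1, stats::sd, na.rm = TRUE)
    }
  }
  structure(list(weights = out_w, accuracy = acc, bootstrap_sd = out_sd,
                 lambda = lambda),
            class = "error_axis")
}

# stratified train/test indices preserving the class ratio
stratified_split <- function(y, train_frac) {
  train <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_tr <- max(1, round(train_frac * length(idx)))
    train <- c(train, sample(idx, min(n_tr, length(idx))))
  }
  list(train = sort(train), test = setdiff(seq_along(y), train))
}

# no-intercept logistic regression with ridge penalty, by Newton iterations;
# class coding: miss (0) -> 1, hit (1) -> 0 so positive scores flag errors
ridge_logistic <- function(X, y, lambda, max_iter = 100) {
  z <- as.numeric(y == 0)
  P <- ncol(X)
  w <- numeric(P)
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% w)
    p <- 1 / (1 + exp(-eta))
    g <- as.numeric(crossprod(X, p - z)) + 2 * lambda * w
    Wd <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X, X * Wd) + 2 * lambda * diag(P)
    step <- solve(H, g)
    w <- w - step
    if (sqrt(sum(step^2)) < 1e-10 * (1 + sqrt(sum(w^2)))) break
  }
  w
}

#' Interpolate between the coding and residual components of an error axis
#'
#' Splits the error axis into its coding part (latent coordinates 1..C) and
#' residual part (C+1..P) and forms
#' \eqn{I(\alpha) = I_{Error} - \alpha I_{coding} + \alpha I_{residual}},
#' normalised to unit length so perturbations at different \eqn{\alpha}
#' share the same magnitude. \eqn{\alpha = -1} returns the normalised pure
#' coding component, \eqn{\alpha = 1} the normalised pure residual
#' component, \eqn{\alpha = 0} the normalised original axis.
#'
#' @param axis length-P error axis (a column of
#'   \code{estimate_error_axis()$weights}).
#' @param alpha interpolation parameter in [-1, 1].
#' @param C number of coding coordinates.
#' @return unit-norm length-P input-bias direction.
#' @export
interpolate_error_axis <- function(axis, alpha, C) {
  if (alpha < -1 || alpha > 1) stop("alpha must lie in [-1, 1]")
  axis <- as.numeric(axis)
  P <- length(axis)
  if (C < 1 || C >= P) stop("C must satisfy 1 <= C < P")
  coding <- c(axis[seq_len(C)], numeric(P - C))
  residual <- c(numeric(C), axis[(C + 1):P])
  if (sum(coding^2) == 0 || sum(residual^2) == 0)
    stop("error axis must have nonzero coding and residual components")
  v <- axis - alpha * coding + alpha * residual
  v / sqrt(sum(v^2))
}
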