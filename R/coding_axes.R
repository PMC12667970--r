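#' Extract a task-coding dimension by linear discriminant analysis
#'
#' Computes the two-class Fisher discriminant direction
#' \eqn{S_w^{-1}(\mu_R - \mu_L)} between the left and right
#' condition-averaged population vectors, treating the time bins inside
#' \code{window} as observations labelled by condition. Because pooled
#' pseudopopulations typically have far more neurons than time samples, the
#' within-class scatter is regularised by shrinkage towards a scaled
#' identity, \eqn{S_w(\gamma) = (1-\gamma) S_w + \gamma \,
#' \mathrm{tr}(S_w)/N \, I}.
#'
#' @param avgL,avgR T x N condition-averaged rate matrices on a shared grid.
#' @param time length-T vector of bin times (seconds relative to go cue).
#' @param window length-2 half-open interval selecting the time bins.
#' @param shrinkage shrinkage intensity in [0, 1] (default 0.1; use 0 only
#'   when the scatter is well-conditioned).
#' @return unit-norm length-N discriminant vector.
#' @export
extract_coding_dimension <- function(avgL, avgR, time, window,
                                     shrinkage = 0.1) {
  stopifnot(nrow(avgL) == length(time), nrow(avgR) == length(time),
            ncol(avgL) == ncol(avgR))
  idx <- which(time >= window[1] & time < window[2])
  if (!length(idx)) stop("window [", window[1], ", ", window[2],
                         ") contains no time bins of the grid")
  XL <- avgL[idx, , drop = FALSE]; XR <- avgR[idx, , drop = FALSE]
  muL <- colMeans(XL); muR <- colMeans(XR)
  d <- muR - muL
  scale <- max(sqrt(mean(muL^2) + mean(muR^2)), .Machine$double.eps)
  if (sqrt(sum(d^2)) < 1e-10 * max(scale, 1))
    stop("degenerate window: conditions are identical (no between-class separation)")
  N <- ncol(XL)
  cL <- sweep(XL, 2, muL); cR <- sweep(XR, 2, muR)
  n <- nrow(XL) + nrow(XR)
  Sw <- (crossprod(cL) + crossprod(cR)) / max(n - 2, 1)
  if (shrinkage > 0) {
    target <- sum(diag(Sw)) / N
    if (target <= 0) target <- 1
    Sw <- (1 - shrinkage) * Sw + shrinkage * target * diag(N)
  }
  w <- tryCatch(solve(Sw, d),
                error = function(e)
                  stop("within-class scatter is singular; increase shrinkage"))
  as.numeric(w / sqrt(sum(w^2)))
}

#' Default epoch windows for the three coding dimensions
#'
#' Sample: the first 600 ms of the sample period; choice: the 600 ms
#' preceding the go cue; response: the 350 ms following the go cue. All
#' intervals are half-open, in seconds relative to the go cue.
#'
#' @param sample_start onset of the sample period (first tone), default -1.85 s.
#' @param go_time go-cue time (default 0).
#' @return named list of length-2 intervals (sample, choice, response).
#' @export
default_windows <- function(sample_start = -1.85, go_time = 0) {
  list(sample = c(sample_start, sample_start + 0.6),
       choice = c(go_time - 0.6, go_time),
       response = c(go_time, go_time + 0.35))
}

#' Orthogonalise raw coding vectors into a coding basis
#'
#' Applies the Gram-Schmidt procedure to the columns in order (sample,
#' choice, response by convention), preserving the span and leaving the
#' first column's direction unchanged.
#'
#' @param raw_vectors N x C matrix of linearly independent columns.
#' @param windows optional named list of the defining time windows.
#' @param source tag, \code{"data-derived"} or \code{"model-derived"}.
#' @return a \code{coding_basis}: list with \code{vectors} (N x C,
#'   orthonormal), \code{windows}, \code{source}.
#' @export
orthogonalize_basis <- function(raw_vectors, windows = NULL,
                                source = c("data-derived", "model-derived")) {
  source <- match.arg(source)
  V <- as.matrix(raw_vectors)
  C <- ncol(V)
  nm <- colnames(V)
  if (is.null(nm)) nm <- paste0("v", seq_len(C))
  for (j in seq_len(C)) {
    v <- V[, j]
    if (j > 1) v <- v - V[, 1:(j - 1), drop = FALSE] %*%
        crossprod(V[, 1:(j - 1), drop = FALSE], v)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10 * max(sqrt(sum(V[, j]^2)), 1))
      stop("column ", nm[j], " is linearly dependent on the preceding columns")
    V[, j] <- v / nv
  }
  structure(list(vectors = V, windows = windows, source = source),
            class = "coding_basis")
}

#' Estimate the coding basis of a recording
#'
#' Runs \code{\link{extract_coding_dimension}} for the sample, choice and
#' response windows on the hit-trial condition averages, orthogonalises the
#' three directions by Gram-Schmidt (in that order), and orients the choice
#' axis so that the right-condition delay average projects positively (the
#' sample and response axes inherit their sign from the raw discriminants).
#'
#' @param tensor an \code{activity_tensor}.
#' @param windows named list of windows (default \code{\link{default_windows}}
#'   anchored at the tensor's tone schedule).
#' @param shrinkage passed to \code{\link{extract_coding_dimension}}. The
#'   default of 1 (full shrinkage to the isotropic target) reduces the
#'   discriminant to the normalised mean-difference direction, which is the
#'   appropriate limit for time-bin observations: the within-window scatter
#'   of a condition-averaged trajectory is deterministic ramping, not noise,
#'   and whitening by it distorts the axes. Use intermediate values for
#'   per-trial observations.
#' @return a \code{coding_basis}.
#' @export
estimate_coding_basis <- function(tensor, windows = NULL, shrinkage = 1) {
  if (is.null(windows))
    windows <- default_windows(sample_start = min(tensor$tone_windows),
                               go_time = tensor$go_window[1])
  avg <- condition_average(tensor)
  V <- vapply(windows, function(w)
    extract_coding_dimension(avg$left, avg$right, tensor$time, w, shrinkage),
    numeric(ncol(avg$left)))
  basis <- orthogonalize_basis(V, windows = windows, source = "data-derived")
  # sign convention: right-condition delay average projects positive on choice
  delay <- tensor$time >= windows$choice[1] & tensor$time < windows$choice[2]
  proj <- mean(avg$right[delay, , drop = FALSE] %*% basis$vectors[, 2])
  if (proj < 0) basis$vectors[, 2] <- -basis$vectors[, 2]
  basis
}

#' @export
print.coding_basis <- function(x, ...) {
  cat(sprintf("<coding_basis> %d neurons x %d dimensions (%s)\n",
              nrow(x$vectors), ncol(x$vectors), x$source))
  invisible(x)
}
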