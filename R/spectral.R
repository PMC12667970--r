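#' Normalised Henrici departure from normality
#'
#' \deqn{d_F(A) = \sqrt{\|A\|_F^2 - \sum_i |\lambda_i|^2} \, / \, \|A\|_F,}
#' clamped at 0 against round-off. A matrix is normal
#' (\eqn{A A^\top = A^\top A}, orthogonal eigenvectors) iff \eqn{d_F = 0};
#' the maximum \eqn{d_F = 1} is attained by nilpotent matrices, whose
#' eigenvalues all vanish and whose action is purely feedforward.
#'
#' @param A square numeric matrix, nonzero.
#' @return scalar in [0, 1].
#' @export
henrici_index <- function(A) {
  A <- as.matrix(A)
  fro2 <- sum(A^2)
  if (fro2 == 0) stop("Henrici index is undefined for the zero matrix")
  lam <- eigen(A, only.values = TRUE)$values
  sqrt(max(fro2 - sum(Mod(lam)^2), 0)) / sqrt(fro2)
}

#' Resolvent norm at a complex point
#'
#' \eqn{\|(zI - A)^{-1}\|_2}, computed as the reciprocal of the smallest
#' singular value of \eqn{zI - A}. For normal matrices this equals
#' \eqn{1/\min_i |z - \lambda_i|}; for non-normal matrices it can be much
#' larger even far from the spectrum. Returns \code{Inf} when \code{z} lies
#' within \code{tol} of an eigenvalue (resolvent unbounded).
#'
#' @param A square matrix.
#' @param z complex (or real) scalar.
#' @param tol distance to the spectrum below which the resolvent is flagged
#'   as unbounded.
#' @return positive scalar (possibly \code{Inf}).
#' @export
resolvent_norm <- function(A, z, tol = 1e-12) {
  A <- as.matrix(A)
  lam <- eigen(A, only.values = TRUE)$values
  if (min(Mod(z - lam)) < tol) return(Inf)
  M <- diag(as.complex(z), nrow(A)) - A
  1 / min(svd(M)$d)
}

#' Pseudospectrum of the interaction matrix on a complex grid
#'
#' Evaluates the resolvent norm \eqn{\|(zI-A)^{-1}\|_2} over a rectangular
#' lattice of complex values surrounding the spectrum, and (optionally) the
#' residual-subspace alignment of the most amplified input direction at each
#' point. Contours of \eqn{\log_{10}} resolvent norm visualise where small
#' input perturbations are most strongly amplified; for normal matrices the
#' contours are unions of circles around the eigenvalues.
#'
#' @param A square (P x P) matrix.
#' @param xlim,ylim real and imaginary ranges; default a bounding box 1.5x
#'   the spectral radius (at least 1) around the origin.
#' @param n lattice points per axis (default 201).
#' @param C number of leading coding coordinates; when given (and < P), the
#'   alignment field \eqn{\|R^\top v_1(z)\|} is also computed, with
#'   \eqn{v_1(z)} the top right singular vector of the resolvent and R the
#'   canonical residual coordinates C+1..P.
#' @param levels contour levels of resolvent norm retained as an attribute
#'   for reporting (defaults follow the conventional 5e-2..5e-3 decade for
#'   the inverse scale, i.e. resolvent norms 20..200).
#' @return a \code{pseudospectrum} object: list with \code{x}, \code{y},
#'   \code{resolvent_norm} (n x n matrix), and \code{alignment} (n x n or
#'   NULL).
#' @export
pseudospectrum_map <- function(A, xlim = NULL, ylim = NULL, n = 201,
                               C = NULL, levels = 1 / c(5e-2, 2e-2, 1e-2, 5e-3)) {
  A <- as.matrix(A)
  P <- nrow(A)
  lam <- eigen(A, only.values = TRUE)$values
  if (is.null(xlim) || is.null(ylim)) {
    rad <- max(Mod(lam), 1) * 1.5
    if (is.null(xlim)) xlim <- c(-rad, rad)
    if (is.null(ylim)) ylim <- c(-rad, rad)
  }
  x <- seq(xlim[1], xlim[2], length.out = n)
  y <- seq(ylim[1], ylim[2], length.out = n)
  res <- matrix(NA_real_, n, n)
  ali <- if (!is.null(C) && C < P) matrix(NA_real_, n, n) else NULL
  resid_idx <- if (!is.null(ali)) (C + 1):P else integer(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      z <- complex(real = x[i], imaginary = y[j])
      M <- diag(as.complex(z), P) - A
      sv <- svd(M)
      smin <- min(sv$d)
      res[i, j] <- if (smin < 1e-14) Inf else 1 / smin
      if (!is.null(ali)) {
        # most amplified input direction = left singular vector of M for
        # its smallest singular value
        v1 <- sv$u[, which.min(sv$d)]
        ali[i, j] <- min(sqrt(sum(Mod(v1[resid_idx])^2)), 1)
      }
    }
  }
  structure(list(x = x, y = y, resolvent_norm = res, alignment = ali,
                 eigenvalues = lam, levels = levels),
            class = "pseudospectrum")
}

#' Residual-subspace alignment of maximal amplification
#'
#' Convenience wrapper around \code{\link{pseudospectrum_map}} returning only
#' the alignment field \eqn{\|R^\top v_1(z)\|_2 \in [0,1]}: 0 when the most
#' amplified input direction lies in the coding coordinates, 1 when it lies
#' fully in the residual coordinates.
#'
#' @inheritParams pseudospectrum_map
#' @param C number of coding coordinates (must be < P).
#' @return a \code{pseudospectrum} whose \code{alignment} field is filled.
#' @export
residual_alignment_map <- function(A, C, xlim = NULL, ylim = NULL, n = 101) {
  if (C >= nrow(A)) stop("C must be smaller than the matrix dimension")
  pseudospectrum_map(A, xlim = xlim, ylim = ylim, n = n, C = C)
}

#' Ordered real Schur decomposition of the interaction matrix
#'
#' Computes \eqn{A = Q T Q^\top} with \eqn{Q} orthogonal and \eqn{T}
#' quasi-lower-triangular (2 x 2 diagonal blocks for complex-conjugate
#' pairs), with the modes ordered so that eigenvalues with negative real
#' parts come first. The strictly lower off-diagonal content of \eqn{T}
#' encodes the hidden feedforward (non-normal) couplings between Schur
#' modes. Only the negative/nonnegative partition of the ordering is
#' guaranteed; within the two groups the decomposition retains the
#' rotational freedom inherent to the Schur form.
#'
#' @param A real square matrix.
#' @return a \code{schur_modes} object: list with \code{Q}, \code{T},
#'   \code{eig} (complex eigenvalues in diagonal order), \code{eig_real},
#'   \code{n_negative} (size of the leading negative-real block).
#' @export
schur_modes <- function(A) {
  A <- as.matrix(A)
  # lower quasi-triangular form via the upper Schur form of t(A):
  # t(A) = Q Tu Q'  =>  A = Q t(Tu) Q' with t(Tu) lower quasi-triangular
  up <- ordered_schur_upper(t(A))
  Tm <- t(up$T)
  Q <- up$Q
  eig <- quasi_diag_eigenvalues(Tm)
  structure(list(Q = Q, T = Tm, eig = eig, eig_real = Re(eig),
                 n_negative = up$n_negative),
            class = "schur_modes")
}

# upper real Schur form with negative-real eigenvalues leading: compute an
# orthonormal basis of the invariant subspace of the negative-real
# eigenvalues, rotate A into block upper-triangular form, then Schur-factor
# each diagonal block with LAPACK (via Matrix::Schur).
ordered_schur_upper <- function(A) {
  P <- nrow(A)
  ev <- eigen(A)
  neg <- Re(ev$values) < 0
  k <- sum(neg)
  if (k == 0 || k == P) {
    s <- Matrix::Schur(A)
    return(list(Q = as.matrix(s$Q), T = as.matrix(s$T), n_negative = k))
  }
  # real basis of the invariant subspace for the negative-real group
  Vc <- ev$vectors[, neg, drop = FALSE]
  Vr <- cbind(Re(Vc), Im(Vc))
  qr1 <- qr(Vr)
  Q1 <- qr.Q(qr1)[, seq_len(k), drop = FALSE]
  Qfull <- qr.Q(qr(cbind(Q1, diag(P))))[, seq_len(P), drop = FALSE]
  B <- t(Qfull) %*% A %*% Qfull   # block upper triangular: B[(k+1):P, 1:k] ~ 0
  s1 <- Matrix::Schur(B[seq_len(k), seq_len(k), drop = FALSE])
  s2 <- Matrix::Schur(B[(k + 1):P, (k + 1):P, drop = FALSE])
  Qb <- as.matrix(Matrix::bdiag(s1$Q, s2$Q))
  Q <- Qfull %*% Qb
  Tm <- t(Qb) %*% B %*% Qb
  # zero the (2,1) block, which is zero up to round-off by construction
  Tm[(k + 1):P, seq_len(k)] <- 0
  list(Q = Q, T = Tm, n_negative = k)
}

# eigenvalues read off the 1x1 / 2x2 diagonal blocks of a quasi-triangular
# matrix (lower or upper)
quasi_diag_eigenvalues <- function(Tm, tol = 1e-10) {
  P <- nrow(Tm)
  eig <- complex(P)
  i <- 1
  scale <- max(abs(Tm), 1)
  while (i <= P) {
    paired <- i < P &&
      abs(Tm[i, i + 1]) > tol * scale && abs(Tm[i + 1, i]) > tol * scale
    if (paired) {
      blk <- Tm[i:(i + 1), i:(i + 1)]
      eig[i:(i + 1)] <- eigen(blk, only.values = TRUE)$values
      i <- i + 2
    } else {
      eig[i] <- Tm[i, i]
      i <- i + 1
    }
  }
  eig
}

#' Energy of the feedforward (non-normal) part of a Schur form
#'
#' Sums the squared strictly-lower entries of \eqn{T} outside the 2 x 2
#' diagonal blocks, plus the non-normal energy \eqn{(b + c)^2} of each
#' complex-pair block \eqn{[[a, b], [c, a]]} (whose skew part encodes the
#' rotation at frequency \eqn{\mathrm{Im}\,\lambda} and is normal). This
#' quantity equals \eqn{\|A\|_F^2 - \sum_i |\lambda_i|^2}, the unnormalised
#' Henrici departure of the original matrix.
#'
#' @param schur a \code{schur_modes} object.
#' @param tol block-detection tolerance.
#' @return nonnegative scalar.
#' @export
feedforward_energy <- function(schur, tol = 1e-10) {
  Tm <- schur$T
  P <- nrow(Tm)
  if (P < 2) return(0)
  scale <- max(abs(Tm), 1)
  in_block <- rep(FALSE, P - 1)  # i -> (i, i+1) is a 2x2 block
  i <- 1
  while (i < P) {
    if (abs(Tm[i, i + 1]) > tol * scale && abs(Tm[i + 1, i]) > tol * scale) {
      in_block[i] <- TRUE
      i <- i + 2
    } else i <- i + 1
  }
  total <- 0
  for (i in 2:P) for (j in seq_len(i - 1)) {
    if (i == j + 1 && in_block[j]) next  # within-block subdiagonal
    total <- total + Tm[i, j]^2
  }
  for (j in which(in_block))
    total <- total + (Tm[j, j + 1] + Tm[j + 1, j])^2
  total
}

#' Project latent trajectories onto the Schur mode basis
#'
#' \eqn{s(t) = Q^\top m(t)}: the columns of \eqn{Q} are the Schur vectors,
#' so the mode coordinates are the orthogonal projections of the latent
#' state. The transform is orthogonal, hence norm-preserving.
#'
#' @param latents a \code{latent_trajectory} (or T x P matrix).
#' @param Q P x P orthogonal Schur basis.
#' @return a \code{latent_trajectory} whose \code{m} holds the Schur-mode
#'   coordinates \eqn{s_l(t)}.
#' @export
project_schur <- function(latents, Q) {
  M <- if (is.list(latents)) latents$m else as.matrix(latents)
  S <- M %*% Q
  structure(list(time = if (is.list(latents)) latents$time else NULL, m = S),
            class = "latent_trajectory")
}
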