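# Ancestry inference by PCA projection: genetic relationship matrix,
# eigen-decomposition coordinates, and projection Procrustes alignment of a
# combined (reference + study sample) PCA space onto the reference space.

#' Genetic relationship matrix
#'
#' Computes `R R^T` over samples from a genotype matrix coded 0/1/2.
#' Missing genotypes are imputed to their column mean; columns are centered
#' by default (raw 0/1/2 products let allele-frequency offsets dominate the
#' leading eigenvector), optionally standardized.
#'
#' @param genotypes Numeric samples x loci matrix (0/1/2, `NA` allowed).
#' @param center,scale. Center / standardize genotype columns.
#' @return Symmetric positive semidefinite samples x samples matrix.
#' @export
compute_grm <- function(genotypes, center = TRUE, scale. = FALSE) {
  G <- as.matrix(genotypes)
  all_missing <- colSums(!is.na(G)) == 0L
  if (any(all_missing)) {
    warn(sprintf("%d all-missing column(s) dropped.", sum(all_missing)))
    G <- G[, !all_missing, drop = FALSE]
  }
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  G <- scale(G, center = center, scale = scale.)
  if (scale.) {
    # constant columns scale to NaN; treat as zero signal
    G[!is.finite(G)] <- 0
  }
  tcrossprod(G)
}

#' PCA coordinates from a GRM
#'
#' Top-K eigenvectors of the genetic relationship matrix scaled by the
#' square roots of their eigenvalues. Each coordinate's sign is fixed so
#' that its largest-magnitude element is positive.
#'
#' @param grm Symmetric samples x samples matrix.
#' @param K Number of components; must not exceed the number of positive
#'   eigenvalues.
#' @return Samples x K coordinate matrix.
#' @export
pca_coords <- function(grm, K = 2L) {
  e <- eigen(grm, symmetric = TRUE)
  pos <- sum(e$values > max(e$values) * 1e-12)
  if (K > pos) {
    abort(sprintf("K = %d exceeds the GRM rank (%d).", K, pos))
  }
  Y <- e$vectors[, seq_len(K), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(K)]), K)
  for (k in seq_len(K)) {
    if (Y[which.max(abs(Y[, k])), k] < 0) Y[, k] <- -Y[, k]
  }
  Y
}

# Projection-Procrustes objective ||rho * X A - Y||_F^2.
procrustes_objective <- function(X, Y, A, rho) {
  D <- rho * X %*% A - Y
  sum(D * D)
}

#' Projection Procrustes alignment
#'
#' Finds an orthonormal projection matrix `A` (K' x K, `A^T A = I`) and an
#' isotropic scaling factor `rho` minimizing `||rho * Y_combined A -
#' Y_ref||_F^2`, where the rows of `Y_combined` excluding the new sample(s)
#' correspond 1:1 to rows of `Y_ref`. Solved by a
#' majorization-minimization iteration whose inner step is an orthogonal
#' Procrustes problem (SVD polar factor), alternated with the closed-form
#' update of `rho`; monotone in the objective and initialized from the SVD
#' of the cross-covariance.
#'
#' @param Y_ref Reference coordinates (n x K).
#' @param Y_combined Combined-space coordinates ((n + m) x K'), K' >= K; the
#'   first n rows correspond to `Y_ref`, trailing rows are the new
#'   sample(s).
#' @param tol,max_iter Convergence tolerance on the objective and iteration
#'   cap.
#' @return An `ancestry_projection`: list with `A`, `rho`, `y` (projected
#'   coordinates of the trailing rows), `Y_ref`, `error` (minimized
#'   objective) and `K`, `Kprime`.
#' @export
procrustes_project <- function(Y_ref, Y_combined, tol = 1e-12,
                               max_iter = 2000L) {
  Y <- as.matrix(Y_ref)
  Z <- as.matrix(Y_combined)
  n <- nrow(Y)
  K <- ncol(Y)
  Kp <- ncol(Z)
  if (Kp < K) abort("`Y_combined` must have at least as many columns as `Y_ref`.")
  if (nrow(Z) < n) abort("`Y_combined` must contain the reference rows.")
  X <- Z[seq_len(n), , drop = FALSE]

  S <- crossprod(X)              # K' x K'
  C <- crossprod(X, Y)           # K' x K
  lam <- max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)

  polar <- function(W) {
    sv <- svd(W)
    sv$u %*% t(sv$v)
  }

  # init: orthonormal factor of the cross-covariance
  A <- polar(C)
  rho <- sum(A * C) / sum(A * (S %*% A))
  obj <- procrustes_objective(X, Y, A, rho)
  for (it in seq_len(max_iter)) {
    # MM step for A: majorize rho^2 tr(A' S A) at the current A, leaving a
    # linear Stiefel problem solved by the polar factor
    W <- rho * C + rho^2 * ((lam * diag(Kp) - S) %*% A)
    A <- polar(W)
    rho <- sum(A * C) / sum(A * (S %*% A))
    new_obj <- procrustes_objective(X, Y, A, rho)
    if (obj - new_obj < tol * max(1, obj)) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }

  extra <- Z[-seq_len(n), , drop = FALSE]
  structure(list(
    A = A, rho = rho,
    y = rho * extra %*% A,
    Y_ref = Y, Y_combined = Z,
    error = obj, K = K, Kprime = Kp
  ), class = "ancestry_projection")
}

#' @export
print.ancestry_projection <- function(x, ...) {
  cat(sprintf("<ancestry_projection> K'=%d -> K=%d; rho=%.4f; error=%.6g; %d projected sample(s)\n",
              x$Kprime, x$K, x$rho, x$error, nrow(x$y)))
  invisible(x)
}

#' @export
glance.ancestry_projection <- function(x, ...) {
  tibble(K = x$K, Kprime = x$Kprime, rho = x$rho, error = x$error,
         n_reference = nrow(x$Y_ref), n_projected = nrow(x$y))
}

#' @export
tidy.ancestry_projection <- function(x, ...) {
  bind_rows(
    as_tibble(x$Y_ref, .name_repair = ~ paste0("PC", seq_along(.x))) %>%
      mutate(role = "reference"),
    as_tibble(x$y, .name_repair = ~ paste0("PC", seq_len(ncol(x$y)))) %>%
      mutate(role = "projected")
  )
}

#' Project a study sample onto a reference population PCA
#'
#' End-to-end wrapper: builds the GRM and PCA coordinates of the reference
#' genotypes (K components), repeats both for the combined matrix including
#' the study sample(s) (K' components), and aligns the combined space onto
#' the reference space with projection Procrustes.
#'
#' @param ref_genotypes Reference samples x loci genotype matrix (0/1/2).
#' @param sample_genotypes Study genotypes: vector (one sample) or matrix
#'   over the same loci; `NA` for missing calls.
#' @param K,Kprime Reference / combined PCA dimensions (K' >= K).
#' @param center,scale. Passed to [compute_grm()].
#' @return An `ancestry_projection`.
#' @export
project_ancestry <- function(ref_genotypes, sample_genotypes, K = 2L,
                             Kprime = 4L, center = TRUE, scale. = FALSE) {
  R <- as.matrix(ref_genotypes)
  g <- if (is.null(dim(sample_genotypes))) {
    matrix(sample_genotypes, nrow = 1)
  } else {
    as.matrix(sample_genotypes)
  }
  if (ncol(g) != ncol(R)) abort("locus sets of reference and sample differ.")
  Y_ref <- pca_coords(compute_grm(R, center, scale.), K)
  Y_comb <- pca_coords(compute_grm(rbind(R, g), center, scale.), Kprime)
  procrustes_project(Y_ref, Y_comb)
}
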