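# Independent oracle implementations used to cross-check the package:
# written as direct transcriptions of the definitions (loops and explicit
# enumeration), deliberately sharing no code with the implementation.

# Genotype posteriors by exhaustive enumeration over all pairs of donor
# paths of the haplotype-copying model (feasible for K^(2n) small).
oracle_hmm_gp <- function(gl_lin, hap, pos, theta, rho_scale) {
  K <- nrow(hap)
  n <- ncol(hap)
  r <- 1 - exp(-diff(pos) / rho_scale)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  w <- rep(1 / K, nrow(paths))
  if (n > 1) {
    for (t in 2:n) {
      stay <- paths[, t] == paths[, t - 1]
      w <- w * ifelse(stay, (1 - r[t - 1]) + r[t - 1] / K, r[t - 1] / K)
    }
  }
  q <- matrix(ifelse(t(hap) == 1, 1 - theta, theta), n, K)
  gp <- matrix(0, n, 3)
  tot <- 0
  np <- nrow(paths)
  for (i in seq_len(np)) {
    qi <- q[cbind(seq_len(n), paths[i, ])]
    for (j in seq_len(np)) {
      qj <- q[cbind(seq_len(n), paths[j, ])]
      p0 <- (1 - qi) * (1 - qj)
      p1 <- qi * (1 - qj) + (1 - qi) * qj
      p2 <- qi * qj
      e <- gl_lin[, 1] * p0 + gl_lin[, 2] * p1 + gl_lin[, 3] * p2
      wp <- w[i] * w[j] * prod(e)
      tot <- tot + wp
      gp <- gp + (wp / e) *
        cbind(gl_lin[, 1] * p0, gl_lin[, 2] * p1, gl_lin[, 3] * p2)
    }
  }
  gp / tot
}

# Two- and three-locus LD refinement profile by brute-force loops over all
# cells and index pairs/triples, following the neighbourhood set-builders
# literally (intermediate sites must carry zero counts; three-locus flanks
# must agree on a haplotype, pooled over both haplotypes).
oracle_ld_profile <- function(c1, c2, pos, bins) {
  n_sites <- nrow(c1)
  n_cells <- ncol(c1)
  n_bins <- length(bins) - 1L
  cnt2 <- coseg2 <- cnt3 <- coseg3 <- rep(0L, n_bins)
  covered <- (c1 + c2) > 0
  for (j in seq_len(n_cells)) {
    for (k in seq_len(n_sites - 1L)) {
      if (!covered[k, j]) next
      for (i in (k + 1L):n_sites) {
        if (!covered[i, j]) next
        # adjacency: all intermediate sites uncovered in this cell
        if (i > k + 1L && any(covered[(k + 1L):(i - 1L), j])) break
        d <- pos[i] - pos[k]
        b <- max(which(bins <= d))
        if (b > n_bins) b <- n_bins
        cnt2[b] <- cnt2[b] + 1L
        if (c1[k, j] * c1[i, j] > 0 || c2[k, j] * c2[i, j] > 0) {
          coseg2[b] <- coseg2[b] + 1L
        }
        # extend to the next covered site for the three-locus triple
        if (i < n_sites) {
          for (l in (i + 1L):n_sites) {
            if (!covered[l, j]) next
            if (l > i + 1L && any(covered[(i + 1L):(l - 1L), j])) break
            d3 <- pos[i] - pos[k]
            b3 <- max(which(bins <= d3))
            if (b3 > n_bins) b3 <- n_bins
            if (c1[k, j] * c1[l, j] > 0) {
              cnt3[b3] <- cnt3[b3] + 1L
              if (c1[i, j] > 0) coseg3[b3] <- coseg3[b3] + 1L
            }
            if (c2[k, j] * c2[l, j] > 0) {
              cnt3[b3] <- cnt3[b3] + 1L
              if (c2[i, j] > 0) coseg3[b3] <- coseg3[b3] + 1L
            }
            break
          }
        }
        break
      }
    }
  }
  list(score2 = ifelse(cnt2 > 0, 1 - coseg2 / cnt2, NA_real_), n2 = cnt2,
       score3 = ifelse(cnt3 > 0, 1 - coseg3 / cnt3, NA_real_), n3 = cnt3)
}

# Random sparse phased count matrices for the oracle-equivalence suite.
random_count_matrix <- function(n_cells, n_sites, span = 2000) {
  pos <- sort(sample.int(span, n_sites))
  c1 <- matrix(rbinom(n_sites * n_cells, 2, 0.3), n_sites, n_cells)
  c2 <- matrix(rbinom(n_sites * n_cells, 2, 0.3), n_sites, n_cells)
  list(c1 = c1, c2 = c2, pos = pos)
}

count_matrix_to_tibbles <- function(m) {
  idx <- which((m$c1 + m$c2) >= 0, arr.ind = TRUE)
  counts <- tibble::tibble(
    site = as.integer(idx[, 1]),
    cell = sprintf("c%03d", idx[, 2]),
    c1 = as.integer(m$c1[idx]),
    c2 = as.integer(m$c2[idx])
  )
  sites <- tibble::tibble(site = seq_along(m$pos), pos = m$pos)
  list(counts = counts, sites = sites)
}

# Projection-Procrustes objective minimized by a general-purpose optimizer
# over an unconstrained parameterization (orthonormalized by QR) with
# multiple random restarts.
oracle_procrustes_min <- function(Y_ref, Y_comb, n_starts = 20) {
  X <- as.matrix(Y_comb)[seq_len(nrow(Y_ref)), , drop = FALSE]
  Y <- as.matrix(Y_ref)
  Kp <- ncol(X)
  K <- ncol(Y)
  obj <- function(par) {
    M <- matrix(par[-1], Kp, K)
    qr_m <- qr(M)
    if (qr_m$rank < K) return(1e10)
    A <- qr.Q(qr_m)[, seq_len(K), drop = FALSE]
    D <- par[1] * X %*% A - Y
    sum(D * D)
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    par0 <- c(runif(1, 0.1, 2), rnorm(Kp * K))
    fit <- optim(par0, obj, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
    fit <- optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
    if (fit$value < best) best <- fit$value
  }
  best
}
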