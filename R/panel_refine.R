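# Reference-panel genotype refinement: a diploid haplotype-copying
# (Li-Stephens-type) HMM over ordered pairs of panel haplotypes. Each of the
# two chains copies one panel haplotype, switching donors between adjacent
# sites with probability r = 1 - exp(-distance / rho_scale) (after a switch
# the donor is uniform over the panel) and miscopying an allele with
# probability theta. The per-site observation likelihood GL(g | d) is folded
# into the emission, so the posterior GP(g | H, d) borrows LD information
# from the panel. Chain transitions factorize, which keeps the forward-
# backward pass at O(K^2) per site.

# Emission matrix over state pairs at one site.
# q[k] = P(chain emits the alternative allele | donor k).
pair_emission <- function(gl_lin, q) {
  p0 <- outer(1 - q, 1 - q)
  p1 <- outer(q, 1 - q) + outer(1 - q, q)
  p2 <- outer(q, q)
  list(E = gl_lin[1] * p0 + gl_lin[2] * p1 + gl_lin[3] * p2,
       p0 = p0, p1 = p1, p2 = p2)
}

# Apply the factorized pair transition to a K x K mass matrix.
pair_transition <- function(M, r, K) {
  if (r <= 0) return(M)
  M1 <- (1 - r) * M + (r / K) * matrix(colSums(M), K, K, byrow = TRUE)
  (1 - r) * M1 + (r / K) * matrix(rowSums(M1), K, K)
}

# Forward-backward + Viterbi over the pair HMM.
# gl_lin: n x 3 normalized likelihoods; hap: K x n 0/1 panel matrix;
# pos: site positions (bp). Returns genotype posteriors and the Viterbi
# donor pair per site.
copy_hmm <- function(gl_lin, hap, pos, theta = 1e-3, rho_scale = 1e5) {
  K <- nrow(hap)
  n <- ncol(hap)
  if (K < 2) abort("the reference panel must contain at least 2 haplotypes.")
  r <- if (n > 1) 1 - exp(-diff(pos) / rho_scale) else numeric(0)

  Es <- vector("list", n)
  for (t in seq_len(n)) {
    q <- ifelse(hap[, t] == 1L, 1 - theta, theta)
    Es[[t]] <- pair_emission(gl_lin[t, ], q)
  }

  # forward
  alphas <- vector("list", n)
  a <- Es[[1]]$E / (K * K)
  alphas[[1]] <- a / sum(a)
  for (t in seq_len(n)[-1]) {
    a <- pair_transition(alphas[[t - 1]], r[t - 1], K) * Es[[t]]$E
    alphas[[t]] <- a / sum(a)
  }

  # backward
  betas <- vector("list", n)
  betas[[n]] <- matrix(1, K, K)
  if (n > 1) {
    for (t in rev(seq_len(n - 1))) {
      b <- pair_transition(betas[[t + 1]] * Es[[t + 1]]$E, r[t], K)
      betas[[t]] <- b / sum(b)
    }
  }

  gp <- matrix(NA_real_, n, 3)
  for (t in seq_len(n)) {
    w <- alphas[[t]] * betas[[t]] / Es[[t]]$E
    w[!is.finite(w)] <- 0
    g0 <- gl_lin[t, 1] * sum(w * Es[[t]]$p0)
    g1 <- gl_lin[t, 2] * sum(w * Es[[t]]$p1)
    g2 <- gl_lin[t, 3] * sum(w * Es[[t]]$p2)
    s <- g0 + g1 + g2
    gp[t, ] <- c(g0, g1, g2) / s
  }

  # Viterbi (max-product) with the same factorized transition; rescaled by
  # the matrix maximum each step to avoid underflow.
  V <- Es[[1]]$E / (K * K)
  V <- V / max(V)
  Vs <- vector("list", n)
  Vs[[1]] <- V
  for (t in seq_len(n)[-1]) {
    rt <- r[t - 1]
    c1 <- (1 - rt)
    c2 <- rt / K
    cm <- matrix(apply(V, 2, max), K, K, byrow = TRUE)
    rm <- matrix(apply(V, 1, max), K, K)
    gm <- max(V)
    V <- pmax(c1 * c1 * V, c1 * c2 * cm, c2 * c1 * rm, c2 * c2 * gm) *
      Es[[t]]$E
    V <- V / max(V)
    Vs[[t]] <- V
  }
  path <- matrix(NA_integer_, n, 2)
  idx <- which(Vs[[n]] == max(Vs[[n]]), arr.ind = TRUE)[1, ]
  path[n, ] <- as.integer(idx)
  if (n > 1) {
    for (t in rev(seq_len(n - 1))) {
      rt <- r[t]
      c1 <- (1 - rt)
      c2 <- rt / K
      kk <- path[t + 1, 1]
      ll <- path[t + 1, 2]
      V <- Vs[[t]]
      cand <- c(
        c1 * c1 * V[kk, ll],
        c1 * c2 * max(V[, ll]),
        c2 * c1 * max(V[kk, ]),
        c2 * c2 * max(V)
      )
      best <- which.max(cand)
      path[t, ] <- switch(best,
        c(kk, ll),
        c(which.max(V[, ll]), ll),
        c(kk, which.max(V[kk, ])),
        as.integer(which(V == max(V), arr.ind = TRUE)[1, ])
      )
    }
  }

  list(gp = gp, path = path)
}

#' Refine genotype likelihoods with a phased reference panel
#'
#' Updates per-site genotype likelihoods GL(g | d) to genotype posteriors
#' GP(g | H, d) by running a diploid haplotype-copying HMM over the phased
#' reference haplotypes, so that linkage disequilibrium in the panel
#' compensates for sparse or noisy per-site evidence. Also reports the
#' maximum-likelihood / maximum-posterior genotypes, a per-site concordance
#' status, and a Viterbi-based phase orientation at heterozygous sites
#' (which haplotype carries the alternative allele), consumed by the
#' cell-population LD models.
#'
#' @param gl Tibble of sites with `chrom`, `pos`, `ref`, `alt` and
#'   log-likelihood columns `gl0`, `gl1`, `gl2` (from
#'   [genotype_likelihoods()]); all sites must be present in the panel and
#'   ordered by position.
#' @param panel A `ref_panel` (or a list with `sites` and `haplotypes`).
#' @param theta Copying fidelity: probability that a copied allele differs
#'   from its donor (default 1e-3).
#' @param rho_scale Distance scale of donor switching in bp (default 1e5,
#'   i.e. one expected switch per 100 kb).
#' @param max_panel_haplotypes Cap on the number of panel haplotypes used
#'   (the first so many rows); keeps the O(K^2) state space tractable.
#' @return The input tibble with added columns `gp0`, `gp1`, `gp2`
#'   (normalized posteriors), `gt_gl`, `gt_gp` (argmax genotypes, ties broken
#'   toward the smaller g), `status` (`germline_kept`,
#'   `discordant_error_candidate`, or `discordant_other`) and `hap1_is_alt`
#'   (phase orientation at het sites; NA elsewhere).
#' @export
refine_genotypes <- function(gl, panel, theta = 1e-3, rho_scale = 1e5,
                             max_panel_haplotypes = 200L) {
  gl <- as_tibble(gl)
  stopifnot(all(c("chrom", "pos", "gl0", "gl1", "gl2") %in% names(gl)))
  psites <- panel$sites
  key <- paste(gl$chrom, gl$pos)
  pkey <- paste(psites$chrom, psites$pos)
  m <- match(key, pkey)
  if (anyNA(m)) {
    abort(sprintf("%d site(s) are not present in the reference panel.",
                  sum(is.na(m))))
  }
  if (is.unsorted(gl$pos)) abort("`gl` sites must be ordered by position.")
  hap <- panel$haplotypes[, m, drop = FALSE]
  if (nrow(hap) > max_panel_haplotypes) {
    hap <- hap[seq_len(max_panel_haplotypes), , drop = FALSE]
  }

  gl_lin <- gl_normalize(as.matrix(gl[, c("gl0", "gl1", "gl2")]))
  fit <- copy_hmm(gl_lin, hap, gl$pos, theta = theta, rho_scale = rho_scale)

  gt_gl <- argmax_genotype(gl_lin)
  gt_gp <- argmax_genotype(fit$gp)
  hap1_allele <- hap[cbind(fit$path[, 1], seq_len(nrow(gl)))]
  hap2_allele <- hap[cbind(fit$path[, 2], seq_len(nrow(gl)))]
  # phase orientation only meaningful at het calls; when the Viterbi donors
  # disagree with the het call, fall back to the first-chain allele
  hap1_is_alt <- ifelse(gt_gp == 1L,
                        ifelse(hap1_allele != hap2_allele,
                               hap1_allele == 1L, NA),
                        NA)
  # deterministic fallback for ambiguous het phases
  amb <- which(gt_gp == 1L & is.na(hap1_is_alt))
  if (length(amb)) hap1_is_alt[amb] <- rep(c(TRUE, FALSE),
                                           length.out = length(amb))

  gl %>%
    mutate(gp0 = fit$gp[, 1], gp1 = fit$gp[, 2], gp2 = fit$gp[, 3],
           gt_gl = gt_gl, gt_gp = gt_gp,
           status = case_when(
             gt_gl == gt_gp ~ "germline_kept",
             gt_gp == 0L & gt_gl %in% c(1L, 2L) ~ "discordant_error_candidate",
             TRUE ~ "discordant_other"
           ),
           hap1_is_alt = hap1_is_alt)
}

#' Split refined calls into final germline calls and error-model loci
#'
#' Concordant loci (argmax GL equals argmax GP) form the final germline call
#' set. Loci called non-reference from the data but imputed homozygous
#' reference by the panel are routed to the sequencing-error model (with
#' their allele pair and pooled BAF); all discordant loci are excluded from
#' the germline call set.
#'
#' @param refined Output of [refine_genotypes()]; a `baf` column is carried
#'   through to the error-model loci when present.
#' @return List with `germline` (tibble of kept calls with `genotype`) and
#'   `error_loci` (tibble with `chrom`, `pos`, `ref`, `alt`, `hom_allele`,
#'   `baf`).
#' @export
consensus_calls <- function(refined) {
  refined <- as_tibble(refined)
  germline <- refined %>%
    filter(.data$status == "germline_kept") %>%
    mutate(genotype = .data$gt_gp)
  error_loci <- refined %>%
    filter(.data$status == "discordant_error_candidate") %>%
    mutate(hom_allele = .data$ref) %>%
    select(dplyr::any_of(c("chrom", "pos", "ref", "alt", "hom_allele",
                           "baf", "gt_gl", "gt_gp")))
  list(germline = germline, error_loci = error_loci)
}
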