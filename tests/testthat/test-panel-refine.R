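flat_gl <- function(pos, chrom = "chr1", ref = "A", alt = "G") {
  tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 gl0 = 0, gl1 = 0, gl2 = 0)
}

test_that("GP concentrates on a consistent panel haplotype pair", {
  p <- simulate_panel(n_hap = 10, n_sites = 40, span_bp = 2e4,
                      maf_min = 0.1, seed = 14)
  g_true <- p$haplotypes[3, ] + p$haplotypes[7, ]
  gl <- flat_gl(p$sites$pos)
  gl$ref <- p$sites$ref
  gl$alt <- p$sites$alt
  # delta-function likelihoods at the true genotypes
  m <- matrix(log(1e-12), nrow(gl), 3)
  m[cbind(seq_len(nrow(gl)), g_true + 1L)] <- 0
  gl$gl0 <- m[, 1]; gl$gl1 <- m[, 2]; gl$gl2 <- m[, 3]
  ref <- refine_genotypes(gl, p, theta = 1e-6)
  gp <- as.matrix(ref[, c("gp0", "gp1", "gp2")])
  expect_true(all(gp[cbind(seq_len(nrow(gp)), g_true + 1L)] > 0.99))
  expect_equal(rowSums(gp), rep(1, nrow(gp)), tolerance = 1e-9)
  # deterministic given identical inputs
  expect_identical(ref, refine_genotypes(gl, p, theta = 1e-6))
})

test_that("single-site flat GL recovers Hardy-Weinberg panel frequencies", {
  H <- matrix(c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L), ncol = 1)
  panel <- structure(list(
    sites = tibble::tibble(chrom = "chr1", pos = 500L, ref = "A", alt = "T"),
    haplotypes = H, span_bp = 1000), class = "ref_panel")
  theta <- 1e-3
  ref <- refine_genotypes(flat_gl(500L, ref = "A", alt = "T"), panel,
                          theta = theta)
  q <- mean(H) * (1 - theta) + (1 - mean(H)) * theta # theta-adjusted freq
  expect_equal(c(ref$gp0, ref$gp1, ref$gp2),
               c((1 - q)^2, 2 * q * (1 - q), q^2), tolerance = 1e-12)
})

test_that("pair HMM equals exhaustive haplotype-pair summation", {
  withr::with_seed(31, {
    for (rep in 1:3) {
      K <- 4; n <- 4
      hap <- matrix(rbinom(K * n, 1, 0.5), K, n)
      pos <- sort(sample.int(2e5, n))
      gl_lin <- cellsnv:::gl_normalize(matrix(rnorm(n * 3), n, 3))
      fit <- cellsnv:::copy_hmm(gl_lin, hap, pos, theta = 1e-3,
                                rho_scale = 1e5)
      oracle <- oracle_hmm_gp(gl_lin, hap, pos, theta = 1e-3,
                              rho_scale = 1e5)
      expect_lt(max(abs(fit$gp - oracle) / pmax(oracle, 1e-12)), 1e-8)
    }
  })
})

test_that("refinement validates its inputs", {
  p <- simulate_panel(n_hap = 8, n_sites = 20, span_bp = 1e4, seed = 1)
  off_panel <- flat_gl(p$sites$pos[1] + 1L)
  expect_error(refine_genotypes(off_panel, p), "not present")
  one_hap <- p
  one_hap$haplotypes <- p$haplotypes[1, , drop = FALSE]
  expect_error(refine_genotypes(flat_gl(p$sites$pos, ref = p$sites$ref,
                                        alt = p$sites$alt), one_hap),
               "at least 2")
})

test_that("consensus routing keeps concordant calls and flags errors", {
  refined <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L), ref = "A", alt = "T",
    baf = c(0.5, 0.1, 0.02),
    gt_gl = c(1L, 1L, 0L), gt_gp = c(1L, 0L, 2L),
    status = c("germline_kept", "discordant_error_candidate",
               "discordant_other"))
  cc <- consensus_calls(refined)
  expect_identical(cc$germline$pos, 10L)
  expect_identical(cc$germline$genotype, 1L)
  # het-by-data, hom-ref-by-panel routed to the error model
  expect_identical(cc$error_loci$pos, 20L)
  # other discordances excluded but not routed
  expect_false(30L %in% cc$error_loci$pos)
})

test_that("panel refinement improves genotype accuracy on sparse data", {
  withr::with_seed(55, {
    p <- simulate_panel(n_hap = 40, n_sites = 600, span_bp = 5e5,
                        recomb_intensity = 2e-5, seed = 77)
    s <- simulate_sample(p, expected_breakpoints = 2, seed = 78)
    # 20% of sites covered at depth 1-2, 1% error rate, Q20 reads
    covered <- withr::with_seed(79, which(runif(600) < 0.2))
    gl <- flat_gl(p$sites$pos, ref = p$sites$ref, alt = p$sites$alt)
    for (i in covered) {
      dp <- sample(1:2, 1)
      alleles <- ifelse(runif(dp) < s$genotype[i] / 2, 1L, 0L)
      err <- runif(dp) < 0.01
      alleles <- ifelse(err, 1L - alleles, alleles)
      ll <- cellsnv:::gl_from_counts(sum(alleles == 0), sum(alleles == 1),
                                     error_rate = 0.01)
      gl$gl0[i] <- ll[1]; gl$gl1[i] <- ll[2]; gl$gl2[i] <- ll[3]
    }
    ref <- refine_genotypes(gl, p)
    acc_gl <- mean(ref$gt_gl == s$genotype)
    acc_gp <- mean(ref$gt_gp == s$genotype)
    expect_gt(acc_gp, acc_gl)
  })
})
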