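tbl_counts <- function(mat_c1, mat_c2, pos) {
  m <- list(c1 = mat_c1, c2 = mat_c2, pos = pos)
  count_matrix_to_tibbles(m)
}

test_that("two-locus neighbourhoods are adjacent covered pairs", {
  pos <- c(100L, 200L, 300L)
  # cell A covers sites 1 and 3 (2 uncovered); cell B covers all three;
  # cell C covers one site only
  c1 <- cbind(c(1, 0, 1), c(1, 1, 1), c(0, 1, 0))
  c2 <- matrix(0, 3, 3)
  x <- tbl_counts(c1, c2, pos)
  nb <- cellsnv:::neighborhoods_two(x$counts, x$sites)
  a <- nb[nb$cell == "c001", ]
  expect_identical(nrow(a), 1L)
  expect_identical(c(a$site_k, a$site_i), c(1L, 3L))
  b <- nb[nb$cell == "c002", ]
  expect_identical(nrow(b), 2L)
  expect_identical(b$site_i, c(2L, 3L))
  expect_identical(nrow(nb[nb$cell == "c003", ]), 0L)
})

test_that("perfect haplotype-1 sampling gives zero scores", {
  withr::with_seed(6, {
    pos <- sort(sample.int(5000, 8))
    c1 <- matrix(rbinom(8 * 10, 1, 0.7), 8, 10)
    c2 <- matrix(0L, 8, 10)
    x <- tbl_counts(c1, c2, pos)
    prof <- ld_profile(x$counts, x$sites)$profile
    expect_true(all(prof$score2[prof$n2 > 0] == 0))
    expect_true(all(prof$score3[prof$n3 > 0] == 0))
    expect_true(all(is.na(prof$score2[prof$n2 == 0])))
  })
})

test_that("independent balanced sampling at two far loci scores 0.5", {
  # 4000 cells, alternating allele combinations exactly evenly
  combos <- expand.grid(a = 0:1, b = 0:1)[rep(1:4, 1000), ]
  c1 <- rbind(combos$a, combos$b)
  c2 <- rbind(1 - combos$a, 1 - combos$b)
  x <- tbl_counts(c1, c2, c(1000L, 900000L))
  prof <- ld_profile(x$counts, x$sites)$profile
  expect_equal(prof$score2[13], 0.5)
  expect_identical(prof$n2[13], 4000L)
})

test_that("ld_profile equals exhaustive enumeration on random matrices", {
  withr::with_seed(99, {
    for (i in 1:100) {
      m <- random_count_matrix(sample(2:4, 1), sample(3:5, 1))
      x <- count_matrix_to_tibbles(m)
      prof <- ld_profile(x$counts, x$sites)$profile
      oracle <- oracle_ld_profile(m$c1, m$c2, m$pos, ld_bins())
      expect_identical(prof$n2, oracle$n2)
      expect_identical(prof$n3, oracle$n3)
      expect_equal(prof$score2, oracle$score2, tolerance = 1e-12)
      expect_equal(prof$score3, oracle$score3, tolerance = 1e-12)
    }
  })
})

# ideal somatic construction: fraction f of cells carry the alternative
# allele on haplotype 1; every informative cell shows one allele at the de
# novo site and one at a germline neighbour 50 bp away, split evenly
# between fragments of the two haplotypes.
ideal_somatic_fixture <- function(f, n_cells = 500) {
  n_car <- round(f * n_cells)
  n_non <- n_cells - n_car
  cells <- sprintf("cell%04d", seq_len(n_cells))
  # germline matrix: two het sites phased A1|A2 at pos 1000 and 1050 used
  # to estimate a clean profile, plus the neighbour used for phasing
  half <- function(n) rep(c(TRUE, FALSE), length.out = n)
  g_counts <- dplyr::bind_rows(
    tibble::tibble(site = 1L, cell = cells, c1 = as.integer(half(n_cells)),
                   c2 = as.integer(!half(n_cells))),
    tibble::tibble(site = 2L, cell = cells, c1 = as.integer(half(n_cells)),
                   c2 = as.integer(!half(n_cells))))
  g_sites <- tibble::tibble(site = 1:2, pos = c(1000L, 1050L))
  # de novo site at 1100: carriers' fragments cosegregate with the
  # germline haplotype; non-carriers are hom-ref on both haplotypes
  carrier <- c(rep(TRUE, n_car), rep(FALSE, n_non))
  frag_h1 <- half(n_cells) # which haplotype the cell's fragment comes from
  # allele labels at s: A1 = ref, A2 = alt (alt sits on haplotype 1)
  cs2 <- as.integer(carrier & frag_h1)        # alt read from hap1
  cs1 <- as.integer(!(carrier & frag_h1))     # ref read otherwise
  d_counts <- tibble::tibble(site = 99L, cell = cells, c1 = cs1, c2 = cs2)
  # neighbour (site 2) support matches the same fragment haplotype
  g_counts$c1[g_counts$site == 2L] <- as.integer(frag_h1)
  g_counts$c2[g_counts$site == 2L] <- as.integer(!frag_h1)
  list(g_counts = g_counts, g_sites = g_sites,
       d_sites = tibble::tibble(site = 99L, pos = 1100L),
       d_counts = d_counts)
}

# direct evaluation of the per-cell phasing terms for the fixture
oracle_ideal_ps <- function(f, n_cells = 500) {
  fx <- ideal_somatic_fixture(f, n_cells)
  prof <- ld_profile(fx$g_counts, fx$g_sites)
  p2 <- prof$profile$score2[1]
  d <- fx$d_counts
  g <- fx$g_counts[fx$g_counts$site == 2L, ]
  t12 <- t21 <- numeric(0)
  for (i in seq_len(nrow(d))) {
    gi <- g[g$cell == d$cell[i], ]
    con12 <- (d$c1[i] * gi$c1 > 0) || (d$c2[i] * gi$c2 > 0)
    con21 <- (d$c1[i] * gi$c2 > 0) || (d$c2[i] * gi$c1 > 0)
    if (con12 && con21) next
    t12 <- c(t12, if (con12) 1 - p2 else p2)
    t21 <- c(t21, if (con21) 1 - p2 else p2)
  }
  min(mean(t12), mean(t21))
}

test_that("an ideal somatic SNV at carrier fraction 0.3 scores near 0.3", {
  fx <- ideal_somatic_fixture(0.3)
  prof <- ld_profile(fx$g_counts, fx$g_sites)
  expect_equal(prof$profile$score2[1], 0) # clean profile at short range
  call <- phase_denovo(fx$d_sites, fx$d_counts, fx$g_counts, fx$g_sites,
                       prof, cap2 = 100, cap3 = 10000)
  expect_lte(abs(call$p_s - 0.3), 0.05)
  # and agrees exactly with direct evaluation of the per-cell terms
  expect_equal(call$p_s, oracle_ideal_ps(0.3), tolerance = 1e-12)
})

test_that("germline-like de novo SNVs score near zero", {
  fx <- ideal_somatic_fixture(1) # carried by every cell: true het
  prof <- ld_profile(fx$g_counts, fx$g_sites)
  call <- phase_denovo(fx$d_sites, fx$d_counts, fx$g_counts, fx$g_sites,
                       prof, cap2 = 100, cap3 = 10000)
  expect_lt(call$p_s, 0.01)
  expect_identical(classify_somatic(call)$class, "germline_like")
})

test_that("phasing is symmetric under allele label swap and branch exchange", {
  withr::with_seed(12, {
    for (f in c(0.2, 0.45, 0.8)) {
      fx <- ideal_somatic_fixture(f, n_cells = 101) # odd: no exact ties
      # jitter counts so orientations are not degenerate
      fx$d_counts$c1[3] <- fx$d_counts$c1[3] + 1L
      prof <- ld_profile(fx$g_counts, fx$g_sites)
      base <- phase_denovo(fx$d_sites, fx$d_counts, fx$g_counts,
                           fx$g_sites, prof, cap2 = 100, cap3 = 10000)
      swapped_counts <- dplyr::mutate(fx$d_counts, tmp = c1, c1 = c2,
                                      c2 = tmp)[, c("site", "cell", "c1", "c2")]
      sw <- phase_denovo(fx$d_sites, swapped_counts, fx$g_counts,
                         fx$g_sites, prof, cap2 = 100, cap3 = 10000)
      expect_identical(base$p_s, sw$p_s)
      expect_equal(base$p_a1_a2, sw$p_a2_a1, tolerance = 1e-12)
      br <- phase_denovo(fx$d_sites, fx$d_counts, fx$g_counts, fx$g_sites,
                         prof, cap2 = 100, cap3 = 10000,
                         swap_branches = TRUE)
      expect_identical(base$p_s, br$p_s) # bitwise
      if (base$orientation != "A1|A2" || br$orientation != "A1|A2") {
        expect_false(base$orientation == br$orientation)
      }
      expect_equal(base$p_a1_a2 + base$p_a2_a1, 1, tolerance = 1e-9)
      expect_gte(base$p_s, 0)
      expect_lte(base$p_s, 0.5)
    }
  })
})

test_that("zero informative cells yield an unknown call", {
  fx <- ideal_somatic_fixture(0.3, n_cells = 20)
  prof <- ld_profile(fx$g_counts, fx$g_sites)
  empty_counts <- fx$d_counts[0, ]
  call <- phase_denovo(fx$d_sites, empty_counts, fx$g_counts, fx$g_sites,
                       prof, cap2 = 100, cap3 = 10000)
  expect_identical(call$n_informative, 0L)
  expect_identical(classify_somatic(call)$class, "unknown")
})

test_that("somatic classification uses a strict 0.25 threshold", {
  calls <- tibble::tibble(site = 1:3, pos = 1:3,
                          p_a1_a2 = 0.5, p_a2_a1 = 0.5,
                          orientation = "A1|A2",
                          p_s = c(0.30, 0.10, 0.25),
                          n_informative = 10L)
  cls <- classify_somatic(calls)$class
  expect_identical(cls, c("putative_somatic", "germline_like",
                          "germline_like"))
})

test_that("per-cluster genotyping pools counts through the GL model", {
  counts <- tibble::tibble(
    site = c(1L, 1L, 1L, 2L, 2L, 3L),
    cell = c("a", "b", "c", "a", "b", "c"),
    n_ref = c(0L, 0L, 0L, 5L, 5L, 0L),
    n_alt = c(2L, 1L, 3L, 5L, 5L, 0L))
  clusters <- tibble::tibble(cell = c("a", "b", "c"),
                             cluster = c("k1", "k1", "k2"))
  g <- cluster_genotype(counts, clusters, error_rate = 0.001)
  pick <- function(s, k) g$genotype[g$site == s & g$cluster == k]
  expect_identical(pick(1L, "k1"), 2L)  # only alt reads
  expect_identical(pick(2L, "k1"), 1L)  # 10 ref / 10 alt
  expect_true(is.na(pick(3L, "k2")))    # no reads
  # oracle: direct GL argmax for the mixed cluster
  ll <- cellsnv:::gl_from_counts(10, 10, 0.001)
  expect_identical(which.max(ll) - 1L, 1L)
  expect_error(cluster_genotype(counts, clusters[1:2, ]), "cover")
})
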