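test_that("simulation is bit-identical under a fixed seed", {
  p1 <- simulate_panel(n_hap = 12, n_sites = 80, span_bp = 5e4, seed = 11)
  p2 <- simulate_panel(n_hap = 12, n_sites = 80, span_bp = 5e4, seed = 11)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_identical(p1$sites, p2$sites)

  s1 <- simulate_sample(p1, expected_breakpoints = 3, seed = 5)
  s2 <- simulate_sample(p1, expected_breakpoints = 3, seed = 5)
  expect_identical(s1$hap1, s2$hap1)
  expect_identical(s1$breakpoints, s2$breakpoints)

  cl <- clone_population(40, c(0.5, 0.5))
  d1 <- simulate_cells(s1, cl, mean_depth = 1, seed = 9)
  d2 <- simulate_cells(s1, cl, mean_depth = 1, seed = 9)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$sites, d2$sites)
})

test_that("panel respects MAF floor, ordering and bi-allelic sites", {
  p <- simulate_panel(n_hap = 30, n_sites = 120, span_bp = 1e5,
                      maf_min = 0.05, seed = 2)
  expect_true(all(diff(p$sites$pos) > 0))
  expect_true(all(p$sites$ref != p$sites$alt))
  maf <- pmin(colMeans(p$haplotypes), 1 - colMeans(p$haplotypes))
  expect_true(all(maf >= 0.05))
  expect_error(simulate_panel(n_hap = 2, n_sites = 10, span_bp = 100))
  expect_error(simulate_panel(n_hap = 8, n_sites = 1, span_bp = 100))
})

test_that("panel LD decays with physical distance (direct r^2 oracle)", {
  p <- simulate_panel(n_hap = 40, n_sites = 500, span_bp = 1e6, seed = 3)
  H <- p$haplotypes
  pos <- p$sites$pos
  r2 <- function(i, j) suppressWarnings(cor(H[, i], H[, j])^2)
  near <- far <- c()
  for (i in seq_len(ncol(H) - 1)) {
    for (j in (i + 1):min(i + 12, ncol(H))) {
      d <- pos[j] - pos[i]
      if (d < 1000) near <- c(near, r2(i, j))
      if (d > 1e5) far <- c(far, r2(i, j))
    }
  }
  # supplement far pairs from distant columns
  set.seed(1)
  for (k in 1:400) {
    ij <- sort(sample(ncol(H), 2))
    if (pos[ij[2]] - pos[ij[1]] > 1e5) far <- c(far, r2(ij[1], ij[2]))
  }
  expect_gt(mean(near, na.rm = TRUE), mean(far, na.rm = TRUE))
})

test_that("no-recombination samples copy single panel haplotypes", {
  p <- simulate_panel(n_hap = 10, n_sites = 60, span_bp = 2e4, seed = 4)
  s <- simulate_sample(p, expected_breakpoints = 0, seed = 1)
  match1 <- apply(p$haplotypes, 1, function(h) all(h == s$hap1))
  match2 <- apply(p$haplotypes, 1, function(h) all(h == s$hap2))
  expect_true(any(match1))
  expect_true(any(match2))
  expect_identical(s$genotype, s$hap1 + s$hap2)
})

test_that("breakpoint counts match the Poisson switching process", {
  p <- simulate_panel(n_hap = 10, n_sites = 150, span_bp = 2e5, seed = 6)
  pos <- p$sites$pos
  lambda <- 5 / (max(pos) - min(pos))
  # closed-form expectation/variance of the stated per-gap Bernoulli draws
  p_sw <- 1 - exp(-lambda * diff(pos))
  mu <- sum(p_sw)
  v <- sum(p_sw * (1 - p_sw))
  n_rep <- 1000
  counts <- withr::with_seed(42, vapply(seq_len(n_rep), function(i) {
    length(simulate_sample(p, expected_breakpoints = 5)$breakpoints$hap1)
  }, numeric(1)))
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(v / n_rep))
})

test_that("empirical mean per-cell-site depth matches mean_depth", {
  p <- simulate_panel(n_hap = 8, n_sites = 100, span_bp = 5e4, seed = 8)
  s <- simulate_sample(p, expected_breakpoints = 0, seed = 1)
  cl <- clone_population(1000, 1)
  sim <- simulate_cells(s, cl, mean_depth = 2, dropout = 0,
                        error_rate = 0, zero_inflation = 0.3, seed = 3)
  mean_depth <- sum(sim$counts$n_ref + sim$counts$n_alt) / (100 * 1000)
  expect_lt(abs(mean_depth - 2) / 2, 0.05)
})

test_that("noise-free data are consistent with the truth tables", {
  p <- simulate_panel(n_hap = 8, n_sites = 60, span_bp = 3e4, seed = 12)
  s <- simulate_sample(p, expected_breakpoints = 0, seed = 2)
  cl <- clone_population(30, c(0.4, 0.6))
  hom <- which(s$genotype == 0)
  som <- tibble::tibble(site = hom[1], clone = 1L, haplotype = 1L)
  sim <- simulate_cells(s, cl, som, mean_depth = 50, dropout = 0,
                        error_rate = 0, zero_inflation = 0, seed = 5)
  joined <- dplyr::inner_join(sim$counts, sim$sites, by = "site")
  # hom-ref, non-somatic sites show only reference support in every cell
  hom_rows <- dplyr::filter(joined, genotype == 0, !somatic)
  expect_true(all(hom_rows$n_alt == 0))
  # hom-alt sites show only alternative support
  alt_rows <- dplyr::filter(joined, genotype == 2)
  expect_true(all(alt_rows$n_ref == 0))
  # carrier flags equal clone membership for the somatic site
  carriers <- sim$truth$carriers
  members <- sim$cells$cell[sim$cells$clone == 1L]
  expect_setequal(carriers$cell, members)
  # non-carrier cells carry no alt reads at the somatic site
  som_rows <- dplyr::filter(joined, somatic)
  expect_true(all(som_rows$n_alt[!(som_rows$cell %in% members)] == 0))
  expect_true(any(som_rows$n_alt[som_rows$cell %in% members] > 0))
})

test_that("somatic placement on a het germline site errors", {
  p <- simulate_panel(n_hap = 8, n_sites = 60, span_bp = 3e4, seed = 12)
  s <- simulate_sample(p, expected_breakpoints = 0, seed = 2)
  cl <- clone_population(10, 1)
  het <- which(s$genotype == 1)[1]
  expect_error(
    simulate_cells(s, cl, tibble::tibble(site = het, clone = 1L,
                                         haplotype = 1L), seed = 1),
    "homozygous-reference")
})

test_that("pooled BAF at het sites approaches 0.5 at high pooled depth", {
  p <- simulate_panel(n_hap = 8, n_sites = 40, span_bp = 2e4, seed = 9)
  s <- simulate_sample(p, expected_breakpoints = 0, seed = 3)
  cl <- clone_population(500, 1)
  sim <- simulate_cells(s, cl, mean_depth = 5, dropout = 0, error_rate = 0,
                        zero_inflation = 0, seed = 4)
  pooled <- sim$counts %>%
    dplyr::group_by(site) %>%
    dplyr::summarise(dp = sum(n_ref + n_alt), baf = sum(n_alt) / dp)
  het <- dplyr::filter(dplyr::inner_join(pooled, sim$sites, by = "site"),
                       genotype == 1, dp >= 2000)
  expect_gt(nrow(het), 0)
  expect_true(all(abs(het$baf - 0.5) < 0.05))
})

test_that("fragments phase nearby loci and decorrelate distant ones", {
  p <- simulate_panel(n_hap = 16, n_sites = 250, span_bp = 2e4,
                      recomb_intensity = 1e-4, seed = 21)
  s <- simulate_sample(p, expected_breakpoints = 0, seed = 6)
  cl <- clone_population(5000, 1)
  read_len <- 400
  eps <- 0.002
  sim <- simulate_cells(s, cl, mean_depth = 0.015, dropout = 0,
                        error_rate = eps, read_len = read_len,
                        zero_inflation = 0, seed = 7)
  het <- sim$sites$site[sim$sites$genotype == 1]
  # single-allele observations at het sites, labelled by supported haplotype
  obs <- sim$counts %>%
    dplyr::filter(site %in% het, xor(n_ref > 0, n_alt > 0)) %>%
    dplyr::inner_join(sim$sites[, c("site", "pos", "hap1")], by = "site") %>%
    dplyr::mutate(on_h1 = ifelse(n_alt > 0, hap1 == 1L, hap1 == 0L))
  pairs <- dplyr::inner_join(obs, obs, by = "cell",
                             relationship = "many-to-many") %>%
    dplyr::filter(site.x < site.y) %>%
    dplyr::mutate(d = abs(pos.y - pos.x),
                  discordant = on_h1.x != on_h1.y)
  near <- dplyr::filter(pairs, d < read_len)
  far <- dplyr::filter(pairs, d > 5 * read_len)
  expect_gt(nrow(near), 200)
  expect_gt(nrow(far), 200)
  expect_lt(mean(near$discordant), 2 * eps + 0.01)
  expect_gt(mean(far$discordant), 0.42)
  expect_lt(mean(far$discordant), 0.58)
})
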