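# Self-contained validation experiments on synthetic data: somatic-score
# recovery across clone fractions, the germline-refinement accuracy gain,
# and the two-locus cosegregation distance decay. Used by the test suite
# and the acceptance script.

#' Somatic LD-score recovery experiment
#'
#' Simulates a clonal cell population in which a set of somatic SNVs is
#' carried, on one haplotype, by the cells of a clone of fraction `f`, runs
#' the cell-population LD refinement (profile estimation, de novo phasing,
#' classification), and scores held-out germline heterozygous SNVs through
#' the same machinery as a null. Sites are placed densely (tens of bp
#' apart) so that most cells have a phase-informative germline neighbour
#' within the distance caps.
#'
#' @param f Somatic clone cell fraction.
#' @param n_cells,mean_depth,error_rate,dropout,read_len,zero_inflation
#'   Generator settings (see [simulate_cells()]).
#' @param n_sites,span_bp Panel density.
#' @param n_somatic,n_germline_test Numbers of somatic SNVs and of held-out
#'   germline het SNVs scored as the null.
#' @param cap2,cap3 Distance caps for the two-/three-locus models.
#' @param ps_threshold Somatic classification threshold.
#' @param seed Integer seed.
#' @return List with `somatic` and `germline` call tibbles (phased and
#'   classified) and the estimated `profile`.
#' @export
somatic_recovery_experiment <- function(f, n_cells = 500, mean_depth = 5,
                                        error_rate = 0.001, dropout = 0.1,
                                        read_len = 1000,
                                        zero_inflation = 0.3,
                                        n_sites = 600, span_bp = 2e4,
                                        n_somatic = 8,
                                        n_germline_test = 12,
                                        cap2 = 250, cap3 = 250,
                                        ps_threshold = 0.25, seed = 1) {
  panel <- simulate_panel(n_hap = 40, n_sites = n_sites, span_bp = span_bp,
                          recomb_intensity = 1e-4, seed = seed)
  smp <- simulate_sample(panel, expected_breakpoints = 1, seed = seed + 1L)
  clones <- clone_population(n_cells, c(f, 1 - f))
  hom <- which(smp$genotype == 0L)
  som_idx <- hom[round(seq(0.1, 0.9, length.out = n_somatic) * length(hom))]
  som <- tibble(site = som_idx, clone = 1L, haplotype = 1L)
  sim <- simulate_cells(smp, clones, som, mean_depth = mean_depth,
                        dropout = dropout, error_rate = error_rate,
                        read_len = read_len,
                        zero_inflation = zero_inflation, seed = seed + 2L)

  germ <- sim$sites %>%
    filter(.data$genotype == 1L, !.data$somatic) %>%
    mutate(hap1_is_alt = .data$hap1 == 1L)
  am <- build_allele_matrix(sim$counts, germ,
                            sim$sites %>% filter(.data$somatic))
  profile <- ld_profile(am$counts, am$sites)
  som_calls <- phase_denovo(am$denovo_sites, am$denovo_counts, am$counts,
                            am$sites, profile, cap2 = cap2, cap3 = cap3) %>%
    classify_somatic(ps_threshold)

  g_idx <- round(seq(0.08, 0.92, length.out = n_germline_test) * nrow(germ))
  g_test <- germ[pmax(1, g_idx), ] %>% distinct(.data$site, .keep_all = TRUE)
  g_rest <- germ %>% anti_join(g_test, by = "site")
  am_g <- build_allele_matrix(sim$counts, g_rest, g_test)
  profile_g <- ld_profile(am_g$counts, am_g$sites)
  germ_calls <- phase_denovo(am_g$denovo_sites, am_g$denovo_counts,
                             am_g$counts, am_g$sites, profile_g,
                             cap2 = cap2, cap3 = cap3) %>%
    classify_somatic(ps_threshold)

  list(somatic = som_calls, germline = germ_calls, profile = profile,
       f = f)
}

#' Germline refinement accuracy-gain experiment
#'
#' Simulates sparse coverage over a reference panel (a fraction of sites
#' covered at low read depth with sequencing errors), computes genotype
#' likelihoods from the counts, refines them against the panel and compares
#' the genotype accuracy of the data-only argmax (GL) with the
#' panel-refined argmax (GP) over all panel sites.
#'
#' @param n_sites,n_hap,span_bp Panel settings.
#' @param coverage Fraction of sites with any reads.
#' @param max_depth Covered sites receive 1..`max_depth` reads.
#' @param error_rate Per-read allele error probability.
#' @param seed Integer seed.
#' @return List with `acc_gl`, `acc_gp`, `n_sites`.
#' @export
refinement_gain_experiment <- function(n_sites = 600, n_hap = 40,
                                       span_bp = 5e5, coverage = 0.2,
                                       max_depth = 2, error_rate = 0.01,
                                       seed = 1) {
  panel <- simulate_panel(n_hap = n_hap, n_sites = n_sites,
                          span_bp = span_bp, recomb_intensity = 2e-5,
                          seed = seed)
  smp <- simulate_sample(panel, expected_breakpoints = 2, seed = seed + 1L)
  withr::with_seed(seed + 2L, {
    covered <- which(runif(n_sites) < coverage)
    gl <- panel$sites %>% mutate(gl0 = 0, gl1 = 0, gl2 = 0)
    for (i in covered) {
      dp <- sample.int(max_depth, 1L)
      alleles <- as.integer(runif(dp) < smp$genotype[i] / 2)
      flip <- runif(dp) < error_rate
      alleles <- ifelse(flip, 1L - alleles, alleles)
      ll <- gl_from_counts(sum(alleles == 0L), sum(alleles == 1L),
                           error_rate = error_rate)
      gl$gl0[i] <- ll[1]
      gl$gl1[i] <- ll[2]
      gl$gl2[i] <- ll[3]
    }
    refined <- refine_genotypes(gl, panel)
    list(acc_gl = mean(refined$gt_gl == smp$genotype),
         acc_gp = mean(refined$gt_gp == smp$genotype),
         n_sites = n_sites)
  })
}

#' Two-locus cosegregation distance-decay experiment
#'
#' Estimates the two-locus LD refinement profile from simulated germline
#' heterozygous SNVs and summarises its short-range (below the fragment
#' length) and long-range (far beyond it) scores: near zero within
#' fragments, approaching 0.5 where allele draws are independent.
#'
#' @param n_cells,mean_depth,error_rate,read_len Generator settings.
#' @param n_sites,span_bp Site density and span.
#' @param seed Integer seed.
#' @return List with `short_range`, `long_range` scores and the `profile`.
#' @export
ld_decay_experiment <- function(n_cells = 800, mean_depth = 0.25,
                                error_rate = 0.001, read_len = 500,
                                n_sites = 600, span_bp = 4e4, seed = 1) {
  panel <- simulate_panel(n_hap = 30, n_sites = n_sites, span_bp = span_bp,
                          recomb_intensity = 5e-5, seed = seed)
  smp <- simulate_sample(panel, expected_breakpoints = 1, seed = seed + 1L)
  clones <- clone_population(n_cells, 1)
  sim <- simulate_cells(smp, clones, mean_depth = mean_depth,
                        dropout = 0.05, error_rate = error_rate,
                        read_len = read_len, zero_inflation = 0.2,
                        seed = seed + 2L)
  germ <- sim$sites %>%
    filter(.data$genotype == 1L) %>%
    mutate(hap1_is_alt = .data$hap1 == 1L)
  am <- build_allele_matrix(sim$counts, germ)
  profile <- ld_profile(am$counts, am$sites)
  prof <- profile$profile
  short_bins <- prof$hi <= read_len & prof$n2 > 0
  long_bins <- prof$lo >= 10 * read_len & prof$n2 > 0
  list(
    short_range = sum(prof$score2[short_bins] * prof$n2[short_bins]) /
      sum(prof$n2[short_bins]),
    long_range = sum(prof$score2[long_bins] * prof$n2[long_bins]) /
      sum(prof$n2[long_bins]),
    profile = profile
  )
}
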