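# Cell-population LD refinement: two- and three-locus cosegregation
# profiles over distance bins estimated from phased germline heterozygous
# SNVs, then used to phase de novo SNVs and score how often their alleles
# fail to cosegregate with neighbouring germline alleles across cells.
#
# The cell-level matrix stores, per site i and cell j, the read counts c1,
# c2 supporting the two phased alleles A1|A2 (germline; A1 = the haplotype-1
# allele) or the unphased pair A1/A2 (de novo). Within a cell, two covered
# loci are two-locus neighbours when no germline site between them is
# covered; they cosegregate when the same-haplotype allele is seen at both
# (c1*c1 > 0 or c2*c2 > 0). Three-locus neighbourhoods chain two adjacent
# pairs whose flanks show the same haplotype allele; they cosegregate when
# the middle site shows that allele too. Flanks agreeing on haplotype 1 and,
# mirrored, on haplotype 2 are pooled (phase symmetry).

# Two-locus neighbourhoods: one row per (cell, adjacent covered pair).
neighborhoods_two <- function(counts, sites) {
  counts %>%
    filter(.data$c1 + .data$c2 > 0) %>%
    inner_join(sites %>% select("site", "pos"), by = "site") %>%
    arrange(.data$cell, .data$pos) %>%
    group_by(.data$cell) %>%
    mutate(site_i = lead(.data$site), pos_i = lead(.data$pos),
           c1_i = lead(.data$c1), c2_i = lead(.data$c2)) %>%
    ungroup() %>%
    filter(!is.na(.data$site_i)) %>%
    mutate(d = .data$pos_i - .data$pos,
           coseg = (.data$c1 * .data$c1_i > 0) |
             (.data$c2 * .data$c2_i > 0)) %>%
    select(cell = "cell", site_k = "site", site_i = "site_i",
           pos_k = "pos", pos_i = "pos_i",
           c1_k = "c1", c2_k = "c2", c1_i = "c1_i", c2_i = "c2_i",
           d = "d", coseg = "coseg")
}

# Three-locus neighbourhoods with haplotype symmetrization: one row per
# (cell, adjacent covered triple, flank haplotype).
neighborhoods_three <- function(counts, sites) {
  cov <- counts %>%
    filter(.data$c1 + .data$c2 > 0) %>%
    inner_join(sites %>% select("site", "pos"), by = "site") %>%
    arrange(.data$cell, .data$pos) %>%
    group_by(.data$cell) %>%
    mutate(pos_i = lead(.data$pos), c1_i = lead(.data$c1),
           c2_i = lead(.data$c2),
           pos_l = lead(.data$pos, 2), c1_l = lead(.data$c1, 2),
           c2_l = lead(.data$c2, 2)) %>%
    ungroup() %>%
    filter(!is.na(.data$pos_l))
  h1 <- cov %>%
    filter(.data$c1 * .data$c1_l > 0) %>%
    mutate(hap = 1L, coseg = .data$c1_i > 0)
  h2 <- cov %>%
    filter(.data$c2 * .data$c2_l > 0) %>%
    mutate(hap = 2L, coseg = .data$c2_i > 0)
  bind_rows(h1, h2) %>%
    mutate(d = .data$pos_i - .data$pos) %>%
    select("cell", pos_k = "pos", "pos_i", "pos_l", "hap", "d", "coseg")
}

#' Distance-binned two- and three-locus LD refinement profile
#'
#' Estimates, from phased germline heterozygous SNVs, the fraction of
#' same-cell neighbourhoods whose alleles do NOT cosegregate, grouped into
#' physical-distance bins. Scores near 0 indicate alleles in near-perfect
#' LD in the cell population (the expectation for germline variation);
#' scores near 0.5 indicate independent allele sampling (distant loci on
#' different fragments). Two-locus distance is between the paired loci;
#' three-locus distance is from the upstream flank to the middle locus.
#'
#' @param counts Cell-level allele counts: tibble with `site`, `cell`, `c1`,
#'   `c2` (reads supporting the haplotype-1 / haplotype-2 allele). Rows must
#'   refer to phased germline het sites only.
#' @param sites Site table with `site` and `pos` (bp), position sorted.
#' @param bins Distance bin edges (default [ld_bins()], 13 bins).
#' @return An `ld_profile`: tibble with per-bin `score2`, `n2`, `score3`,
#'   `n3` (`NA` scores flag empty bins).
#' @export
ld_profile <- function(counts, sites, bins = ld_bins()) {
  counts <- as_tibble(counts)
  sites <- as_tibble(sites)
  stopifnot(all(c("site", "cell", "c1", "c2") %in% names(counts)),
            all(c("site", "pos") %in% names(sites)))
  n_bins <- length(bins) - 1L
  base <- tibble(bin = seq_len(n_bins),
                 lo = bins[-length(bins)], hi = bins[-1])

  n2 <- neighborhoods_two(counts, sites) %>%
    mutate(bin = bin_index(.data$d, bins)) %>%
    group_by(.data$bin) %>%
    summarise(score2 = 1 - mean(.data$coseg), n2 = dplyr::n(),
              .groups = "drop")
  n3 <- neighborhoods_three(counts, sites) %>%
    mutate(bin = bin_index(.data$d, bins)) %>%
    group_by(.data$bin) %>%
    summarise(score3 = 1 - mean(.data$coseg), n3 = dplyr::n(),
              .groups = "drop")

  profile <- base %>%
    left_join(n2, by = "bin") %>%
    left_join(n3, by = "bin") %>%
    mutate(n2 = ifelse(is.na(.data$n2), 0L, .data$n2),
           n3 = ifelse(is.na(.data$n3), 0L, .data$n3))
  structure(list(profile = profile, bins = bins), class = "ld_profile")
}

#' @export
print.ld_profile <- function(x, ...) {
  cat(sprintf("<ld_profile> %d bins; %d two-locus, %d three-locus neighbourhoods\n",
              nrow(x$profile), sum(x$profile$n2), sum(x$profile$n3)))
  print(x$profile, n = nrow(x$profile))
  invisible(x)
}

#' @export
tidy.ld_profile <- function(x, ...) x$profile

#' @export
glance.ld_profile <- function(x, ...) {
  tibble(n_two_locus = sum(x$profile$n2),
         n_three_locus = sum(x$profile$n3),
         n_bins_defined2 = sum(!is.na(x$profile$score2)),
         n_bins_defined3 = sum(!is.na(x$profile$score3)))
}

# Bin-score lookup with fallback: when the bin holding `d` is empty, fall
# back to the nearest non-empty wider bin, then to narrower ones.
lookup_profile_score <- function(profile, d, which = 2L) {
  scores <- if (which == 2L) profile$profile$score2 else profile$profile$score3
  b <- bin_index(d, profile$bins)
  n <- length(scores)
  for (k in c(b:n, rev(seq_len(b - 1L)))) {
    if (!is.na(scores[k])) return(scores[k])
  }
  NA_real_
}

#' Phase de novo SNVs against germline neighbourhoods
#'
#' For each de novo SNV s with unphased alleles A1/A2, evaluates in every
#' cell with evidence at s the probability that A1 lies on haplotype 1,
#' using the two-locus model (nearest covered germline neighbour, used when
#' its distance is at most `cap2`) and the three-locus model (nearest
#' covered flanks agreeing on one haplotype, used when the upstream
#' flank-to-site distance is at most `cap3`). A cell's term equals
#' `1 - p(bin)` when its observation is cosegregation-consistent with the
#' hypothesized orientation and `p(bin)` otherwise, where `p(bin)` is the
#' profile score at the realized distance; the two models are averaged when
#' both apply. Population-level `p(A1|A2)` is the mean over informative
#' cells, `p(A2|A1) = 1 - p(A1|A2)`, the reported orientation is the argmax,
#' and the LD refinement score is `p_s = min` of the two (in `[0, 0.5]`;
#' near 0 for germline variants, larger when the allele cosegregates in
#' only a subpopulation of cells).
#'
#' @param denovo De novo site table: `site`, `pos`.
#' @param denovo_counts Tibble `site`, `cell`, `c1`, `c2` of reads
#'   supporting the de novo alleles A1 / A2 per cell.
#' @param counts,sites Phased germline cell-level counts and site table, as
#'   for [ld_profile()].
#' @param profile An `ld_profile` estimated from the germline counts.
#' @param cap2,cap3 Distance caps (bp) for the two- and three-locus models
#'   (defaults 100 bp and 10 kb, DNA-like; 1 kb / 50 kb suit RNA-like data).
#' @param swap_branches Exchange the two branch assignments of the per-cell
#'   terms (orientation labels flip; `p_s` is invariant). Exposed for
#'   symmetry checking.
#' @return Tibble with one row per de novo site: `p_a1_a2`, `p_a2_a1`,
#'   `orientation`, `p_s`, `n_informative`.
#' @export
phase_denovo <- function(denovo, denovo_counts, counts, sites, profile,
                         cap2 = 100, cap3 = 10000, swap_branches = FALSE) {
  denovo <- as_tibble(denovo)
  denovo_counts <- as_tibble(denovo_counts) %>%
    filter(.data$c1 + .data$c2 > 0)
  stopifnot(inherits(profile, "ld_profile"))

  germ_cov <- counts %>%
    filter(.data$c1 + .data$c2 > 0) %>%
    inner_join(sites %>% select("site", "pos"), by = "site") %>%
    arrange(.data$cell, .data$pos)
  germ_by_cell <- split(germ_cov[, c("pos", "c1", "c2")], germ_cov$cell)

  # Per-cell terms for BOTH orientations, each evaluated through its own
  # (mirrored) branch condition. Computing the two orientations
  # independently, rather than as 1 - the other, makes the final score
  # min{p(A1|A2), p(A2|A1)} exactly invariant under branch exchange.
  score_one_cell <- function(pos_s, cs1, cs2, g) {
    pg <- g$pos
    n <- length(pg)
    idx <- findInterval(pos_s, pg)
    up <- if (idx >= 1L) idx else NA_integer_
    dn <- if (idx < n) idx + 1L else NA_integer_
    t12 <- numeric(0)
    t21 <- numeric(0)

    # two-locus: nearest covered germline neighbour (ties: upstream)
    near <- NA_integer_
    if (!is.na(up) && !is.na(dn)) {
      near <- if ((pos_s - pg[up]) <= (pg[dn] - pos_s)) up else dn
    } else if (!is.na(up)) near <- up else if (!is.na(dn)) near <- dn
    if (!is.na(near)) {
      d2 <- abs(pos_s - pg[near])
      if (d2 <= cap2) {
        p2 <- lookup_profile_score(profile, d2, 2L)
        if (!is.na(p2)) {
          con12 <- (cs1 * g$c1[near] > 0) || (cs2 * g$c2[near] > 0)
          con21 <- (cs1 * g$c2[near] > 0) || (cs2 * g$c1[near] > 0)
          # when both alleles are seen at either locus both orientations'
          # conditions hold and the observation carries no phase
          # information; such terms are dropped rather than averaged in
          if (!(con12 && con21)) {
            t12 <- c(t12, if (con12) 1 - p2 else p2)
            t21 <- c(t21, if (con21) 1 - p2 else p2)
          }
        }
      }
    }

    # three-locus: nearest covered flanks on both sides
    if (!is.na(up) && !is.na(dn)) {
      d3 <- pos_s - pg[up]
      if (d3 <= cap3) {
        p3 <- lookup_profile_score(profile, d3, 3L)
        if (!is.na(p3)) {
          # informative only when the site shows one allele and the flanks
          # agree on exactly one haplotype (otherwise the two mirrored
          # flank conditions cancel)
          f1 <- g$c1[up] * g$c1[dn] > 0
          f2 <- g$c2[up] * g$c2[dn] > 0
          if (xor(f1, f2) && xor(cs1 > 0, cs2 > 0)) {
            s_on_1 <- cs1 > 0
            coseg12 <- if (f1) s_on_1 else !s_on_1
            t12 <- c(t12, if (coseg12) 1 - p3 else p3)
            t21 <- c(t21, if (!coseg12) 1 - p3 else p3)
          }
        }
      }
    }

    if (length(t12) == 0L) c(NA_real_, NA_real_)
    else c(mean(t12), mean(t21))
  }

  res <- purrr::map_dfr(seq_len(nrow(denovo)), function(i) {
    s <- denovo$site[i]
    pos_s <- denovo$pos[i]
    dc <- denovo_counts %>% filter(.data$site == s)
    pj <- vapply(seq_len(nrow(dc)), function(j) {
      g <- germ_by_cell[[dc$cell[j]]]
      if (is.null(g) || nrow(g) == 0L) return(c(NA_real_, NA_real_))
      score_one_cell(pos_s, dc$c1[j], dc$c2[j], g)
    }, numeric(2))
    keep <- !is.na(pj[1, ])
    n_inf <- sum(keep)
    if (n_inf == 0L) {
      tibble(site = s, pos = pos_s, p_a1_a2 = NA_real_, p_a2_a1 = NA_real_,
             orientation = NA_character_, p_s = NA_real_, n_informative = 0L)
    } else {
      p12 <- mean(pj[1, keep])
      p21 <- mean(pj[2, keep])
      if (swap_branches) {
        tmp <- p12
        p12 <- p21
        p21 <- tmp
      }
      tibble(site = s, pos = pos_s, p_a1_a2 = p12, p_a2_a1 = p21,
             orientation = if (p12 >= p21) "A1|A2" else "A2|A1",
             p_s = min(p12, p21), n_informative = n_inf)
    }
  })
  res
}

#' Classify phased de novo SNVs as putative somatic or germline-like
#'
#' A de novo SNV is putative somatic when its LD refinement score exceeds
#' `threshold` (strictly; the default 0.25 keeps a score of exactly 0.25
#' germline-like), `unknown` when no cell was informative.
#'
#' @param calls Output of [phase_denovo()].
#' @param threshold Classification threshold on `p_s` (default 0.25).
#' @return `calls` with an added `class` column.
#' @export
classify_somatic <- function(calls, threshold = 0.25) {
  as_tibble(calls) %>%
    mutate(class = case_when(
      is.na(.data$p_s) | .data$n_informative == 0L ~ "unknown",
      .data$p_s > threshold ~ "putative_somatic",
      TRUE ~ "germline_like"
    ))
}

#' Per-cluster genotyping of putative somatic SNVs
#'
#' Pools read counts over the cells of each cluster and genotypes each site
#' from the pooled counts with the bi-allelic likelihood model (argmax over
#' g in {0, 1, 2}; ties toward the smaller g). Clusters with no reads at a
#' site get a missing genotype.
#'
#' @param site_counts Tibble `site`, `cell`, `n_ref`, `n_alt`.
#' @param cell_clusters Tibble `cell`, `cluster` covering all cells.
#' @param error_rate Assumed per-read error rate of the count model.
#' @return Tibble `site`, `cluster`, `n_ref`, `n_alt`, `genotype`.
#' @export
cluster_genotype <- function(site_counts, cell_clusters, error_rate = 0.001) {
  site_counts <- as_tibble(site_counts)
  cell_clusters <- as_tibble(cell_clusters)
  if (!all(unique(site_counts$cell) %in% cell_clusters$cell)) {
    abort("`cell_clusters` must cover every cell present in `site_counts`.")
  }
  pooled <- site_counts %>%
    inner_join(cell_clusters, by = "cell") %>%
    group_by(.data$site, .data$cluster) %>%
    summarise(n_ref = sum(.data$n_ref), n_alt = sum(.data$n_alt),
              .groups = "drop") %>%
    tidyr::complete(.data$site, .data$cluster,
                    fill = list(n_ref = 0L, n_alt = 0L))
  gl <- gl_from_counts(pooled$n_ref, pooled$n_alt, error_rate)
  pooled %>%
    mutate(genotype = ifelse(.data$n_ref + .data$n_alt == 0L, NA_integer_,
                             argmax_genotype(gl)))
}

#' Build the cell-level allele matrix from simulated data and refined calls
#'
#' Maps per-cell ref/alt read counts onto the phased allele convention of
#' the LD models: at phased germline het sites `c1`/`c2` count reads
#' supporting the haplotype-1 / haplotype-2 allele (using the refinement
#' phase `hap1_is_alt`); at de novo sites the unphased labels are A1 = ref,
#' A2 = alt.
#'
#' @param counts Tibble `site`, `cell`, `n_ref`, `n_alt` (e.g.
#'   `sim$counts`).
#' @param germline Tibble of phased germline het sites: `site`, `pos`,
#'   `hap1_is_alt`.
#' @param denovo Optional tibble of de novo sites: `site`, `pos`.
#' @return List with `sites`, `counts` (germline, phased) and
#'   `denovo_sites`, `denovo_counts`.
#' @export
build_allele_matrix <- function(counts, germline, denovo = NULL) {
  counts <- as_tibble(counts)
  germline <- as_tibble(germline)
  g_counts <- counts %>%
    inner_join(germline %>% select("site", "hap1_is_alt"), by = "site") %>%
    mutate(c1 = ifelse(.data$hap1_is_alt, .data$n_alt, .data$n_ref),
           c2 = ifelse(.data$hap1_is_alt, .data$n_ref, .data$n_alt)) %>%
    select("site", "cell", "c1", "c2")
  out <- list(
    sites = germline %>% select("site", "pos") %>% arrange(.data$pos),
    counts = g_counts
  )
  if (!is.null(denovo) && nrow(denovo) > 0) {
    out$denovo_sites <- as_tibble(denovo) %>% select("site", "pos")
    out$denovo_counts <- counts %>%
      semi_join(out$denovo_sites, by = "site") %>%
      mutate(c1 = .data$n_ref, c2 = .data$n_alt) %>%
      select("site", "cell", "c1", "c2")
  } else {
    out$denovo_sites <- tibble(site = integer(), pos = integer())
    out$denovo_counts <- tibble(site = integer(), cell = character(),
                                c1 = integer(), c2 = integer())
  }
  out
}
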