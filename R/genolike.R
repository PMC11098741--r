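# Read filtering, candidate-SNV scanning from pooled pileups, and genotype
# likelihoods under the classical bi-allelic per-read error model.

#' Filter read observations on mismatches and mapping quality
#'
#' Removes reads with more than `max_mismatch` alignment mismatches or
#' mapping quality below `min_mapq`. The mismatch threshold is inclusive
#' (exactly `max_mismatch` mismatches is tolerated). `mismatch_count` counts
#' substituted plus inserted/deleted bases of the alignment.
#'
#' @param reads Tibble of read observations with at least `mismatch_count`
#'   and `mapping_quality` columns.
#' @param max_mismatch Maximum tolerated mismatches (default 4).
#' @param min_mapq Minimum mapping quality (default 20).
#' @return The retained rows of `reads`, as a tibble.
#' @export
filter_reads <- function(reads, max_mismatch = 4, min_mapq = 20) {
  reads <- as_tibble(reads)
  reads %>%
    filter(.data$mismatch_count <= max_mismatch,
           .data$mapping_quality >= min_mapq)
}

#' Scan pooled read evidence for candidate SNVs
#'
#' Emits every site at which an alternative allele is observed in at least
#' one (pre-filtered) read. The alternative allele is the most frequent
#' non-reference base; further non-reference bases are ignored so sites stay
#' bi-allelic. Ties between non-reference bases are broken alphabetically.
#'
#' @param reads Tibble with columns `chrom`, `pos`, `ref`, `base` (observed
#'   base per read); rows are read observations, assumed already filtered.
#' @return Tibble of candidate sites: `chrom`, `pos`, `ref`, `alt`, `depth`
#'   (all retained reads), `alt_count` and `baf` (= alt_count / depth).
#' @export
scan_candidates <- function(reads) {
  reads <- as_tibble(reads)
  depth_tbl <- reads %>%
    group_by(.data$chrom, .data$pos, .data$ref) %>%
    summarise(depth = dplyr::n(), .groups = "drop")
  alt_tbl <- reads %>%
    filter(.data$base != .data$ref) %>%
    dplyr::count(.data$chrom, .data$pos, .data$ref, .data$base,
                 name = "alt_count") %>%
    group_by(.data$chrom, .data$pos, .data$ref) %>%
    arrange(dplyr::desc(.data$alt_count), .data$base, .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    rename(alt = "base")
  alt_tbl %>%
    inner_join(depth_tbl, by = c("chrom", "pos", "ref")) %>%
    mutate(baf = .data$alt_count / .data$depth) %>%
    arrange(.data$chrom, .data$pos) %>%
    select("chrom", "pos", "ref", "alt", "depth", "alt_count", "baf")
}

# Per-read log-likelihood contributions for the bi-allelic model.
# e = 10^(-min(base_quality, mapping_quality)/10);
# P(ref | g=0) = 1-e, P(ref | g=1) = 0.5, P(ref | g=2) = e (complements for
# alt). Reads showing neither ref nor alt are excluded.
gl_from_reads <- function(is_alt, err) {
  p_ref <- cbind(1 - err, 0.5, err)
  p <- p_ref
  p[is_alt, ] <- 1 - p_ref[is_alt, , drop = FALSE]
  colSums(log(p))
}

# Genotype log-likelihoods from ref/alt counts under a constant error rate;
# shared by the per-cluster genotyper and count-only workflows.
gl_from_counts <- function(n_ref, n_alt, error_rate = 0.001) {
  e <- error_rate
  cbind(
    n_ref * log(1 - e) + n_alt * log(e),
    (n_ref + n_alt) * log(0.5),
    n_ref * log(e) + n_alt * log(1 - e)
  )
}

# Normalize log-likelihood triplets to linear-scale probabilities.
gl_normalize <- function(ll) {
  ll <- ll - apply(ll, 1, max)
  p <- exp(ll)
  p / rowSums(p)
}

#' Genotype likelihoods at candidate sites
#'
#' Computes per-site genotype likelihoods GL(g | d) for g in {0, 1, 2}
#' (hom-ref, het, hom-alt) as a product of independent per-read terms. The
#' per-read error probability is `10^(-min(base_quality, mapping_quality)/10)`;
#' a read supports the reference with probability 1-e, e, or 0.5 under g = 0,
#' 2, 1 respectively. Sites with no informative reads get a flat triplet.
#'
#' @param reads Read-observation tibble with `chrom`, `pos`, `ref`, `base`,
#'   `base_quality`, `mapping_quality`.
#' @param sites Candidate sites as returned by [scan_candidates()]. If
#'   `NULL`, candidates are scanned from `reads`.
#' @return `sites` with added log-likelihood columns `gl0`, `gl1`, `gl2` and
#'   normalized linear-scale columns `pl0`, `pl1`, `pl2` (summing to 1).
#' @export
genotype_likelihoods <- function(reads, sites = NULL) {
  reads <- as_tibble(reads)
  if (is.null(sites)) sites <- scan_candidates(reads)
  obs <- reads %>%
    select("chrom", "pos", "ref", "base", "base_quality",
           "mapping_quality") %>%
    inner_join(sites %>% select("chrom", "pos", "ref", "alt"),
               by = c("chrom", "pos", "ref")) %>%
    filter(.data$base == .data$ref | .data$base == .data$alt) %>%
    mutate(err = 10^(-pmin(.data$base_quality, .data$mapping_quality) / 10),
           is_alt = .data$base == .data$alt)
  ll <- obs %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(
      gl0 = sum(log(ifelse(.data$is_alt, .data$err, 1 - .data$err))),
      gl1 = sum(log(rep(0.5, dplyr::n()))),
      gl2 = sum(log(ifelse(.data$is_alt, 1 - .data$err, .data$err))),
      .groups = "drop"
    )
  out <- sites %>%
    left_join(ll, by = c("chrom", "pos")) %>%
    mutate(dplyr::across(c("gl0", "gl1", "gl2"), ~ ifelse(is.na(.x), 0, .x)))
  if (!"depth" %in% names(out)) {
    dp <- obs %>%
      group_by(.data$chrom, .data$pos) %>%
      summarise(depth = dplyr::n(), alt_count = sum(.data$is_alt),
                .groups = "drop")
    out <- out %>%
      left_join(dp, by = c("chrom", "pos")) %>%
      mutate(depth = ifelse(is.na(.data$depth), 0L, .data$depth),
             alt_count = ifelse(is.na(.data$alt_count), 0L,
                                .data$alt_count),
             baf = ifelse(.data$depth > 0, .data$alt_count / .data$depth,
                          NA_real_))
  }
  p <- unname(gl_normalize(as.matrix(out[, c("gl0", "gl1", "gl2")])))
  out$pl0 <- p[, 1]
  out$pl1 <- p[, 2]
  out$pl2 <- p[, 3]
  out
}
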