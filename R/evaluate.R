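# Benchmarking and concordance metrics: call-set sensitivity/precision and
# genotype accuracy against a truth set, genotyping-array concordance, and
# clone-level cellular concordance for somatic SNV groups.

#' Benchmark a call set against a truth set
#'
#' Both sets are restricted to bi-allelic loci carrying at least one
#' alternative allele and keyed by (chrom, pos, ref, alt). Sensitivity
#' (recall) is `|N ∩ W| / |W|`, precision is `|N ∩ W| / |N|`, genotype
#' accuracy the fraction of identical genotypes over the intersection, and
#' overall accuracy the product of precision and genotype accuracy.
#'
#' @param calls,truth Tibbles with `chrom`, `pos`, `ref`, `alt`, `genotype`
#'   (0/1/2); rows with genotype 0 are dropped.
#' @return A `benchmark_report` list with the counts and rates; undefined
#'   rates (empty sets) are `NA`.
#' @export
benchmark_calls <- function(calls, truth) {
  key <- function(x) {
    x <- as_tibble(x) %>% filter(.data$genotype %in% c(1L, 2L))
    x %>% mutate(.key = paste(.data$chrom, .data$pos, .data$ref, .data$alt))
  }
  n_tbl <- key(calls)
  w_tbl <- key(truth)
  inter <- inner_join(n_tbl %>% select(".key", g_call = "genotype"),
                      w_tbl %>% select(".key", g_truth = "genotype"),
                      by = ".key")
  n_n <- nrow(n_tbl)
  n_w <- nrow(w_tbl)
  n_i <- nrow(inter)
  sens <- if (n_w > 0) n_i / n_w else NA_real_
  prec <- if (n_n > 0) n_i / n_n else NA_real_
  gacc <- if (n_i > 0) mean(inter$g_call == inter$g_truth) else NA_real_
  breakdown <- inter %>%
    filter(.data$g_call != .data$g_truth) %>%
    dplyr::count(.data$g_truth, .data$g_call, name = "n")
  structure(list(
    n_calls = n_n, n_truth = n_w, n_overlap = n_i,
    sensitivity = sens, precision = prec, genotype_accuracy = gacc,
    overall_accuracy = prec * gacc,
    genotype_errors = breakdown
  ), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf(paste0("<benchmark_report> |N|=%d |W|=%d overlap=%d\n",
                     "  sensitivity %.4f  precision %.4f  genotype acc %.4f",
                     "  overall %.4f\n"),
              x$n_calls, x$n_truth, x$n_overlap, x$sensitivity, x$precision,
              x$genotype_accuracy, x$overall_accuracy))
  invisible(x)
}

#' @export
glance.benchmark_report <- function(x, ...) {
  tibble(n_calls = x$n_calls, n_truth = x$n_truth, n_overlap = x$n_overlap,
         sensitivity = x$sensitivity, precision = x$precision,
         genotype_accuracy = x$genotype_accuracy,
         overall_accuracy = x$overall_accuracy)
}

#' @export
tidy.benchmark_report <- function(x, ...) x$genotype_errors

# allele multiset per 0/1/2 genotype
genotype_alleles <- function(g) {
  lapply(g, function(x) c(2L - x, x)) # counts of (ref, alt)
}

#' Genotype concordance against array genotypes
#'
#' Per shared locus, counts matching alleles between the two genotype
#' multisets (0-2), subtracts the minimum possible match (1 when either
#' genotype is heterozygous — some match is then always possible — else 0),
#' and normalizes. With `normalization = "attainable"` (default) the summed
#' excess matches are divided by the summed attainable excess
#' `sum(2 - min_possible)`, giving a score in `[0, 1]` that is 1 exactly for
#' identical, informative genotypes; `"per_locus"` divides by the number of
#' loci evaluated instead.
#'
#' @param calls,array Tibbles with `chrom`, `pos`, `genotype` (0/1/2).
#' @param normalization `"attainable"` or `"per_locus"`.
#' @return A single concordance score.
#' @export
array_concordance <- function(calls, array,
                              normalization = c("attainable", "per_locus")) {
  normalization <- match.arg(normalization)
  shared <- inner_join(
    as_tibble(calls) %>% select("chrom", "pos", g1 = "genotype"),
    as_tibble(array) %>% select("chrom", "pos", g2 = "genotype"),
    by = c("chrom", "pos"))
  if (nrow(shared) == 0L) abort("no shared loci between the two call sets.")
  match_n <- with(shared, pmin(2L - g1, 2L - g2) + pmin(g1, g2))
  min_possible <- with(shared, as.integer(g1 == 1L | g2 == 1L))
  num <- sum(match_n - min_possible)
  den <- switch(normalization,
                attainable = sum(2L - min_possible),
                per_locus = nrow(shared))
  num / den
}

#' Cellular concordance between somatic SNV groups and reference clones
#'
#' Matches each reference clone (e.g. an mtDNA clone) to the SNV group with
#' the highest Jaccard overlap of cell memberships (or uses a supplied
#' matching), then scores each clone as the number of cells detected in
#' both, divided by the clone size; the overall concordance is the
#' unweighted mean over clones. Optionally pre-filters SNV groups to those
#' significantly enriched in a clone (two-sample rank test on per-cell
#' membership indicators, p < `enrich_p`).
#'
#' @param snv_groups Tibble `cell`, `group`: cells carrying each somatic SNV
#'   group.
#' @param clones Tibble `cell`, `clone`: reference clone memberships.
#' @param matching Optional tibble `clone`, `group` fixing the assignment.
#' @param enrich_p When not `NULL`, drop groups whose best clone enrichment
#'   rank-test p-value is above this cutoff.
#' @return List with `per_clone` (tibble: clone, group, n_clone, n_both,
#'   concordance) and `overall` (mean concordance).
#' @export
clone_concordance <- function(snv_groups, clones, matching = NULL,
                              enrich_p = NULL) {
  snv_groups <- as_tibble(snv_groups)
  clones <- as_tibble(clones)
  if (length(intersect(unique(snv_groups$cell), unique(clones$cell))) == 0L) {
    abort("the cell universes of `snv_groups` and `clones` do not overlap.")
  }
  group_cells <- split(snv_groups$cell, snv_groups$group)
  clone_cells <- split(clones$cell, clones$clone)
  universe <- union(snv_groups$cell, clones$cell)

  if (!is.null(enrich_p)) {
    keep <- vapply(group_cells, function(gc) {
      ind <- as.integer(universe %in% gc)
      ps <- vapply(clone_cells, function(cc) {
        inc <- universe %in% cc
        if (all(inc) || !any(inc)) return(1)
        suppressWarnings(wilcox.test(ind[inc], ind[!inc],
                                     alternative = "greater",
                                     exact = FALSE)$p.value)
      }, numeric(1))
      any(ps < enrich_p)
    }, logical(1))
    group_cells <- group_cells[keep]
  }

  per_clone <- purrr::map_dfr(names(clone_cells), function(cl) {
    a <- clone_cells[[cl]]
    if (length(a) == 0L) {
      warn(sprintf("reference clone %s is empty; skipped.", cl))
      return(tibble())
    }
    if (!is.null(matching)) {
      grp <- matching$group[match(cl, as.character(matching$clone))]
    } else if (length(group_cells)) {
      jac <- vapply(group_cells, function(b) {
        length(intersect(a, b)) / length(union(a, b))
      }, numeric(1))
      grp <- names(group_cells)[which.max(jac)]
    } else {
      grp <- NA_character_
    }
    b <- if (is.na(grp)) character(0) else group_cells[[grp]]
    tibble(clone = cl, group = grp, n_clone = length(a),
           n_both = length(intersect(a, b)),
           concordance = length(intersect(a, b)) / length(a))
  })
  list(per_clone = per_clone, overall = mean(per_clone$concordance))
}
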