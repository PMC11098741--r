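# Sequencing-error model: loci called heterozygous (or hom-alt) from the
# data but imputed homozygous-reference by the panel are binned into 12
# het-to-hom collapse categories; the median BAF per category separates
# sequencing errors from true heterozygotes among de novo candidates.

# The 12 categories: 6 unordered base pairs x 2 collapse directions.
error_categories <- function() {
  pairs <- utils::combn(DNA_BASES, 2, simplify = FALSE)
  unlist(lapply(pairs, function(p) {
    pair <- paste0(p[1], p[2])
    c(paste0(pair, "->", p[1], p[1]), paste0(pair, "->", p[2], p[2]))
  }))
}

#' Discordance category of a het-to-hom collapse
#'
#' Maps a heterozygous allele pair collapsed to one of its alleles onto one
#' of the 12 discordance categories (e.g. `{A,T}` collapsed to `A` is
#' `AT->AA`). The pair is unordered; labels use alphabetical order within
#' the pair.
#'
#' @param het_alleles Character vector of two distinct bases (or a vector of
#'   2-character strings).
#' @param hom_allele The allele the site collapsed to; must be one of
#'   `het_alleles`.
#' @return Category label(s), e.g. `"AT->AA"`.
#' @export
discordance_category <- function(het_alleles, hom_allele) {
  if (is.character(het_alleles) && length(het_alleles) == 2L &&
      all(nchar(het_alleles) == 1L) && length(hom_allele) == 1L) {
    het_alleles <- paste0(het_alleles[1], het_alleles[2])
  }
  a1 <- substr(het_alleles, 1, 1)
  a2 <- substr(het_alleles, 2, 2)
  if (any(a1 == a2)) abort("heterozygous alleles must be distinct.")
  if (!all(c(a1, a2, hom_allele) %in% DNA_BASES)) {
    abort("alleles must be A, C, G or T.")
  }
  if (any(hom_allele != a1 & hom_allele != a2)) {
    abort("`hom_allele` must be one of the heterozygous alleles.")
  }
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  paste0(lo, hi, "->", hom_allele, hom_allele)
}

#' Fit the 12-category sequencing-error model
#'
#' The per-category BAF threshold is the median BAF over all discordant loci
#' in that category; a category with no loci falls back to the global median
#' over all error loci (or `default_threshold` when there are no loci at
#' all).
#'
#' @param error_loci Tibble of discordant loci with either a `category`
#'   column or `ref`/`alt`/`hom_allele` columns, plus `baf` in `[0, 1]`.
#' @param default_threshold Fallback threshold when no error loci exist.
#' @return A `snv_error_model`: thresholds per category plus counts.
#' @export
fit_error_model <- function(error_loci, default_threshold = 0.1) {
  error_loci <- as_tibble(error_loci)
  cats <- error_categories()
  if (nrow(error_loci) > 0) {
    if (!"category" %in% names(error_loci)) {
      stopifnot(all(c("ref", "alt", "hom_allele") %in% names(error_loci)))
      error_loci$category <- purrr::map2_chr(
        paste0(pmin(error_loci$ref, error_loci$alt),
               pmax(error_loci$ref, error_loci$alt)),
        error_loci$hom_allele, discordance_category)
    }
    if (any(error_loci$baf < 0 | error_loci$baf > 1)) {
      abort("`baf` values must lie in [0, 1].")
    }
    fallback <- median(error_loci$baf)
  } else {
    warn("no error loci supplied; using the default fallback threshold.")
    fallback <- default_threshold
  }
  per_cat <- if (nrow(error_loci) > 0) {
    error_loci %>%
      group_by(.data$category) %>%
      summarise(threshold = median(.data$baf), n = dplyr::n(),
                .groups = "drop")
  } else {
    tibble(category = character(), threshold = double(), n = integer())
  }
  tbl <- tibble(category = cats) %>%
    left_join(per_cat, by = "category") %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
           from_fallback = is.na(.data$threshold),
           threshold = ifelse(is.na(.data$threshold), fallback,
                              .data$threshold))
  structure(list(thresholds = tbl, fallback = fallback,
                 n_loci = nrow(error_loci)),
            class = "snv_error_model")
}

#' @export
print.snv_error_model <- function(x, ...) {
  cat(sprintf("<snv_error_model> 12 categories; %d error loci; fallback %.4f\n",
              x$n_loci, x$fallback))
  print(x$thresholds, n = 12)
  invisible(x)
}

#' @export
tidy.snv_error_model <- function(x, ...) x$thresholds

#' @export
glance.snv_error_model <- function(x, ...) {
  tibble(n_loci = x$n_loci, fallback = x$fallback,
         n_categories_observed = sum(x$thresholds$n > 0))
}

# Threshold applied to a candidate with allele pair {ref, alt}: the max of
# the two collapse-direction thresholds of that pair.
error_model_threshold <- function(model, ref, alt) {
  tbl <- model$thresholds
  lo <- pmin(ref, alt)
  hi <- pmax(ref, alt)
  c1 <- paste0(lo, hi, "->", ref, ref)
  c2 <- paste0(lo, hi, "->", alt, alt)
  pmax(tbl$threshold[match(c1, tbl$category)],
       tbl$threshold[match(c2, tbl$category)])
}

#' Depth and BAF filtering of de novo candidates
#'
#' A de novo candidate (a scanned SNV absent from the reference panel)
#' passes when its pooled sequencing depth is at least `min_depth`
#' (threshold inclusive) and its pooled BAF is not below the
#' sequencing-error threshold for its allele pair: a candidate with alleles
#' A/T fails when BAF < max{threshold(AT->AA), threshold(AT->TT)}.
#'
#' @param sites Candidate tibble with `ref`, `alt`, `depth`, `baf`.
#' @param model A fitted `snv_error_model`.
#' @param min_depth Minimum pooled depth (default 100).
#' @return `sites` with added `baf_threshold`, `filter` (`"pass"`,
#'   `"dp_low"` or `"baf_error_like"`) and logical `pass` columns.
#' @export
filter_denovo_candidates <- function(sites, model, min_depth = 100) {
  stopifnot(inherits(model, "snv_error_model"))
  sites <- as_tibble(sites)
  sites %>%
    mutate(
      baf_threshold = error_model_threshold(model, .data$ref, .data$alt),
      filter = case_when(
        .data$depth < min_depth ~ "dp_low",
        .data$baf < .data$baf_threshold ~ "baf_error_like",
        TRUE ~ "pass"
      ),
      pass = .data$filter == "pass"
    )
}
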