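# SVM-based artifact filter for de novo candidates: variant-quality features
# extracted from pooled read evidence, training sets built from
# panel-overlapping germline calls (positives) and consecutive de novo
# chunks (negatives), and a radial-kernel support-vector classifier with
# deterministic Platt-scaled probabilities.

# Variant distance bias: dispersion of alternative-read positions within the
# read, relative to the uniform-placement expectation (L^2 - 1) / 12 over
# the observed read span. Values near 1 mean alt calls are spread across
# read positions as cleanly mapped variants are; values near 0 flag alt
# calls clustered at one read position (e.g. splice-site artifacts).
# Neutral value (fewer than 2 alt reads): 1.
vdb_statistic <- function(read_position, is_alt) {
  rp_alt <- read_position[is_alt]
  if (length(rp_alt) < 2L) return(1)
  span <- diff(range(read_position)) + 1
  expected <- (span^2 - 1) / 12
  if (expected <= 0) return(1)
  min(1, var(rp_alt) * (length(rp_alt) - 1) / length(rp_alt) / expected)
}

# Segregation-based metric: concentration of alternative reads in few cells.
# 0 when every alt read sits in a distinct cell, approaching 1 when all alt
# reads come from one cell. Neutral value (no alt reads): 0.
sgb_statistic <- function(cell, is_alt) {
  cells_alt <- cell[is_alt]
  n <- length(cells_alt)
  if (n == 0L) return(0)
  1 - length(unique(cells_alt)) / n
}

# Strand-balance component of MQSB: z-transformed Fisher exact test of the
# strand x allele 2x2 table; 0 when strands are balanced or one-sided.
strand_bias_z <- function(strand, is_alt) {
  if (length(unique(strand)) < 2L || !any(is_alt) || all(is_alt)) return(0)
  tab <- table(factor(strand, c("+", "-")), factor(is_alt, c(FALSE, TRUE)))
  p <- fisher.test(tab)$p.value
  qnorm(1 - min(p, 1) / 2)
}

#' Variant-quality features for the SVM filter
#'
#' Computes, per candidate site, the feature vector used to separate true
#' SNVs from sequencing artifacts: `qs` (phred-scaled probability that the
#' site is non-reference, from the genotype likelihoods), `vdb` (variant
#' distance bias of alt-read positions), `rpb` and `bqb` (Mann-Whitney
#' rank-sum z statistics comparing ref- vs alt-supporting reads on read
#' position and base quality), `mqsb` (mapping-quality rank-sum z combined
#' with a strand-balance exact-test z), `sgb` (segregation of alt reads
#' across cells) and `baf`. One-sided sites (no alt reads on one side of a
#' comparison) get neutral imputation (z = 0).
#'
#' @param reads Read-observation tibble (`chrom`, `pos`, `ref`, `base`,
#'   `base_quality`, `mapping_quality`, `read_position`, `strand`, `cell`).
#' @param sites Candidate sites ([scan_candidates()]); scanned from `reads`
#'   when `NULL`.
#' @return `sites` with feature columns `qs`, `vdb`, `rpb`, `bqb`, `mqsb`,
#'   `sgb`, `baf`.
#' @export
site_features <- function(reads, sites = NULL) {
  reads <- as_tibble(reads)
  if (is.null(sites)) sites <- scan_candidates(reads)
  gl <- genotype_likelihoods(reads, sites)
  qs <- -10 * log10(pmax(gl$pl0, 1e-30))

  obs <- reads %>%
    select("chrom", "pos", "ref", "base", "base_quality",
           "mapping_quality", "read_position", "strand", "cell") %>%
    inner_join(sites %>% select("chrom", "pos", "ref", "alt"),
               by = c("chrom", "pos", "ref")) %>%
    filter(.data$base == .data$ref | .data$base == .data$alt) %>%
    mutate(is_alt = .data$base == .data$alt)
  feats <- obs %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(
      vdb = vdb_statistic(.data$read_position, .data$is_alt),
      rpb = rank_sum_z(.data$read_position[!.data$is_alt],
                       .data$read_position[.data$is_alt]),
      bqb = rank_sum_z(.data$base_quality[!.data$is_alt],
                       .data$base_quality[.data$is_alt]),
      mqsb = 0.5 * (rank_sum_z(.data$mapping_quality[!.data$is_alt],
                               .data$mapping_quality[.data$is_alt]) +
                      strand_bias_z(.data$strand, .data$is_alt)),
      sgb = sgb_statistic(.data$cell, .data$is_alt),
      .groups = "drop"
    )
  sites %>%
    mutate(qs = qs) %>%
    left_join(feats, by = c("chrom", "pos")) %>%
    mutate(vdb = ifelse(is.na(.data$vdb), 1, .data$vdb),
           rpb = ifelse(is.na(.data$rpb), 0, .data$rpb),
           bqb = ifelse(is.na(.data$bqb), 0, .data$bqb),
           mqsb = ifelse(is.na(.data$mqsb), 0, .data$mqsb),
           sgb = ifelse(is.na(.data$sgb), 0, .data$sgb))
}

#' Build SVM training sets from germline calls and de novo candidates
#'
#' Positives are all panel-overlapping germline calls. Negatives are de novo
#' candidates lying in genomic chunks (fixed windows of `chunk_size` bp)
#' that contain no germline call and more than `min_run` de novo candidates
#' (multiple somatic SNVs clustering in a germline-free region are
#' implausible at typical somatic mutation rates). Remaining de novo
#' candidates form the test set.
#'
#' @param germline Tibble of germline calls (`chrom`, `pos`).
#' @param denovo Tibble of de novo candidates (`chrom`, `pos`), position
#'   sorted.
#' @param chunk_size Chunk width in bp (default 50 kb).
#' @param min_run Negative chunks must carry strictly more than this many de
#'   novo candidates (default 2).
#' @return List with `positives`, `negatives`, `test` tibbles.
#' @export
build_training_sets <- function(germline, denovo, chunk_size = 5e4,
                                min_run = 2L) {
  germline <- as_tibble(germline)
  denovo <- as_tibble(denovo)
  g_chunks <- unique(paste(germline$chrom, germline$pos %/% chunk_size))
  denovo <- denovo %>%
    mutate(.chunk = paste(.data$chrom, .data$pos %/% chunk_size))
  chunk_n <- denovo %>% dplyr::count(.data$.chunk)
  neg_chunks <- chunk_n$.chunk[chunk_n$n > min_run &
                                 !(chunk_n$.chunk %in% g_chunks)]
  negatives <- denovo %>% filter(.data$.chunk %in% neg_chunks) %>%
    select(-".chunk")
  test <- denovo %>% filter(!(.data$.chunk %in% neg_chunks)) %>%
    select(-".chunk")
  if (nrow(germline) == 0L) {
    abort(paste0("no positive training sites: no germline calls overlap ",
                 "the panel. Provide germline calls before SVM filtering."))
  }
  if (nrow(negatives) == 0L) {
    abort(paste0("no negative training sites: no germline-free chunk ",
                 "contains more than ", min_run, " de novo candidates. ",
                 "Consider a larger chunk_size or skip the SVM filter."))
  }
  list(positives = germline, negatives = negatives, test = test)
}

FEATURE_COLS <- c("qs", "vdb", "rpb", "bqb", "mqsb", "sgb", "baf")

#' Fit the SVM artifact classifier
#'
#' Trains a radial-kernel support-vector machine on labelled feature
#' vectors. Features are standardized with training-set means and standard
#' deviations (constant features get unit scale); class probabilities are
#' obtained by Platt scaling, i.e. a logistic fit of the labels on the SVM
#' decision values, which is deterministic.
#'
#' @param features Tibble containing the feature columns `qs`, `vdb`,
#'   `rpb`, `bqb`, `mqsb`, `sgb`, `baf`.
#' @param label Logical or 0/1 vector, `TRUE` for positives (germline-like).
#' @param cost SVM cost parameter.
#' @return A `snv_svm` object.
#' @export
fit_snv_svm <- function(features, label, cost = 1) {
  features <- as_tibble(features)
  stopifnot(all(FEATURE_COLS %in% names(features)))
  label <- as.logical(label)
  if (length(unique(label)) < 2L) {
    abort("training labels are single-class; cannot fit the SVM filter.")
  }
  X <- as.matrix(features[, FEATURE_COLS])
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  fit <- e1071::svm(Xs, factor(label, c(FALSE, TRUE)), kernel = "radial",
                    cost = cost, scale = FALSE)
  dv_attr <- attr(predict(fit, Xs, decision.values = TRUE),
                  "decision.values")
  dv <- as.numeric(dv_attr)
  # orient decision values so larger = positive class
  sgn <- if (colnames(dv_attr)[1] == "TRUE/FALSE") 1 else -1
  platt <- suppressWarnings(
    glm(label ~ dv, family = binomial(), data = data.frame(label = label,
                                                           dv = sgn * dv)))
  structure(list(svm = fit, center = mu, scale = sdv, platt = platt,
                 sign = sgn, n_pos = sum(label), n_neg = sum(!label)),
            class = "snv_svm")
}

#' @export
predict.snv_svm <- function(object, newdata, ...) {
  newdata <- as_tibble(newdata)
  X <- as.matrix(newdata[, FEATURE_COLS])
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  dv <- as.numeric(attr(predict(object$svm, Xs, decision.values = TRUE),
                        "decision.values")) * object$sign
  as.numeric(predict(object$platt, data.frame(dv = dv), type = "response"))
}

#' @export
print.snv_svm <- function(x, ...) {
  cat(sprintf("<snv_svm> radial kernel; %d positives, %d negatives, %d SVs\n",
              x$n_pos, x$n_neg, x$svm$tot.nSV))
  invisible(x)
}

#' @export
glance.snv_svm <- function(x, ...) {
  tibble(n_pos = x$n_pos, n_neg = x$n_neg, n_support_vectors = x$svm$tot.nSV,
         cost = x$svm$cost)
}

#' Score de novo candidates with the SVM filter
#'
#' Fits the classifier on the labelled training features and scores the test
#' candidates; candidates with predicted probability of the positive label
#' below 0.5 are marked as sequencing errors (`retained = FALSE`;
#' probability exactly 0.5 is retained).
#'
#' @param train_features Feature tibble for training sites.
#' @param train_label Logical labels for `train_features`.
#' @param test_features Feature tibble for the candidates to score.
#' @param threshold Retention threshold on the positive-class probability.
#' @param cost SVM cost parameter.
#' @return `test_features` with added `svm_prob` and `retained` columns.
#' @export
classify_denovo <- function(train_features, train_label, test_features,
                            threshold = 0.5, cost = 1) {
  model <- fit_snv_svm(train_features, train_label, cost = cost)
  prob <- predict(model, test_features)
  as_tibble(test_features) %>%
    mutate(svm_prob = prob, retained = prob >= threshold)
}
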