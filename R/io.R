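# Plain-text interchange: bi-allelic VCF for panels and calls, sparse
# triplet TSV for the cell-level allele matrix, TSV/JSON for models,
# profiles and manifests. VCF reading goes through vcfR when available;
# writing emits minimal VCFv4.2-conformant text.

vcf_header <- function(extra = character()) {
  c("##fileformat=VCFv4.2",
    extra,
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT"), collapse = "\t")))
}

#' Write a reference panel as a phased bi-allelic VCF
#'
#' Consecutive haplotype pairs form diploid individuals; genotypes use the
#' phased `|` separator.
#'
#' @param panel A `ref_panel` with an even number of haplotypes.
#' @param path Output file path.
#' @export
write_panel_vcf <- function(panel, path) {
  H <- panel$haplotypes
  if (nrow(H) %% 2L != 0L) abort("panel must have an even number of haplotypes.")
  n_ind <- nrow(H) / 2L
  gts <- vapply(seq_len(ncol(H)), function(j) {
    paste(paste0(H[seq(1, nrow(H), 2), j], "|", H[seq(2, nrow(H), 2), j]),
          collapse = "\t")
  }, character(1))
  hdr <- vcf_header('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  hdr[length(hdr)] <- paste(c(hdr[length(hdr)],
                              sprintf("IND%04d", seq_len(n_ind))),
                            collapse = "\t")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                  panel$sites$chrom, panel$sites$pos, panel$sites$ref,
                  panel$sites$alt, gts)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a phased reference panel from VCF
#'
#' Parses a bi-allelic, phased (GT with `|`) VCF into a `ref_panel`.
#' Requires the vcfR package.
#'
#' @param path VCF file path.
#' @return A `ref_panel`.
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF panels requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(!grepl("|", gt, fixed = TRUE))) {
    abort("panel genotypes must be phased ('|' separator).")
  }
  sp <- strsplit(as.vector(t(gt)), "|", fixed = TRUE)
  n_ind <- ncol(gt)
  n_sites <- nrow(gt)
  H <- matrix(0L, 2L * n_ind, n_sites)
  for (j in seq_len(n_sites)) {
    row <- sp[((j - 1L) * n_ind + 1L):(j * n_ind)]
    H[seq(1, 2 * n_ind, 2), j] <- as.integer(vapply(row, `[`, "", 1))
    H[seq(2, 2 * n_ind, 2), j] <- as.integer(vapply(row, `[`, "", 2))
  }
  structure(list(
    sites = tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                   ref = fix$REF, alt = fix$ALT),
    haplotypes = H,
    span_bp = max(as.integer(fix$POS)),
    params = list(source = path)
  ), class = "ref_panel")
}

#' Write genotype calls as VCF
#'
#' Emits one record per call with `GT` (and `GP` posteriors plus a `STATUS`
#' tag when present); de novo/somatic call tables may carry `ps_score`,
#' `orientation`, `n_cells_informative` and `class` columns, which are
#' written as INFO fields.
#'
#' @param calls Tibble with `chrom`, `pos`, `ref`, `alt` and optionally
#'   `genotype`, `gp0..gp2`, `status`, `filter`, `p_s`, `orientation`,
#'   `n_informative`, `class`.
#' @param path Output file path.
#' @param sample Sample name for the genotype column.
#' @export
write_calls_vcf <- function(calls, path, sample = "SAMPLE") {
  calls <- as_tibble(calls)
  n <- nrow(calls)
  gt_str <- if ("genotype" %in% names(calls)) {
    c("0/0", "0/1", "1/1")[calls$genotype + 1L]
  } else {
    rep("./.", n)
  }
  fmt <- "GT"
  if (all(c("gp0", "gp1", "gp2") %in% names(calls))) {
    fmt <- "GT:GP"
    gt_str <- sprintf("%s:%.4g,%.4g,%.4g", gt_str, calls$gp0, calls$gp1,
                      calls$gp2)
  }
  info <- rep(".", n)
  info_bits <- list()
  if ("status" %in% names(calls)) info_bits$STATUS <- calls$status
  if ("p_s" %in% names(calls)) info_bits$ps_score <- sprintf("%.6g", calls$p_s)
  if ("orientation" %in% names(calls)) {
    info_bits$orientation <- calls$orientation
  }
  if ("n_informative" %in% names(calls)) {
    info_bits$n_cells_informative <- calls$n_informative
  }
  if ("class" %in% names(calls)) info_bits$class <- calls$class
  if (length(info_bits)) {
    info <- vapply(seq_len(n), function(i) {
      paste(vapply(names(info_bits), function(k) {
        paste0(k, "=", info_bits[[k]][i])
      }, character(1)), collapse = ";")
    }, character(1))
  }
  filt <- if ("filter" %in% names(calls)) calls$filter else rep("PASS", n)
  hdr <- vcf_header(c(
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GP,Number=3,Type=Float,Description="Genotype posterior">',
    '##INFO=<ID=STATUS,Number=1,Type=String,Description="Refinement status">',
    '##INFO=<ID=ps_score,Number=1,Type=Float,Description="LD refinement score">',
    '##INFO=<ID=orientation,Number=1,Type=String,Description="Phase orientation">',
    '##INFO=<ID=n_cells_informative,Number=1,Type=Integer,Description="Informative cells">',
    '##INFO=<ID=class,Number=1,Type=String,Description="Somatic classification">'))
  hdr[length(hdr)] <- paste(hdr[length(hdr)], sample, sep = "\t")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s\t%s\t%s",
                  calls$chrom, calls$pos, calls$ref, calls$alt, filt, info,
                  fmt, gt_str)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write / read the sparse cell-level allele matrix as triplet TSV
#'
#' The triplet file has columns `cell_id`, `site_index`, `count_allele1`,
#' `count_allele2`; site and cell index files accompany it.
#'
#' @param counts Tibble `site`, `cell`, `c1`, `c2` (or `n_ref`/`n_alt`).
#' @param sites,cells Index tibbles.
#' @param prefix Output path prefix; writes `<prefix>_counts.tsv`,
#'   `<prefix>_sites.tsv`, `<prefix>_cells.tsv`.
#' @return The three file paths, invisibly.
#' @export
write_counts_tsv <- function(counts, sites, cells, prefix) {
  counts <- as_tibble(counts)
  if (!"c1" %in% names(counts) && "n_ref" %in% names(counts)) {
    counts <- counts %>% rename(c1 = "n_ref", c2 = "n_alt")
  }
  paths <- paste0(prefix, c("_counts.tsv", "_sites.tsv", "_cells.tsv"))
  utils::write.table(
    counts %>% select(cell_id = "cell", site_index = "site",
                      count_allele1 = "c1", count_allele2 = "c2"),
    paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sites, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cells, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(prefix) {
  paths <- paste0(prefix, c("_counts.tsv", "_sites.tsv", "_cells.tsv"))
  counts <- as_tibble(utils::read.delim(paths[1])) %>%
    select(cell = "cell_id", site = "site_index", c1 = "count_allele1",
           c2 = "count_allele2")
  list(counts = counts,
       sites = as_tibble(utils::read.delim(paths[2])),
       cells = as_tibble(utils::read.delim(paths[3])))
}

#' Serialize the sequencing-error model as TSV
#' @param model A `snv_error_model`.
#' @param path Output path.
#' @export
write_error_model_tsv <- function(model, path) {
  utils::write.table(model$thresholds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the LD refinement profile as TSV
#' @param profile An `ld_profile`.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(
    profile$profile %>% select(bin_lo = "lo", bin_hi = "hi",
                               score2 = "score2", n2 = "n2",
                               score3 = "score3", n3 = "n3"),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest (seeds, parameters, parameter hash) as JSON
#' @param config A pipeline configuration list.
#' @param path Output path.
#' @export
write_manifest_json <- function(config, path) {
  manifest <- list(
    package = "cellsnv",
    version = as.character(utils::packageVersion("cellsnv")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "stages")],
    parameter_hash = rlang::hash(config)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
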