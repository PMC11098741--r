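# End-to-end orchestration: simulate -> germline (scan, GL, panel
# refinement, error model) -> de novo (depth/BAF filter, SVM) -> somatic
# (LD profile, phasing, classification, cluster genotypes) -> evaluation,
# with optional chunked execution and a reproducible run manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default: read filters
#' (`max_mismatch` 4, `min_mapq` 20), refinement HMM (`theta` 1e-3,
#' `rho_scale` 1e5 bp), de novo depth cutoff (`min_depth` 100), SVM
#' retention probability (`svm_prob` 0.5) and negative-chunk size
#' (`svm_chunk_size` 50 kb), somatic classification threshold
#' (`ps_threshold` 0.25), two-/three-locus distance caps (`cap2`, `cap3`;
#' 100 bp / 10 kb suit DNA-like fragments, 1 kb / 50 kb RNA-like), the 13
#' distance bins, chunked execution (`n_chunks`, `chunk_overlap`), stage
#' toggles and the synthetic-data parameters.
#'
#' @param seed Integer seed driving every random draw of the run.
#' @param ... Overrides for any configuration field (unknown names error).
#' @return A `snv_pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    max_mismatch = 4, min_mapq = 20,
    theta = 1e-3, rho_scale = 1e5, max_panel_haplotypes = 200L,
    min_depth = 100, svm_prob = 0.5, svm_chunk_size = 5e4,
    svm = "auto", # "on", "off", or "auto" (skip when no training sets)
    ps_threshold = 0.25, cap2 = 100, cap3 = 1e4, bins = ld_bins(),
    n_chunks = 1L, chunk_overlap = 5e5,
    stages = list(germline = TRUE, denovo = TRUE, somatic = TRUE,
                  evaluate = TRUE),
    sim = list(n_hap = 40L, n_sites = 600L, span_bp = 2e4,
               recomb_intensity = 1e-4, maf_min = 0.05,
               expected_breakpoints = 1, n_cells = 300L,
               clone_fractions = c(0.3, 0.7), somatic_clone = 1L,
               n_somatic = 4L, somatic_haplotype = 1L,
               mean_depth = 0.5, dropout = 0.1, error_rate = 0.001,
               read_len = 1000, zero_inflation = 0.3)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm == "sim") {
      if (any(!names(dots$sim) %in% names(cfg$sim))) {
        abort("unknown `sim` configuration field(s).")
      }
      cfg$sim[names(dots$sim)] <- dots$sim
    } else if (nm == "stages") {
      cfg$stages[names(dots$stages)] <- dots$stages
    } else if (nm %in% names(cfg)) {
      cfg[[nm]] <- dots[[nm]]
    } else {
      abort(sprintf("unknown configuration field `%s`.", nm))
    }
  }
  structure(cfg, class = "snv_pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path File path.
#' @param config A `snv_pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config,
          c(list(seed = raw$seed), raw[setdiff(names(raw), "seed")]))
}

# Chunked panel refinement: split sites into position windows, refine each
# window extended by the overlap margin, and keep each site's result from
# the window whose core contains it.
refine_chunked <- function(gl, panel, config) {
  n_chunks <- config$n_chunks
  if (n_chunks <= 1L) {
    return(refine_genotypes(gl, panel, theta = config$theta,
                            rho_scale = config$rho_scale,
                            max_panel_haplotypes = config$max_panel_haplotypes))
  }
  brks <- seq(min(gl$pos) - 1, max(gl$pos), length.out = n_chunks + 1)
  out <- purrr::map_dfr(seq_len(n_chunks), function(i) {
    lo <- brks[i]
    hi <- brks[i + 1]
    sub <- gl %>% filter(.data$pos > lo - config$chunk_overlap,
                         .data$pos <= hi + config$chunk_overlap)
    if (nrow(sub) == 0) return(tibble())
    refine_genotypes(sub, panel, theta = config$theta,
                     rho_scale = config$rho_scale,
                     max_panel_haplotypes = config$max_panel_haplotypes) %>%
      filter(.data$pos > lo, .data$pos <= hi) %>%
      mutate(chunk = i)
  })
  out %>% arrange(.data$pos)
}

# Chunked LD profile: neighbourhoods are collected per window (extended by
# the overlap margin) and attributed to the window whose core contains
# their upstream site, so each neighbourhood is counted exactly once;
# neighbourhoods spanning more than the overlap margin are not recovered.
ld_profile_chunked <- function(counts, sites, config) {
  n_chunks <- config$n_chunks
  bins <- config$bins
  if (n_chunks <= 1L) return(ld_profile(counts, sites, bins))
  brks <- seq(min(sites$pos) - 1, max(sites$pos), length.out = n_chunks + 1)
  acc2 <- acc3 <- NULL
  for (i in seq_len(n_chunks)) {
    lo <- brks[i]
    hi <- brks[i + 1]
    s_sub <- sites %>% filter(.data$pos > lo - config$chunk_overlap,
                              .data$pos <= hi + config$chunk_overlap)
    c_sub <- counts %>% semi_join(s_sub, by = "site")
    if (nrow(c_sub) == 0) next
    nb2 <- neighborhoods_two(c_sub, s_sub) %>%
      filter(.data$pos_k > lo, .data$pos_k <= hi)
    nb3 <- neighborhoods_three(c_sub, s_sub) %>%
      filter(.data$pos_k > lo, .data$pos_k <= hi)
    acc2 <- bind_rows(acc2, nb2)
    acc3 <- bind_rows(acc3, nb3)
  }
  summarize_bins <- function(nb, score_col, n_col) {
    n_bins <- length(bins) - 1L
    base <- tibble(bin = seq_len(n_bins))
    if (is.null(nb) || nrow(nb) == 0) {
      base[[score_col]] <- NA_real_
      base[[n_col]] <- 0L
      return(base)
    }
    out <- nb %>%
      mutate(bin = bin_index(.data$d, bins)) %>%
      group_by(.data$bin) %>%
      summarise(score = 1 - mean(.data$coseg), n = dplyr::n(),
                .groups = "drop")
    res <- base %>% left_join(out, by = "bin") %>%
      mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
    res <- res %>% rename(!!score_col := "score", !!n_col := "n")
    res
  }
  profile <- tibble(bin = seq_len(length(bins) - 1L),
                    lo = bins[-length(bins)], hi = bins[-1]) %>%
    left_join(summarize_bins(acc2, "score2", "n2"), by = "bin") %>%
    left_join(summarize_bins(acc3, "score3", "n3"), by = "bin")
  structure(list(profile = profile, bins = bins), class = "ld_profile")
}

#' Run the full SNV-calling pipeline on simulated data
#'
#' Executes the stages enabled in the configuration in order: synthetic
#' data generation, germline calling (read filtering, candidate scan,
#' genotype likelihoods, panel refinement, consensus), the sequencing-error
#' model and de novo filters, the SVM artifact filter (skipped, under
#' `svm = "auto"`, when no valid training sets exist in the run), somatic
#' LD refinement (profile, phasing, classification, per-clone genotypes)
#' and benchmarking against the simulation truth. All randomness derives
#' from `config$seed`.
#'
#' @param config A `snv_pipeline_config`.
#' @param out_dir Optional directory; when given, VCFs, TSVs and the run
#'   manifest are written there.
#' @return A `snv_pipeline_result` list with per-stage tibbles and a
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "snv_pipeline_config"))
  sm <- config$sim
  seed <- config$seed

  panel <- simulate_panel(n_hap = sm$n_hap, n_sites = sm$n_sites,
                          span_bp = sm$span_bp,
                          recomb_intensity = sm$recomb_intensity,
                          maf_min = sm$maf_min, seed = seed)
  smp <- simulate_sample(panel, expected_breakpoints = sm$expected_breakpoints,
                         seed = seed + 1L)
  clones <- clone_population(sm$n_cells, sm$clone_fractions)
  # somatic SNVs live at non-panel positions (de novo by construction):
  # midpoints of well-separated panel-site gaps, spread along the span
  extra_som <- NULL
  if (sm$n_somatic > 0) {
    ppos <- panel$sites$pos
    gaps <- which(diff(ppos) >= 4L)
    pick <- gaps[round(seq(0.15, 0.85, length.out = sm$n_somatic) *
                         length(gaps))]
    extra_som <- with_seed_if(seed + 3L, {
      ref <- sample(DNA_BASES, length(pick), replace = TRUE)
      alt <- DNA_BASES[(match(ref, DNA_BASES) - 1L +
                          sample.int(3L, length(pick), TRUE)) %% 4L + 1L]
      tibble(pos = (ppos[pick] + ppos[pick + 1L]) %/% 2L,
             ref = ref, alt = alt,
             clone = sm$somatic_clone, haplotype = sm$somatic_haplotype)
    })
  }
  sim <- simulate_cells(smp, clones, NULL, extra_somatic = extra_som,
                        mean_depth = sm$mean_depth,
                        dropout = sm$dropout, error_rate = sm$error_rate,
                        read_len = sm$read_len,
                        zero_inflation = sm$zero_inflation,
                        pileup = TRUE, seed = seed + 2L)

  result <- list(config = config, panel = panel, sim = sim)

  if (!config$stages$germline) {
    return(finish_pipeline(result, out_dir))
  }

  reads <- filter_reads(sim$pileup, config$max_mismatch, config$min_mapq)
  candidates <- scan_candidates(reads)
  gl_panel <- genotype_likelihoods(reads, panel$sites)
  refined <- refine_chunked(gl_panel, panel, config)
  consensus <- consensus_calls(refined)
  result$candidates <- candidates
  result$refined <- refined
  result$germline <- consensus$germline
  result$error_loci <- consensus$error_loci

  if (config$stages$denovo) {
    denovo_cand <- candidates %>%
      anti_join(panel$sites, by = c("chrom", "pos"))
    model <- withCallingHandlers(
      fit_error_model(result$error_loci),
      warning = function(w) invokeRestart("muffleWarning"))
    filtered <- filter_denovo_candidates(denovo_cand, model,
                                         config$min_depth)
    result$error_model <- model
    result$denovo <- filtered
    passing <- filtered %>% filter(.data$pass)

    svm_status <- "skipped"
    if (config$svm != "off" && nrow(passing) > 0) {
      ts <- tryCatch(
        build_training_sets(result$germline, passing,
                            chunk_size = config$svm_chunk_size),
        error = function(e) e)
      if (inherits(ts, "error")) {
        if (config$svm == "on") abort(conditionMessage(ts))
      } else {
        feat_all <- site_features(
          reads, bind_rows(ts$positives %>%
                             select("chrom", "pos", "ref", "alt"),
                           passing %>%
                             select("chrom", "pos", "ref", "alt")) %>%
            distinct())
        fk <- paste(feat_all$chrom, feat_all$pos)
        f_pos <- feat_all[fk %in% paste(ts$positives$chrom,
                                        ts$positives$pos), ]
        f_neg <- feat_all[fk %in% paste(ts$negatives$chrom,
                                        ts$negatives$pos), ]
        f_test <- feat_all[fk %in% paste(passing$chrom, passing$pos), ]
        scored <- classify_denovo(bind_rows(f_pos, f_neg),
                                  c(rep(TRUE, nrow(f_pos)),
                                    rep(FALSE, nrow(f_neg))),
                                  f_test, threshold = config$svm_prob)
        passing <- passing %>%
          inner_join(scored %>% select("chrom", "pos", "svm_prob",
                                       "retained"),
                     by = c("chrom", "pos")) %>%
          filter(.data$retained)
        svm_status <- "applied"
      }
    }
    result$svm_status <- svm_status
    result$denovo_retained <- passing
  }

  if (config$stages$somatic && !is.null(result$denovo_retained) &&
      nrow(result$denovo_retained) > 0) {
    site_ids <- sim$sites %>% select("site", "chrom", "pos")
    germ_phased <- result$germline %>%
      filter(.data$genotype == 1L) %>%
      inner_join(site_ids, by = c("chrom", "pos")) %>%
      select("site", "pos", "hap1_is_alt")
    den_sites <- result$denovo_retained %>%
      inner_join(site_ids, by = c("chrom", "pos")) %>%
      select("site", "pos")
    am <- build_allele_matrix(sim$counts, germ_phased, den_sites)
    profile <- ld_profile_chunked(am$counts, am$sites, config)
    phased <- phase_denovo(am$denovo_sites, am$denovo_counts, am$counts,
                           am$sites, profile,
                           cap2 = config$cap2, cap3 = config$cap3)
    somatic <- classify_somatic(phased, config$ps_threshold) %>%
      left_join(site_ids, by = c("site", "pos")) %>%
      left_join(result$denovo_retained %>% select("chrom", "pos", "ref",
                                                  "alt"),
                by = c("chrom", "pos"))
    result$ld_profile <- profile
    result$somatic <- somatic
    result$cluster_genotypes <- cluster_genotype(
      sim$counts %>% semi_join(den_sites, by = "site"),
      sim$cells %>% rename(cluster = "clone"),
      error_rate = max(sm$error_rate, 1e-4))
  }

  if (config$stages$evaluate && !is.null(result$germline)) {
    truth <- sim$truth$germline %>% filter(.data$genotype > 0L)
    result$benchmark <- benchmark_calls(result$germline, truth)
    if (!is.null(result$somatic)) {
      truth_som <- sim$sites %>% filter(.data$somatic) %>% pull("site")
      result$somatic_summary <- result$somatic %>%
        mutate(is_true_somatic = .data$site %in% truth_som) %>%
        dplyr::count(.data$class, .data$is_true_somatic)
    }
  }

  finish_pipeline(result, out_dir)
}

finish_pipeline <- function(result, out_dir) {
  result$manifest <- list(
    package = "cellsnv",
    version = as.character(utils::packageVersion("cellsnv")),
    seed = result$config$seed,
    parameter_hash = rlang::hash(unclass(result$config)),
    stages_run = names(which(unlist(result$config$stages)))
  )
  class(result) <- "snv_pipeline_result"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_panel_vcf(result$panel, file.path(out_dir, "panel.vcf"))
    write_counts_tsv(result$sim$counts, result$sim$sites, result$sim$cells,
                     file.path(out_dir, "cell_matrix"))
    if (!is.null(result$germline)) {
      write_calls_vcf(result$germline, file.path(out_dir, "germline.vcf"))
    }
    if (!is.null(result$error_model)) {
      write_error_model_tsv(result$error_model,
                            file.path(out_dir, "error_model.tsv"))
    }
    if (!is.null(result$ld_profile)) {
      write_profile_tsv(result$ld_profile,
                        file.path(out_dir, "ld_profile.tsv"))
    }
    if (!is.null(result$somatic)) {
      write_calls_vcf(result$somatic %>%
                        filter(!is.na(.data$ref)),
                      file.path(out_dir, "somatic.vcf"))
    }
    write_manifest_json(unclass(result$config),
                        file.path(out_dir, "manifest.json"))
  }
  result
}

#' @export
print.snv_pipeline_result <- function(x, ...) {
  cat("<snv_pipeline_result>\n")
  cat(sprintf("  seed %d; stages: %s\n", x$config$seed,
              paste(x$manifest$stages_run, collapse = ", ")))
  if (!is.null(x$germline)) {
    cat(sprintf("  germline calls: %d (of %d refined sites)\n",
                nrow(x$germline), nrow(x$refined)))
  }
  if (!is.null(x$denovo)) {
    cat(sprintf("  de novo candidates: %d scanned, %d past filters (SVM %s)\n",
                nrow(x$denovo),
                if (is.null(x$denovo_retained)) 0L else nrow(x$denovo_retained),
                x$svm_status %||% "skipped"))
  }
  if (!is.null(x$somatic)) {
    cat(sprintf("  somatic classification: %s\n",
                paste(sprintf("%s=%d", names(table(x$somatic$class)),
                              table(x$somatic$class)), collapse = " ")))
  }
  if (!is.null(x$benchmark)) {
    cat(sprintf("  germline benchmark: sens %.3f prec %.3f gacc %.3f overall %.3f\n",
                x$benchmark$sensitivity, x$benchmark$precision,
                x$benchmark$genotype_accuracy, x$benchmark$overall_accuracy))
  }
  invisible(x)
}
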