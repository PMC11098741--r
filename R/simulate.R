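# Synthetic-data generator: reference haplotype panels, diploid samples,
# clonal cell populations, and sparse per-cell sequencing evidence with known
# truth. The generator reproduces the statistical structure the caller
# assumes: block-wise LD in the panel, mosaic diploid haplotypes, zero-
# inflated per-cell depth, allelic dropout, and read-length-limited physical
# phasing (loci on one fragment share a haplotype draw).

#' Simulate a phased reference haplotype panel
#'
#' Generates `n_hap` phased haplotypes over `n_sites` bi-allelic SNVs with a
#' copying process: each new haplotype copies a previously generated one,
#' switching donors along the chromosome at rate `recomb_intensity` per bp and
#' miscopying each allele with probability `mutation_rate`. This yields
#' block-wise LD that decays with physical distance, the property the
#' genotype-refinement HMM and the cell-population LD models rely on.
#'
#' @param n_hap Number of haplotypes (>= 4). Haplotypes are conventionally
#'   paired into diploid individuals, so an even number is natural.
#' @param n_sites Number of SNV sites (>= 2).
#' @param span_bp Chromosome span in bp; positions are drawn uniformly.
#' @param recomb_intensity Donor-switch rate per bp of the copying process.
#' @param maf_min Minimum minor-allele frequency enforced per site
#'   (0 <= maf_min < 0.5). When > 0 every site is guaranteed polymorphic.
#' @param mutation_rate Per-site miscopy probability of the copying process.
#' @param chrom Chromosome name used in site records.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   panels.
#' @return A `ref_panel` object: list with `sites` (tibble: chrom, pos, ref,
#'   alt), `haplotypes` (n_hap x n_sites 0/1 matrix, 1 = alternative allele)
#'   and `span_bp`.
#' @examples
#' p <- simulate_panel(n_hap = 8, n_sites = 20, span_bp = 1e4, seed = 1)
#' dim(p$haplotypes)
#' @export
simulate_panel <- function(n_hap = 40, n_sites = 500, span_bp = 1e6,
                           recomb_intensity = 1e-5, maf_min = 0.05,
                           mutation_rate = 0.02, chrom = "chr1", seed = NULL) {
  if (n_hap < 4) abort("`n_hap` must be >= 4.")
  if (n_sites < 2) abort("`n_sites` must be >= 2.")
  if (span_bp < n_sites) abort("`span_bp` must be >= `n_sites`.")
  stopifnot_scalar_number(maf_min, "maf_min", 0, 0.5, strict_upper = TRUE)
  stopifnot_scalar_number(recomb_intensity, "recomb_intensity", 0)

  with_seed_if(seed, {
    pos <- sort(sample.int(span_bp, n_sites))
    ref <- sample(DNA_BASES, n_sites, replace = TRUE)
    alt <- DNA_BASES[(match(ref, DNA_BASES) - 1L +
                        sample.int(3L, n_sites, replace = TRUE)) %% 4L + 1L]

    f <- stats::rbeta(n_sites, 0.4, 0.4)
    H <- matrix(0L, n_hap, n_sites)
    H[1, ] <- rbinom(n_sites, 1L, f)
    gaps <- diff(pos)
    p_switch <- 1 - exp(-recomb_intensity * gaps)
    for (h in 2:n_hap) {
      switch_at <- c(TRUE, runif(n_sites - 1L) < p_switch)
      donors <- sample.int(h - 1L, sum(switch_at), replace = TRUE)
      donor <- donors[cumsum(switch_at)]
      allele <- H[cbind(donor, seq_len(n_sites))]
      flip <- runif(n_sites) < mutation_rate
      H[h, ] <- ifelse(flip, 1L - allele, allele)
    }

    if (maf_min > 0) {
      target <- max(ceiling(maf_min * n_hap), 1L)
      for (j in seq_len(n_sites)) {
        n_alt <- sum(H[, j])
        minor_is_alt <- n_alt <= n_hap / 2
        n_minor <- if (minor_is_alt) n_alt else n_hap - n_alt
        if (n_minor < target) {
          major_idx <- which(H[, j] == as.integer(!minor_is_alt))
          flip_idx <- sample(major_idx, target - n_minor)
          H[flip_idx, j] <- as.integer(minor_is_alt)
        }
      }
    }

    structure(list(
      sites = tibble(chrom = chrom, pos = pos, ref = ref, alt = alt),
      haplotypes = H,
      span_bp = span_bp,
      params = list(n_hap = n_hap, n_sites = n_sites, span_bp = span_bp,
                    recomb_intensity = recomb_intensity, maf_min = maf_min,
                    mutation_rate = mutation_rate, seed = seed)
    ), class = "ref_panel")
  })
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("<ref_panel> %d haplotypes x %d sites over %s bp\n",
              nrow(x$haplotypes), ncol(x$haplotypes),
              format(x$span_bp, big.mark = ",")))
  invisible(x)
}

#' Simulate a diploid sample as a mosaic of panel haplotypes
#'
#' Each of the two sample haplotypes copies panel haplotypes, switching donors
#' along the chromosome so that the expected number of breakpoints per
#' haplotype equals `expected_breakpoints` (Poisson-like switching over
#' inter-site gaps). With `expected_breakpoints = 0` each haplotype is an
#' exact copy of one panel haplotype.
#'
#' @param panel A `ref_panel`.
#' @param expected_breakpoints Expected donor switches per haplotype across
#'   the panel span.
#' @param seed Optional integer seed.
#' @return A `diploid_sample`: list with `hap1`, `hap2` (0/1 allele vectors
#'   over panel sites), `genotype` (= hap1 + hap2), `breakpoints` (list of bp
#'   positions per haplotype) and `sites`.
#' @export
simulate_sample <- function(panel, expected_breakpoints = 1, seed = NULL) {
  stopifnot(inherits(panel, "ref_panel"))
  stopifnot_scalar_number(expected_breakpoints, "expected_breakpoints", 0)
  H <- panel$haplotypes
  pos <- panel$sites$pos
  n_sites <- length(pos)
  n_hap <- nrow(H)
  span <- max(pos) - min(pos)
  lambda <- if (span > 0) expected_breakpoints / span else 0

  with_seed_if(seed, {
    # Draw donors and switches in a single pass per haplotype (clearer than
    # a vectorized form; n_sites is modest).
    draw_hap <- function() {
      donor <- integer(n_sites)
      donor[1] <- sample.int(n_hap, 1L)
      bp <- integer(0)
      if (n_sites > 1) {
        p_sw <- 1 - exp(-lambda * diff(pos))
        sw <- runif(n_sites - 1L) < p_sw
        for (i in seq_len(n_sites - 1L)) {
          if (sw[i]) {
            donor[i + 1L] <- sample(setdiff(seq_len(n_hap), donor[i]), 1L)
            bp <- c(bp, pos[i + 1L])
          } else {
            donor[i + 1L] <- donor[i]
          }
        }
      }
      list(alleles = H[cbind(donor, seq_len(n_sites))], breakpoints = bp,
           donor = donor)
    }
    h1 <- draw_hap()
    h2 <- draw_hap()
    structure(list(
      hap1 = h1$alleles, hap2 = h2$alleles,
      genotype = h1$alleles + h2$alleles,
      breakpoints = list(hap1 = h1$breakpoints, hap2 = h2$breakpoints),
      donors = list(hap1 = h1$donor, hap2 = h2$donor),
      sites = panel$sites
    ), class = "diploid_sample")
  })
}

#' @export
print.diploid_sample <- function(x, ...) {
  cat(sprintf("<diploid_sample> %d sites; %d het sites; %d + %d breakpoints\n",
              length(x$genotype), sum(x$genotype == 1L),
              length(x$breakpoints$hap1), length(x$breakpoints$hap2)))
  invisible(x)
}

#' Define a clonal cell population
#'
#' Builds a clone tree with cell fractions and assigns cells to clones
#' deterministically (largest-remainder rounding), so a somatic allele placed
#' on a clone is carried by exactly the cells of that clone and its
#' descendants.
#'
#' @param n_cells Number of cells.
#' @param fractions Clone cell fractions; must be >= 0 and sum to 1 (within
#'   1e-12).
#' @param parent Integer parent pointer per clone (`NA` for roots).
#' @return A `clone_population`: list with `clones` (tibble: clone, parent,
#'   fraction, n_cells) and `cells` (tibble: cell, clone).
#' @export
clone_population <- function(n_cells, fractions = 1,
                             parent = rep(NA_integer_, length(fractions))) {
  if (any(fractions < 0)) abort("clone `fractions` must be non-negative.")
  if (abs(sum(fractions) - 1) > 1e-12) {
    abort("clone `fractions` must sum to 1 (within 1e-12).")
  }
  if (length(parent) != length(fractions)) {
    abort("`parent` must have one entry per clone.")
  }
  k <- length(fractions)
  base <- floor(fractions * n_cells)
  rem <- n_cells - sum(base)
  if (rem > 0) {
    extra <- order(fractions * n_cells - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  cells <- tibble(
    cell = sprintf("cell%05d", seq_len(n_cells)),
    clone = rep(seq_len(k), times = base)
  )
  structure(list(
    clones = tibble(clone = seq_len(k), parent = as.integer(parent),
                    fraction = fractions, n_cells = as.integer(base)),
    cells = cells
  ), class = "clone_population")
}

#' Clones descending from (and including) a clone
#' @param clones A `clone_population`.
#' @param clone Clone id.
#' @return Integer vector of clone ids.
#' @export
clone_descendants <- function(clones, clone) {
  par <- clones$clones$parent
  ids <- clones$clones$clone
  out <- clone
  repeat {
    kids <- ids[!is.na(par) & par %in% out & !(ids %in% out)]
    if (length(kids) == 0) break
    out <- c(out, kids)
  }
  sort(out)
}

#' Simulate sparse per-cell sequencing evidence
#'
#' Draws per-cell, per-site read counts from a zero-inflated Poisson depth
#' model, samples each fragment from one of the two sample haplotypes (loci
#' within `read_len` of each other in a cell share the haplotype draw of a
#' common fragment, producing short-range physical phasing), flips sampled
#' alleles with probability `error_rate`, applies whole-allele dropout per
#' cell-site, and substitutes somatic alleles on the carrier haplotype in
#' carrier cells only (gain of heterozygosity).
#'
#' @param sample A `diploid_sample`.
#' @param clones A `clone_population`.
#' @param somatic_sites Optional tibble with columns `site` (index into panel
#'   sites), `clone` (originating clone) and `haplotype` (1 or 2, the carrier
#'   haplotype). Sites must be homozygous-reference in the germline sample;
#'   placing a somatic allele on a heterozygous germline site is an error
#'   (the somatic model assumes only two alleles in the cell population).
#' @param extra_somatic Optional tibble of somatic sites at positions absent
#'   from the panel (the usual case for de novo SNVs): columns `pos`, `ref`,
#'   `alt`, `clone`, `haplotype`. These loci are homozygous reference in the
#'   germline; the alternative allele exists only on the carrier haplotype
#'   of carrier cells.
#' @param mean_depth Mean reads per cell-site (marginal, including zeros).
#' @param dropout Whole-allele dropout probability per cell-site in `[0, 1)`.
#' @param error_rate Per-read allele flip probability in `[0, 1)`.
#' @param read_len Fragment length in bp; loci closer than this share
#'   haplotype draws within a cell.
#' @param zero_inflation Extra probability mass at zero depth (expression
#'   sparsity); the Poisson rate is inflated so the marginal mean stays
#'   `mean_depth`.
#' @param base_quality,mapping_quality Centre of the simulated phred
#'   base-quality distribution and the (constant) mapping quality used when
#'   `pileup = TRUE`.
#' @param pileup If `TRUE`, also emit a read-level pooled pileup tibble
#'   (one row per read: chrom, pos, ref, alt, base, base_quality,
#'   mapping_quality, read_position, strand, mismatch_count, cell).
#' @param seed Optional integer seed.
#' @return A `sim_dataset`: list with `sites` (per-site truth and phase),
#'   `counts` (sparse tibble: site, cell, n_ref, n_alt), `cells`, `truth`
#'   (germline genotypes, somatic site list with cell fractions, per-cell
#'   carrier flags), `params`, and optionally `pileup`.
#' @export
simulate_cells <- function(sample, clones, somatic_sites = NULL,
                           mean_depth = 1, dropout = 0.1, error_rate = 0.001,
                           read_len = 100, zero_inflation = 0.3,
                           base_quality = 30, mapping_quality = 60,
                           extra_somatic = NULL, pileup = FALSE,
                           seed = NULL) {
  stopifnot(inherits(sample, "diploid_sample"),
            inherits(clones, "clone_population"))
  stopifnot_scalar_number(mean_depth, "mean_depth", 0, strict_lower = TRUE)
  stopifnot_scalar_number(dropout, "dropout", 0, 1, strict_upper = TRUE)
  stopifnot_scalar_number(error_rate, "error_rate", 0, 1, strict_upper = TRUE)
  stopifnot_scalar_number(zero_inflation, "zero_inflation", 0, 1,
                          strict_upper = TRUE)

  sites <- sample$sites %>%
    mutate(hap1 = sample$hap1, hap2 = sample$hap2, in_panel = TRUE)

  som <- somatic_sites
  if (!is.null(som)) {
    som <- as_tibble(som)
    stopifnot(all(c("site", "clone", "haplotype") %in% names(som)))
    if (any(sample$genotype[som$site] != 0L)) {
      abort(paste0("somatic sites must be homozygous-reference in the ",
                   "germline sample (only two alleles may be present in the ",
                   "cell population)."))
    }
    som$pos <- sites$pos[som$site]
  }
  if (!is.null(extra_somatic)) {
    ex <- as_tibble(extra_somatic)
    stopifnot(all(c("pos", "ref", "alt", "clone", "haplotype") %in%
                    names(ex)))
    if (any(ex$pos %in% sites$pos)) {
      abort("`extra_somatic` positions must not collide with panel sites.")
    }
    sites <- bind_rows(
      sites,
      tibble(chrom = sites$chrom[1], pos = ex$pos, ref = ex$ref,
             alt = ex$alt, hap1 = 0L, hap2 = 0L, in_panel = FALSE))
    som <- bind_rows(som,
                     ex %>% select("pos", "clone", "haplotype"))
  }
  sites <- sites %>% arrange(.data$pos)
  if (!is.null(som)) {
    som$site <- match(som$pos, sites$pos)
    if (!all(som$haplotype %in% 1:2)) abort("`haplotype` must be 1 or 2.")
  }
  pos <- sites$pos
  n_sites <- nrow(sites)
  n_cells <- nrow(clones$cells)
  a1 <- sites$hap1
  a2 <- sites$hap2

  with_seed_if(seed, {
    # Reads come from fragments of length read_len: per cell, fragment
    # starts form a Poisson process along the chromosome and each fragment
    # copies one haplotype, so loci covered by a common fragment (hence
    # closer than read_len) share its haplotype draw while distant loci are
    # sampled independently. A per-cell-site capture mask adds the
    # zero-inflation (expression sparsity); the fragment intensity is
    # inflated so the marginal per-cell-site depth mean stays mean_depth.
    lam_cov <- mean_depth / (1 - zero_inflation)
    frag_rate <- lam_cov / read_len
    lo <- min(pos) - read_len
    hi <- max(pos)
    exp_frags <- frag_rate * (hi - lo)

    n_h1 <- matrix(0L, n_sites, n_cells)
    n_h2 <- matrix(0L, n_sites, n_cells)
    for (j in seq_len(n_cells)) {
      nf <- rpois(1L, exp_frags)
      if (nf == 0L) next
      st <- sort(runif(nf, lo, hi))
      hp <- runif(nf) < 0.5 # TRUE: fragment copies haplotype 1
      cum1 <- c(0L, cumsum(hp))
      cum2 <- c(0L, cumsum(!hp))
      hi_idx <- findInterval(pos, st) + 1L
      lo_idx <- findInterval(pos - read_len, st) + 1L
      n_h1[, j] <- cum1[hi_idx] - cum1[lo_idx]
      n_h2[, j] <- cum2[hi_idx] - cum2[lo_idx]
    }
    if (zero_inflation > 0) {
      masked <- matrix(runif(n_sites * n_cells) < zero_inflation,
                       n_sites, n_cells)
      n_h1[masked] <- 0L
      n_h2[masked] <- 0L
    }

    # whole-allele dropout per cell-site
    if (dropout > 0) {
      drop_mask <- matrix(runif(n_sites * n_cells) < dropout,
                          n_sites, n_cells)
      drop_h1 <- matrix(runif(n_sites * n_cells) < 0.5, n_sites, n_cells)
      n_h1[drop_mask & drop_h1] <- 0L
      n_h2[drop_mask & !drop_h1] <- 0L
    }
    depth <- n_h1 + n_h2

    # allele carried by each haplotype per cell (somatic substitution)
    A1 <- matrix(a1, n_sites, n_cells)
    A2 <- matrix(a2, n_sites, n_cells)
    carriers <- NULL
    if (!is.null(som) && nrow(som) > 0) {
      carrier_rows <- vector("list", nrow(som))
      for (i in seq_len(nrow(som))) {
        members <- clone_descendants(clones, som$clone[i])
        is_carrier <- clones$cells$clone %in% members
        if (som$haplotype[i] == 1L) {
          A1[som$site[i], is_carrier] <- 1L
        } else {
          A2[som$site[i], is_carrier] <- 1L
        }
        carrier_rows[[i]] <- tibble(site = som$site[i],
                                    cell = clones$cells$cell[is_carrier])
      }
      carriers <- bind_rows(carrier_rows)
    }

    n_alt_true <- n_h1 * A1 + n_h2 * A2
    n_ref_true <- depth - n_alt_true

    if (error_rate > 0) {
      alt_lost <- matrix(rbinom(n_sites * n_cells, n_alt_true, error_rate),
                         n_sites, n_cells)
      ref_lost <- matrix(rbinom(n_sites * n_cells, n_ref_true, error_rate),
                         n_sites, n_cells)
      n_alt <- n_alt_true - alt_lost + ref_lost
    } else {
      n_alt <- n_alt_true
    }
    n_ref <- depth - n_alt

    idx <- which(depth > 0, arr.ind = TRUE)
    counts <- tibble(
      site = as.integer(idx[, 1]),
      cell = clones$cells$cell[idx[, 2]],
      n_ref = as.integer(n_ref[idx]),
      n_alt = as.integer(n_alt[idx])
    ) %>% arrange(.data$site, .data$cell)

    site_tbl <- sites %>%
      mutate(site = row_number(),
             genotype = a1 + a2,
             somatic = FALSE,
             carrier_hap = NA_integer_,
             somatic_clone = NA_integer_) %>%
      select("site", dplyr::everything())
    if (!is.null(som) && nrow(som) > 0) {
      site_tbl$somatic[som$site] <- TRUE
      site_tbl$carrier_hap[som$site] <- as.integer(som$haplotype)
      site_tbl$somatic_clone[som$site] <- as.integer(som$clone)
    }

    somatic_truth <- if (!is.null(som) && nrow(som) > 0) {
      som %>%
        mutate(cell_fraction = purrr::map_dbl(.data$clone, function(cc) {
          mean(clones$cells$clone %in% clone_descendants(clones, cc))
        }))
    } else {
      tibble(site = integer(), clone = integer(), haplotype = integer(),
             cell_fraction = double())
    }

    pu <- NULL
    if (pileup) {
      nr <- counts$n_ref
      na <- counts$n_alt
      tot <- nr + na
      rows <- rep.int(seq_len(nrow(counts)), tot)
      is_alt <- sequence(tot) > rep.int(nr, tot)
      n_reads <- length(rows)
      pu <- tibble(
        chrom = site_tbl$chrom[counts$site[rows]],
        pos = site_tbl$pos[counts$site[rows]],
        ref = site_tbl$ref[counts$site[rows]],
        alt = site_tbl$alt[counts$site[rows]],
        base = ifelse(is_alt, site_tbl$alt[counts$site[rows]],
                      site_tbl$ref[counts$site[rows]]),
        base_quality = pmin(40L, pmax(2L,
          as.integer(round(rnorm(n_reads, base_quality, 3))))),
        mapping_quality = as.integer(mapping_quality),
        read_position = sample.int(read_len, n_reads, replace = TRUE) - 1L,
        strand = sample(c("+", "-"), n_reads, replace = TRUE),
        mismatch_count = rpois(n_reads, 0.3),
        cell = counts$cell[rows]
      ) %>% arrange(.data$pos)
    }

    structure(list(
      sites = site_tbl,
      counts = counts,
      cells = clones$cells,
      truth = list(
        germline = site_tbl %>%
          select("site", "chrom", "pos", "ref", "alt", "genotype",
                 "hap1", "hap2"),
        somatic = somatic_truth,
        carriers = carriers %||% tibble(site = integer(), cell = character())
      ),
      params = list(mean_depth = mean_depth, dropout = dropout,
                    error_rate = error_rate, read_len = read_len,
                    zero_inflation = zero_inflation, seed = seed),
      pileup = pu
    ), class = "sim_dataset")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset> %d sites x %d cells; %d nonzero cell-site entries; %d somatic site(s)\n",
    nrow(x$sites), nrow(x$cells), nrow(x$counts), sum(x$sites$somatic)))
  invisible(x)
}
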