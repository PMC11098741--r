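# Small builders shared across test files.

make_reads <- function(pos, ref, bases, bq = 30, mq = 60, rp = NULL,
                       strand = NULL, mm = 0, cell = NULL,
                       chrom = "chr1") {
  n <- length(bases)
  tibble::tibble(
    chrom = chrom, pos = pos, ref = ref, base = bases,
    base_quality = rep_len(bq, n), mapping_quality = rep_len(mq, n),
    read_position = if (is.null(rp)) seq_len(n) * 3L else rep_len(rp, n),
    strand = if (is.null(strand)) rep_len(c("+", "-"), n)
             else rep_len(strand, n),
    mismatch_count = rep_len(mm, n),
    cell = if (is.null(cell)) sprintf("cell%02d", seq_len(n))
           else rep_len(cell, n)
  )
}

# A small simulated dataset reused by several files.
small_sim <- function(seed = 7, n_cells = 150, mean_depth = 0.6,
                      error_rate = 0.001, dropout = 0.1,
                      n_sites = 300, span = 1e4, read_len = 800) {
  panel <- simulate_panel(n_hap = 24, n_sites = n_sites, span_bp = span,
                          recomb_intensity = 1e-4, seed = seed)
  smp <- simulate_sample(panel, expected_breakpoints = 1, seed = seed + 1)
  clones <- clone_population(n_cells, c(0.3, 0.7))
  sim <- simulate_cells(smp, clones, mean_depth = mean_depth,
                        dropout = dropout, error_rate = error_rate,
                        read_len = read_len, seed = seed + 2)
  list(panel = panel, sample = smp, clones = clones, sim = sim)
}
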