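test_that("feature extraction gives BAF and neutral/zero bias statistics", {
  bases <- c(rep("A", 50), rep("G", 50))
  r <- make_reads(100L, "A", bases, rp = rep(1:25, 4),
                  cell = sprintf("c%02d", rep(1:20, 5)))
  f <- site_features(r)
  expect_equal(f$baf, 0.5)
  # identical read-position multisets on both sides: no rank-sum bias
  expect_equal(f$rpb, 0)
  # permutation invariance over reads
  f2 <- site_features(r[withr::with_seed(2, sample(nrow(r))), ])
  expect_equal(f[, c("qs", "vdb", "rpb", "bqb", "mqsb", "sgb", "baf")],
               f2[, c("qs", "vdb", "rpb", "bqb", "mqsb", "sgb", "baf")],
               tolerance = 1e-12)
})

test_that("rank-sum statistic matches hand enumeration on separated sets", {
  ref_pos <- c(10, 20, 30)
  alt_pos <- c(70, 80, 90)
  # U for the alt-vs-ref ordering is 0: every ref position below every alt
  expect_identical(unname(wilcox.test(ref_pos, alt_pos)$statistic), 0)
  # z = (U - n1 n2 / 2) / sqrt(n1 n2 (n + 1) / 12), no ties
  z_hand <- (0 - 4.5) / sqrt(3 * 3 * 7 / 12)
  expect_equal(cellsnv:::rank_sum_z(ref_pos, alt_pos), z_hand,
               tolerance = 1e-12)
  # one-sided sites impute a neutral zero
  expect_identical(cellsnv:::rank_sum_z(numeric(0), alt_pos), 0)
  r <- make_reads(55L, "A", c(rep("A", 3), rep("G", 3)),
                  rp = c(ref_pos, alt_pos))
  expect_equal(site_features(r)$rpb, z_hand, tolerance = 1e-12)
})

test_that("training sets follow the consecutive-chunk negative rule", {
  germline <- tibble::tibble(chrom = "chr1", pos = c(120e3, 130e3))
  denovo <- tibble::tibble(chrom = "chr1", pos = c(
    1e3, 2e3, 3e3,        # chunk 0: run of 3, germline-free -> negatives
    52e3, 53e3,           # chunk 1: only 2 -> test
    121e3, 122e3, 123e3, 124e3)) # chunk 2: 4 but contains germline -> test
  ts <- build_training_sets(germline, denovo, chunk_size = 5e4)
  expect_setequal(ts$negatives$pos, c(1e3, 2e3, 3e3))
  expect_setequal(ts$test$pos, c(52e3, 53e3, 121e3, 122e3, 123e3, 124e3))
  expect_identical(nrow(ts$negatives) + nrow(ts$test), nrow(denovo))
  expect_error(build_training_sets(germline[0, ], denovo), "no positive")
  expect_error(build_training_sets(germline, denovo[4:5, ]), "no negative")
})

test_that("relaxing the chunk-run requirement never shrinks the negatives", {
  withr::with_seed(10, {
    germline <- tibble::tibble(chrom = "chr1",
                               pos = sort(sample.int(1e6, 30)))
    denovo <- tibble::tibble(chrom = "chr1",
                             pos = sort(sample.int(1e6, 120)))
    n2 <- nrow(build_training_sets(germline, denovo, min_run = 2L)$negatives)
    n0 <- nrow(build_training_sets(germline, denovo, min_run = 0L)$negatives)
    expect_gte(n0, n2)
  })
})

test_that("well-separated feature clouds are classified near-perfectly", {
  withr::with_seed(4, {
    n <- 300
    make_cloud <- function(shift) {
      tibble::tibble(qs = rnorm(n, shift * 5), vdb = rnorm(n, shift * 5),
                     rpb = rnorm(n), bqb = rnorm(n), mqsb = rnorm(n),
                     sgb = rnorm(n, shift * 5),
                     baf = pmin(1, pmax(0, rnorm(n, 0.3 + 0.2 * shift, 0.05))))
    }
    pos <- make_cloud(1)
    neg <- make_cloud(0)
    train_idx <- seq_len(n / 2)
    train <- dplyr::bind_rows(pos[train_idx, ], neg[train_idx, ])
    label <- rep(c(TRUE, FALSE), each = n / 2)
    held_pos <- pos[-train_idx, ]
    out <- classify_denovo(train, label, held_pos)
    expect_gte(mean(out$retained), 0.99)
    expect_true(all(out$retained == (out$svm_prob >= 0.5)))
    # strictly-below-threshold exclusion rule
    expect_identical(c(FALSE, TRUE, TRUE),
                     c(0.49, 0.5, 0.51) >= 0.5)
  })
})

test_that("probabilities are invariant to affine rescaling of a feature", {
  withr::with_seed(5, {
    n <- 120
    feats <- tibble::tibble(
      qs = rnorm(n, rep(c(4, 0), each = n / 2)), vdb = rnorm(n),
      rpb = rnorm(n), bqb = rnorm(n), mqsb = rnorm(n),
      sgb = rnorm(n, rep(c(3, 0), each = n / 2)), baf = runif(n))
    label <- rep(c(TRUE, FALSE), each = n / 2)
    test <- feats[seq(1, n, 7), ]
    p1 <- classify_denovo(feats, label, test)$svm_prob
    scaled <- function(x) dplyr::mutate(x, qs = 1000 * qs + 17)
    p2 <- classify_denovo(scaled(feats), label, scaled(test))$svm_prob
    expect_equal(p1, p2, tolerance = 1e-8)
    # degenerate single-class training errors out
    expect_error(fit_snv_svm(feats, rep(TRUE, n)), "single-class")
  })
})
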