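test_that("GRM equals the explicit double loop of centered dot products", {
  withr::with_seed(20, {
    G <- matrix(sample(0:2, 10 * 50, TRUE), 10, 50)
    grm <- compute_grm(G)
    Gc <- scale(G, center = TRUE, scale = FALSE)
    oracle <- matrix(0, 10, 10)
    for (i in 1:10) for (j in 1:10) {
      oracle[i, j] <- sum(Gc[i, ] * Gc[j, ])
    }
    expect_equal(grm, oracle, tolerance = 1e-10, ignore_attr = TRUE)
    # symmetric positive semidefinite
    expect_equal(grm, t(grm), ignore_attr = TRUE)
    expect_gte(min(eigen(grm, symmetric = TRUE)$values), -1e-8)
  })
})

test_that("GRM handles duplicates, missingness and degenerate columns", {
  withr::with_seed(21, {
    G <- matrix(sample(0:2, 8 * 30, TRUE), 8, 30)
    G[3, ] <- G[1, ] # duplicated sample
    grm <- compute_grm(G)
    expect_equal(grm[1, ], grm[3, ], ignore_attr = TRUE)
    coords <- pca_coords(grm, 2)
    expect_equal(coords[1, ], coords[3, ], tolerance = 1e-9)
    # missing genotypes are mean-imputed; all-missing columns dropped
    G2 <- G
    G2[1, 5] <- NA
    G2[, 7] <- NA
    expect_warning(grm2 <- compute_grm(G2), "all-missing")
    expect_identical(dim(grm2), c(8L, 8L))
  })
})

test_that("leading coordinate separates two synthetic populations", {
  withr::with_seed(22, {
    f1 <- runif(80, 0.05, 0.3)
    f2 <- runif(80, 0.7, 0.95)
    draw <- function(f, n) t(replicate(n, rbinom(length(f), 2, f)))
    G <- rbind(draw(f1, 15), draw(f2, 15))
    coords <- pca_coords(compute_grm(G), 2)
    lab <- rep(1:2, each = 15)
    between <- (mean(coords[lab == 1, 1]) - mean(coords[lab == 2, 1]))^2
    within <- var(coords[lab == 1, 1]) + var(coords[lab == 2, 1])
    expect_gt(between, 4 * within)
    expect_error(pca_coords(compute_grm(G), 40), "rank")
  })
})

test_that("procrustes recovers identity and constructed transforms", {
  withr::with_seed(23, {
    Y <- matrix(rnorm(40), 20, 2)
    pr <- procrustes_project(Y, Y)
    expect_equal(pr$rho, 1, tolerance = 1e-8)
    expect_lt(pr$error, 1e-10)
    expect_equal(crossprod(pr$A), diag(2), tolerance = 1e-8)

    # reference rotated by a known orthogonal Q and scaled by 2
    th <- 0.6
    Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    Z <- 2 * Y %*% Q
    pr2 <- procrustes_project(Y, Z)
    expect_equal(pr2$rho, 0.5, tolerance = 1e-8)
    expect_equal(pr2$A, t(Q), tolerance = 1e-6)
    expect_lt(pr2$error, 1e-8)
    expect_error(procrustes_project(Y, Y[, 1, drop = FALSE]), "columns")
  })
})

test_that("procrustes objective matches a brute-force numeric minimizer", {
  withr::with_seed(24, {
    Y_ref <- matrix(rnorm(40), 20, 2)
    Y_comb <- cbind(0.8 * Y_ref + matrix(rnorm(40, sd = 0.3), 20, 2),
                    matrix(rnorm(40, sd = 0.5), 20, 2))
    pr <- procrustes_project(Y_ref, Y_comb)
    best <- oracle_procrustes_min(Y_ref, Y_comb)
    expect_lt(abs(pr$error - best), 1e-6)
    # objective never increases when K' grows over nested coordinates
    objs <- vapply(2:4, function(kp) {
      procrustes_project(Y_ref, Y_comb[, seq_len(kp), drop = FALSE])$error
    }, numeric(1))
    expect_true(all(diff(objs) <= 1e-9))
  })
})

test_that("reference samples project onto their own coordinates", {
  withr::with_seed(25, {
    f1 <- runif(120, 0.05, 0.4)
    f2 <- runif(120, 0.6, 0.95)
    draw <- function(f, n) t(replicate(n, rbinom(length(f), 2, f)))
    R <- rbind(draw(f1, 12), draw(f2, 12))
    Y_ref <- pca_coords(compute_grm(R), 2)
    spread <- sqrt(mean(rowSums(Y_ref^2)))
    for (i in c(2, 20)) {
      pr <- project_ancestry(R, R[i, ], K = 2, Kprime = 4)
      expect_lt(sqrt(sum((pr$y - Y_ref[i, ])^2)), 0.15 * spread)
    }
  })
})
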