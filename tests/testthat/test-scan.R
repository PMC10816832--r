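test_that("effective marker number follows the eigenvalue-share rule", {
  # duplicated columns of a single marker: rank 1
  g <- sample(c(0L, 1L, 2L), 30, TRUE)
  dup <- toy_mm(matrix(rep(g, 5), ncol = 5))
  expect_equal(effective_marker_number(dup), 1L)
  expect_equal(effective_marker_number(dup, variance_fraction = 1), 1L)

  # variance_fraction = 1 returns the rank
  set.seed(8)
  calls <- matrix(sample(c(0L, 1L, 2L), 40 * 10, TRUE), ncol = 10)
  m <- toy_mm(calls)
  Xs <- scale(calls)
  expect_equal(effective_marker_number(m, variance_fraction = 1),
               as.integer(qr(Xs)$rank))

  # 200 mutually independent markers, large n: Me = ceiling(0.995 * 200)
  set.seed(9)
  big <- matrix(sample(c(0L, 1L, 2L), 5000 * 200, TRUE,
                       prob = c(0.25, 0.5, 0.25)), ncol = 200)
  mb <- toy_mm(big)
  expect_equal(effective_marker_number(mb), 199L)

  expect_error(effective_marker_number(dup, variance_fraction = 0), "fraction")
  expect_error(effective_marker_number(dup, variance_fraction = 1.2),
               "fraction")
})

test_that("significance thresholds implement the Me-based Bonferroni rule", {
  expect_equal(significance_threshold(100, 0.05, "main"),
               -log10(0.05 / 100))
  expect_equal(significance_threshold(100, 0.05, "pairwise"),
               -log10(0.05 / (100 * 99 / 2)))
  expect_error(significance_threshold(1, 0.05, "pairwise"), "Me >= 2")
  expect_error(significance_threshold(100, 0, "main"), "alpha")
})

test_that("single-kinship REML matches the eigen-decomposition closed form", {
  stu <- small_study(seed = 23, n_a = 8, n_b = 12, n_markers = 150,
                     n_hybrids = 50, h2 = 0.5, n_add = 0, n_dom = 0,
                     n_epi = 0, polygenic_share = 0.99)
  y <- stu$phenotypes$value
  K <- build_kinships(stu$hybrids)
  fit <- fit_null_reml(y, K, model = "KinA")
  expect_true(fit$converged)
  oracle <- reml_single_oracle(y, K$Ka)
  expect_equal(fit$loglik, oracle$ll, tolerance = 1e-6)
  expect_equal(unname(fit$sigma2["a"]), oracle$sa2, tolerance = 1e-3)
  expect_equal(unname(fit$sigma2["e"]), oracle$se2, tolerance = 1e-3)
})

test_that("an identity additive kinship is flagged as unidentifiable", {
  stu <- small_study(seed = 29, n_markers = 60, n_hybrids = 30)
  K <- build_kinships(stu$hybrids)
  n <- length(stu$phenotypes$value)
  K$Ka <- diag(n)
  dimnames(K$Ka) <- list(stu$hybrids$samples$id, stu$hybrids$samples$id)
  expect_warning(fit_null_reml(stu$phenotypes$value, K, model = "KinA"),
                 "identity")
})

test_that("KinADE REML recovers simulated variance components on average", {
  # centered codings keep the six kinships distinguishable; the raw coding
  # makes Ka and Kaa nearly collinear and only their sum identifiable
  stu <- small_study(seed = 37, n_a = 12, n_b = 25, n_markers = 250,
                     n_hybrids = 250)
  K <- build_kinships(stu$hybrids, center = TRUE)
  n <- nrow(K$Ka)
  truth <- c(a = 1, d = 0.8, aa = 0.6, e = 1)
  chol_a <- chol(K$Ka + diag(1e-8, n))
  chol_d <- chol(K$Kd + diag(1e-8, n))
  chol_aa <- chol(K$Kaa + diag(1e-8, n))
  R <- 10
  est <- matrix(NA_real_, R, 7,
                dimnames = list(NULL, c("a", "d", "aa", "ad", "da", "dd",
                                        "e")))
  set.seed(101)
  for (r in seq_len(R)) {
    y <- sqrt(truth["a"]) * as.vector(crossprod(chol_a, rnorm(n))) +
      sqrt(truth["d"]) * as.vector(crossprod(chol_d, rnorm(n))) +
      sqrt(truth["aa"]) * as.vector(crossprod(chol_aa, rnorm(n))) +
      rnorm(n, sd = sqrt(truth["e"]))
    fit <- suppressWarnings(fit_null_reml(y, K, model = "KinADE"))
    est[r, ] <- fit$sigma2[colnames(est)]
  }
  for (cn in c("a", "d")) {
    mc_se <- sd(est[, cn]) / sqrt(R)
    expect_lt(abs(mean(est[, cn]) - truth[cn]), 3 * mc_se + 0.05)
  }
  # the near-diagonal epistatic kinships trade off against the residual;
  # their joint variance is the identifiable quantity
  epi_res <- rowSums(est[, c("aa", "ad", "da", "dd", "e")])
  mc_se <- sd(epi_res) / sqrt(R)
  expect_lt(abs(mean(epi_res) - (truth["aa"] + truth["e"])),
            3 * mc_se + 0.1)
})

test_that("the P3D scan reduces to ordinary regression when V is diagonal", {
  set.seed(55)
  n <- 30
  calls <- matrix(sample(c(0L, 1L, 2L), n * 8, TRUE), ncol = 8)
  calls[, 1] <- rep(c(0L, 1L, 2L), each = 10)        # guaranteed 3 classes
  m <- toy_mm(calls)
  y <- rnorm(n) + 0.8 * (calls[, 1] - 1)
  null <- null_fit_fixed(y, V = diag(2.37, n))
  scan <- suppressMessages(scan_main_effects(y, m, null))
  Z <- calls - 1; W <- (calls == 1) * 1
  for (j in which(scan$classes == 3)) {
    ols <- summary(lm(y ~ Z[, j] + W[, j]))$coefficients
    expect_equal(scan$a_hat[j], ols[2, 1], tolerance = 1e-8)
    expect_equal(scan$d_hat[j], ols[3, 1], tolerance = 1e-8)
    expect_equal(10^(-scan$logp_add[j]), ols[2, 4], tolerance = 1e-8)
    expect_equal(10^(-scan$logp_dom[j]), ols[3, 4], tolerance = 1e-8)
  }
})

test_that("scan handles additive loci, confounded loci and monomorphic loci", {
  set.seed(66)
  n <- 90
  calls <- cbind(rep(c(0L, 1L, 2L), each = n / 3),     # balanced additive
                 rep(c(0L, 1L), length.out = n),       # two classes
                 rep(1L, n),                           # monomorphic (all het)
                 matrix(sample(c(0L, 1L, 2L), n * 3, TRUE), ncol = 3))
  m <- toy_mm(calls)
  # symmetric homozygote means around the heterozygote: pure additivity
  y <- (calls[, 1] - 1) * 2 + rnorm(n, sd = 0.3)
  null <- null_fit_fixed(y)
  scan <- suppressMessages(scan_main_effects(y, m, null, threshold = 3))
  expect_equal(scan$mode[1], "Add")
  expect_lt(abs(scan$d_hat[1]), 0.3)
  expect_equal(scan$a_hat[1], 2, tolerance = 0.15)
  expect_equal(scan$mode[2], "Add/Dom")
  expect_equal(scan$reason[2], "one_homozygote_missing")
  expect_true(is.na(scan$logp[3]))
  expect_equal(attr(scan, "skipped"), "m003")
  # PVE bounded and positive where fitted
  expect_true(all(scan$pve[!is.na(scan$pve)] >= 0))
  expect_true(all(scan$pve[!is.na(scan$pve)] <= 100))
})

test_that("mode labels follow the significance pattern", {
  base <- data.frame(marker = c("a", "b", "c", "d"), chrom = "chr1",
                     pos = 1:4, n0 = 5, n1 = 5, n2 = 5, classes = 3L,
                     a_hat = 1, d_hat = 1, effect = NA_real_,
                     logp_add = c(5, 1, 6, 1), logp_dom = c(1, 5, 6, 1),
                     logp = c(5, 5, 6, 1), pve = 5, mode = NA_character_,
                     reason = NA_character_, stringsAsFactors = FALSE)
  class(base) <- c("scan_result", "data.frame")
  out <- classify_mode(base, threshold = 3.95)
  expect_equal(out$mode, c("Add", "Dom", "Add/Dom", "NS"))
  expect_equal(out$reason[3], "both_significant")
})

test_that("epistasis scan enumerates all pairs and matches brute force", {
  set.seed(77)
  n <- 60
  calls <- matrix(sample(c(0L, 1L, 2L), n * 10, TRUE), ncol = 10)
  m <- toy_mm(calls)
  y <- rnorm(n)
  null <- null_fit_fixed(y, V = diag(1, n))
  res <- scan_epistasis(y, m, null, candidates = 1:10, types = "aa")
  expect_equal(attr(res, "n_pairs"), 45L)
  skipped <- attr(res, "skipped")
  expect_equal(nrow(res) + if (is.null(skipped)) 0 else nrow(skipped), 45L)

  Z <- calls - 1; W <- (calls == 1) * 1
  for (r in sample(nrow(res), 8)) {
    i <- match(res$marker_i[r], m$map$marker)
    j <- match(res$marker_j[r], m$map$marker)
    mains <- cbind(Z[, i], W[, i], Z[, j], W[, j])
    mains <- mains[, apply(mains, 2, sd) > 0, drop = FALSE]
    inter <- Z[, i] * Z[, j]
    ols <- summary(lm(y ~ mains + inter))$coefficients
    expect_equal(res$alpha_hat[r], ols["inter", 1], tolerance = 1e-8)
    expect_equal(10^(-res$logp[r]), ols["inter", 4], tolerance = 1e-8)
  }
})

test_that("inestimable interaction types are skipped, simulated aa is found", {
  n <- 120
  set.seed(88)
  # marker 2 has no heterozygotes: every *d/dd interaction with it is constant
  calls <- cbind(sample(c(0L, 1L, 2L), n, TRUE),
                 sample(c(0L, 2L), n, TRUE),
                 sample(c(0L, 1L, 2L), n, TRUE))
  m <- toy_mm(calls)
  Z <- calls - 1
  y <- 1.5 * Z[, 1] * Z[, 3] + rnorm(n)
  null <- null_fit_fixed(y)
  res <- scan_epistasis(y, m, null, candidates = 1:3)
  skipped <- attr(res, "skipped")
  expect_true(all(c("ad", "dd") %in%
                    skipped$type[skipped$marker_i == "m001" &
                                   skipped$marker_j == "m002"]))
  # the simulated aa pair dominates its own main effects
  aa13 <- res[res$marker_i == "m001" & res$marker_j == "m003" &
                res$type == "aa", ]
  expect_equal(nrow(aa13), 1)
  expect_gt(aa13$logp, 5)
  scan1 <- suppressMessages(scan_main_effects(y, m, null))
  expect_gt(aa13$logp, max(scan1$logp, na.rm = TRUE))
})

test_that("PVE is the variance share of the fitted term", {
  set.seed(3)
  Mcol <- rnorm(50)
  y <- Mcol * 2
  expect_equal(compute_pve(y, Mcol, 2), 100)
  expect_equal(compute_pve(y, Mcol, 0), 0)
  expect_error(compute_pve(rep(1, 50), Mcol, 1), "zero variance")
})

test_that("LD clumping keeps lead markers and screens on PVE", {
  set.seed(12)
  n <- 80
  g1 <- sample(c(0L, 1L, 2L), n, TRUE)
  g2 <- g1; flip <- sample(n, 4); g2[flip] <- sample(c(0L, 1L, 2L), 4, TRUE)
  g3 <- sample(c(0L, 1L, 2L), n, TRUE)
  m <- toy_mm(cbind(g1, g2, g3), pos = c(10000L, 20000L, 520000L))
  expect_gt(cor(g1, g2)^2, 0.2)
  sr <- data.frame(marker = c("m001", "m002", "m003"), chrom = "chr1",
                   pos = c(10000L, 20000L, 520000L), n0 = 1, n1 = 1, n2 = 1,
                   classes = 3L, a_hat = 1, d_hat = 0, effect = 1,
                   logp_add = c(6, 8, 5), logp_dom = 0,
                   logp = c(6, 8, 5), pve = c(4, 5, 6),
                   mode = "Add", reason = "additive_only",
                   stringsAsFactors = FALSE)
  class(sr) <- c("scan_result", "data.frame")
  out <- clump_significant(sr, m, threshold = 3.95)
  expect_setequal(out$marker, c("m002", "m003"))   # m001 clumped into m002

  # markers far apart are both retained regardless of correlation
  m_far <- toy_mm(cbind(g1, g2), pos = c(10000L, 520000L))
  sr2 <- sr[1:2, ]; sr2$pos <- c(10000L, 520000L)
  class(sr2) <- c("scan_result", "data.frame")
  out2 <- clump_significant(sr2, m_far, threshold = 3.95)
  expect_equal(nrow(out2), 2)

  # the PVE >= 1% screen drops weak leads
  sr3 <- sr; sr3$pve <- c(4, 0.8, 6)
  class(sr3) <- c("scan_result", "data.frame")
  out3 <- clump_significant(sr3, m, threshold = 3.95)
  expect_false("m002" %in% out3$marker)
})

test_that("cross-validation is seed-reproducible and near zero on noise", {
  stu <- small_study(seed = 41, n_markers = 80, n_hybrids = 60)
  K <- build_kinships(stu$hybrids)
  set.seed(999)
  y <- rnorm(60)
  cv1 <- crossvalidate_models(y, K, folds = 5, repeats = 3, seed = 7,
                              models = "KinA")
  cv2 <- crossvalidate_models(y, K, folds = 5, repeats = 3, seed = 7,
                              models = "KinA")
  expect_identical(cv1, cv2)
  expect_lt(cv1$summary$mean_pve, 15)
  expect_error(crossvalidate_models(y[1:8], subset_kinships(K, 1:8),
                                    folds = 5, repeats = 1), "< 2 samples")
})
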