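test_that("favorable genotype calls respect direction and overdominance", {
  cm <- data.frame(marker = rep(c("q1", "q2"), each = 3),
                   class = rep(0:2, 2),
                   mean = c(9, 10, 11,      # additive
                            9, 12, 10),     # overdominant
                   n = 10)
  hi <- favorable_genotypes(cm, "higher_better")
  expect_equal(hi$favorable_class[hi$marker == "q1"], 2)
  expect_equal(hi$favorable_class[hi$marker == "q2"], 1)  # heterozygote wins
  lo <- favorable_genotypes(cm, "lower_better")
  expect_equal(lo$favorable_class[lo$marker == "q1"], 0)
  # trait-name lookup through the direction table
  gm <- favorable_genotypes(cm, "GM")
  expect_equal(gm$direction[1], "lower_better")
  expect_error(favorable_genotypes(cm, "NOT_A_TRAIT"), "direction")
})

test_that("accumulation regression behaves like ordinary least squares", {
  stu <- small_study(seed = 51, n_markers = 100, n_hybrids = 80)
  h <- stu$hybrids
  qtns <- which(apply(h$calls, 2, function(g) all(c(0, 1, 2) %in% g)))[1:5]
  fav <- data.frame(marker = h$map$marker[qtns], favorable_class = 2,
                    direction = "higher_better")
  class(fav) <- c("favorable_call", "data.frame")
  counts <- favorable_counts(h, fav)

  # phenotype equal to the count: perfect fit
  fit <- suppressWarnings(accumulation_regression(as.numeric(counts), h, fav))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 1)

  # R^2 invariant to affine phenotype rescaling
  fit2 <- suppressWarnings(
    accumulation_regression(3 * as.numeric(counts) + 7, h, fav))
  expect_equal(fit2$r_squared, 1)
  expect_equal(fit2$slope, 3)

  # permuted phenotype: no association
  set.seed(1)
  r2 <- p <- numeric(20)
  for (r in 1:20) {
    yp <- sample(as.numeric(counts))
    f <- accumulation_regression(yp, h, fav)
    r2[r] <- f$r_squared; p[r] <- f$p_value
  }
  expect_lt(mean(r2), 0.08)
  expect_gt(mean(p > 0.05), 0.7)

  # simulated additive architecture: slope sign matches direction
  j <- qtns[1]
  arch <- trait_architecture(additive = data.frame(marker = j, effect = 1.5),
                             heritability = 0.9, polygenic_share = 0,
                             seed = 3)
  ph <- simulate_phenotypes(h, arch)
  cmj <- genotype_class_means(ph$phenotypes$value, h, j)
  favj <- favorable_genotypes(cmj, "higher_better")
  fitj <- accumulation_regression(ph$phenotypes$value, h, favj)
  expect_gt(fitj$slope, 0)
  expect_lt(fitj$p_value, 0.001)

  expect_error(accumulation_regression(rnorm(80), h,
                                       transform(fav, favorable_class = 3)),
               "no variance")
})

test_that("group allele frequencies match a hand tally", {
  parents <- toy_mm(rbind(A1 = c(0L, 2L, 0L),
                          A2 = c(2L, 2L, 0L),
                          B1 = c(0L, 0L, 0L),
                          B2 = c(0L, 2L, 0L),
                          B3 = c(2L, NA, 0L)),
                    group = c("A", "A", "B", "B", "B"))
  gf <- group_allele_frequencies(parents)
  expect_equal(gf$freq_alt_a, c(2/4, 4/4, 0))
  expect_equal(gf$freq_alt_b, c(2/6, 2/4, 0))   # missing call excluded
  # allele present only in group A: group-B frequency 0
  expect_equal(gf$freq_alt_b[3], 0)
  # monomorphic marker: frequency 0/1 in both groups, PIC-style labels fixed
  expect_equal(gf$major_allele[3], "A")
  no_b <- toy_mm(matrix(0L, 2, 2), group = c("A", "A"))
  expect_error(group_allele_frequencies(no_b), "group-B")
})

test_that("TOP/BOT enrichment detects and rejects appropriately", {
  # phenotype equal to the count: strong separation
  set.seed(2)
  counts <- rpois(100, 20)
  y <- as.numeric(counts)
  tb <- top_bottom_enrichment(y, counts, fraction = 0.10)
  expect_equal(tb$n, c(10, 10))
  expect_gt(tb$mean_count[tb$group == "TOP"],
            tb$mean_count[tb$group == "BOT"])
  expect_lt(tb$p_value[1], 1e-3)

  # fraction 0.5 on 10 hybrids: two tails of 5
  tb5 <- top_bottom_enrichment(rnorm(10), rpois(10, 5), fraction = 0.5)
  expect_equal(tb5$n, c(5, 5))
  expect_error(top_bottom_enrichment(rnorm(10), rpois(10, 5), 0.1), "< 3")

  # independent phenotype: mostly non-significant over 50 simulations
  set.seed(3)
  hits <- vapply(1:50, function(r) {
    tb <- top_bottom_enrichment(rnorm(100), rpois(100, 20), 0.10)
    tb$p_value[1] < 0.05
  }, logical(1))
  expect_lt(mean(hits), 0.3)
})

test_that("OGMS counting equals brute-force enumeration", {
  # worked example: A testers fixed hom REF, B testers segregate both homs
  parents <- toy_mm(rbind(A1 = c(0L, 0L), A2 = c(0L, 2L),
                          B1 = c(0L, 0L), B2 = c(2L, 2L)),
                    group = c("A", "A", "B", "B"))
  res <- count_ogms(parents, testers_a = c("A1"), testers_b = c("B1", "B2"))
  expect_true(res$flags[["m001"]])    # classes {hom REF, het}
  res2 <- count_ogms(parents, testers_a = c("A1", "A2"),
                     testers_b = c("B1", "B2"))
  expect_false(res2$flags[["m002"]])  # both groups segregate: all 3 classes

  # 50-marker toy against an independent enumeration
  set.seed(7)
  f <- simulate_founders(founder_panel_spec(n_group_a = 5, n_group_b = 6,
                                            n_markers = 50, seed = 7))
  ta <- f$samples$id[1:3]
  tb <- f$samples$id[6:9]
  got <- count_ogms(f, ta, tb)
  brute <- vapply(seq_len(50), function(j) {
    cls <- integer(0)
    for (a in ta) for (b in tb) {
      ga <- f$calls[a, j]; gb <- f$calls[b, j]
      if (is.na(ga) || is.na(gb) || ga == 1L || gb == 1L) next
      cls <- union(cls, (ga + gb) %/% 2L)
    }
    length(cls) == 2 && 1L %in% cls
  }, logical(1))
  expect_equal(unname(got$flags), brute)
  expect_equal(got$total, sum(brute))

  # invariant to sample order (marker identity is carried by the named flags)
  perm_s <- sample(11)
  fp <- marker_matrix(f$calls[perm_s, ], f$map, f$samples[perm_s, ])
  got_p <- count_ogms(fp, ta, tb)
  expect_equal(got_p$total, got$total)
  expect_equal(got_p$flags, got$flags)
  expect_error(count_ogms(f, character(0), tb), "empty tester set")
})

test_that("mating-strategy comparison reduces OGMS burden with seed safety", {
  # identity strategy: zero percent decrease by construction
  f <- simulate_founders(founder_panel_spec(n_group_a = 20, n_group_b = 30,
                                            n_markers = 120, seed = 9))
  ta <- f$samples$id[1:4]
  tb <- f$samples$id[21:25]
  rep1 <- compare_mating_strategies(f, ta, tb, multipliers = 1,
                                    n_resamples = 5, seed = 1)
  expect_equal(rep1$strategies$pct_decrease, 0)
  expect_equal(rep1$strategies$median_ogms, rep1$baseline)

  rep2 <- compare_mating_strategies(f, ta, tb, multipliers = c(2, 3),
                                    n_resamples = 10, seed = 2)
  rep2b <- compare_mating_strategies(f, ta, tb, multipliers = c(2, 3),
                                     n_resamples = 10, seed = 2)
  expect_identical(rep2$strategies, rep2b$strategies)   # reproducible
  # medians lie within the per-resample range
  for (k in c(2, 3)) {
    rs <- rep2$resamples$ogms[rep2$resamples$multiplier == k]
    med <- rep2$strategies$median_ogms[rep2$strategies$multiplier == k]
    expect_gte(med, min(rs)); expect_lte(med, max(rs))
  }
  expect_error(compare_mating_strategies(f, f$samples$id[1:15], tb,
                                         multipliers = 2, n_resamples = 2),
               "not enough")

  # median OGMS non-increasing in the multiplier, averaged over 20 seeds
  meds <- matrix(NA_real_, 20, 3)
  for (s in 1:20) {
    fs <- simulate_founders(founder_panel_spec(n_group_a = 12, n_group_b = 18,
                                               n_markers = 60, seed = 100 + s))
    ta_s <- fs$samples$id[1:3]
    tb_s <- fs$samples$id[13:16]
    rp <- compare_mating_strategies(fs, ta_s, tb_s, multipliers = c(1, 2, 3),
                                    n_resamples = 8, seed = s)
    meds[s, ] <- rp$strategies$median_ogms
  }
  avg <- colMeans(meds)
  expect_true(all(diff(avg) <= 0))
})

test_that("tester subsetting filters the design like a brute-force match", {
  f <- simulate_founders(founder_panel_spec(n_group_a = 4, n_group_b = 5,
                                            n_markers = 10, seed = 3))
  d <- simulate_cross_design(f, mode = "full_factorial")
  all_back <- subset_by_testers(d, f$samples$id[1:4], f$samples$id[5:9])
  expect_equal(nrow(all_back), nrow(d))
  expect_warning(subset_by_testers(d, "A001", "B999"), "no hybrids")

  ta <- f$samples$id[1:3]; tb <- f$samples$id[5:7]
  sub <- subset_by_testers(d, ta, tb)
  brute <- d[d$parent_a %in% ta & d$parent_b %in% tb, ]
  expect_equal(sub$hybrid, brute$hybrid)
  expect_equal(nrow(sub), 9)
})
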