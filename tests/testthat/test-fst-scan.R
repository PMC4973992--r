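test_that("variance components match the brute-force balanced ANOVA oracle", {
  des <- balanced_design(2)   # 2 lines x 2 reps x 2 samples, printed table
  dos <- matrix(c(2L, 2L, 2L, 1L, 0L, 0L, 1L, 0L,   # differentiated locus
                  1L, 0L, 2L, 1L, 1L, 2L, 0L, 1L,   # noisy locus
                  1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L,   # all heterozygous
                  2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L),  # monomorphic
                nrow = 8, dimnames = list(des$sample, NULL))
  g <- toy_genotypes(dos, des)
  comp <- locus_variance_components(g)
  oracle <- brute_force_components(g$dosage, des)
  for (col in colnames(oracle))
    expect_equal(comp[[col]][1:3], unname(oracle[1:3, col]), tolerance = 1e-12)
  # monomorphic locus: all components zero, theta undefined
  expect_equal(unlist(comp[4, c("sigma_L", "sigma_RL", "sigma_SRL", "sigma_G")]),
               c(sigma_L = 0, sigma_RL = 0, sigma_SRL = 0, sigma_G = 0))
  expect_true(is.na(comp$theta[4]))
})

test_that("oracle agreement holds across random balanced datasets", {
  set.seed(5)
  for (n in c(3L, 10L)) {
    des <- balanced_design(n)
    dos <- matrix(rbinom(4 * n * 12, 2, runif(12, 0.2, 0.8)[rep(1:12, each = 4 * n)]),
                  nrow = 4 * n, dimnames = list(des$sample, NULL))
    g <- toy_genotypes(dos, des)
    comp <- locus_variance_components(g)
    oracle <- brute_force_components(g$dosage, des)
    for (col in colnames(oracle))
      expect_equal(comp[[col]], unname(oracle[, col]), tolerance = 1e-10)
  }
})

test_that("divergent fixation gives theta = 1 with all noise components zero", {
  des <- balanced_design(4)
  dos <- matrix(ifelse(des$line == "high", 2L, 0L), nrow(des), 3,
                dimnames = list(des$sample, NULL))
  g <- toy_genotypes(dos, des)
  comp <- locus_variance_components(g)
  expect_true(all(comp$sigma_L > 0))
  expect_equal(comp$sigma_RL, rep(0, 3))
  expect_equal(comp$sigma_SRL, rep(0, 3))
  expect_equal(comp$sigma_G, rep(0, 3))
  expect_equal(comp$theta, rep(1, 3))
})

test_that("missing calls reduce to the complete-case sub-design", {
  set.seed(8)
  des <- balanced_design(4)
  dos <- matrix(rbinom(16 * 5, 2, 0.5), 16, dimnames = list(des$sample, NULL))
  g_full <- toy_genotypes(dos, des)
  dos_na <- dos; dos_na[3, ] <- NA
  g_na <- toy_genotypes(dos_na, des)
  # dropping the sample entirely must give the same components
  des_red <- study_design(des$sample[-3], des$line[-3], des$replicate[-3])
  g_red <- toy_genotypes(dos[-3, , drop = FALSE], des_red)
  expect_equal(locus_variance_components(g_na)$sigma_L,
               locus_variance_components(g_red)$sigma_L, tolerance = 1e-12)
  expect_equal(locus_variance_components(g_na)$denom,
               locus_variance_components(g_red)$denom, tolerance = 1e-12)
})

test_that("windowed theta is a ratio of sums with exact w = 1 identity", {
  comp <- data.frame(chrom = "chr1", pos = (1:9) * 100L,
                     id = paste0("l", 1:9),
                     sigma_L = c(rep(0.02, 4), 0.5, rep(0.02, 4)),
                     sigma_RL = 0.05, sigma_SRL = 0.05,
                     sigma_G = rep(0.38, 9))
  comp$denom <- comp$sigma_L + comp$sigma_RL + comp$sigma_SRL + comp$sigma_G
  comp$theta <- comp$sigma_L / comp$denom
  class(comp) <- c("locus_components", "data.frame")
  t1 <- windowed_theta(comp, 1L)
  expect_equal(t1$theta, comp$theta)                 # identity case
  t3 <- windowed_theta(comp, 3L)
  expect_equal(nrow(t3), 7L)                         # ends unscored
  # uniform components: windowed equals single-locus value
  expect_equal(t3$theta[1], comp$theta[1])
  # a strong locus flanked by neutral ones: strictly between the extremes
  mid <- t3$theta[t3$pos == 500]
  expect_gt(mid, comp$theta[1])
  expect_lt(mid, comp$theta[5])
  # ratio-of-sums, not mean-of-ratios
  expect_equal(mid, sum(comp$sigma_L[4:6]) / sum(comp$denom[4:6]))
  expect_error(windowed_theta(comp, 4L), "odd")
})

test_that("the compiled kernel reproduces the R components path exactly", {
  res <- small_sim(seed = 19, loci = 40, n_chrom = 2)
  g <- res$sim$genotypes
  comp <- locus_variance_components(g)
  pi <- thetascan:::perm_inputs(g, g$design)
  ec <- pi$ec
  parts <- thetascan:::observed_theta_parts_core(
    pi$Y, ec$samp - 1L, ec$cell_of_samp - 1L, ec$line_of_cell - 1L,
    as.numeric(table(ec$samp)),
    as.numeric(table(ec$cell_of_samp[ec$samp])),
    as.numeric(table(ec$line_of_cell[ec$cell_of_samp[ec$samp]])),
    as.numeric(ec$df), as.numeric(ec$coef))
  keep <- pi$keep
  expect_equal(unname(parts[1, ]), comp$sigma_L[keep], tolerance = 1e-12)
  expect_equal(unname(parts[2, ]), comp$denom[keep], tolerance = 1e-12)
})

test_that("sampled permutations match the exhaustive oracle on 8 gametes", {
  des <- study_design(c("h1", "h2", "l1", "l2"), c("high", "high", "low", "low"),
                      c(1, 2, 1, 2))
  set.seed(2)
  dos <- matrix(c(2L, 1L, 0L, 1L, 1L, 2L, 0L, 0L, 0L, 1L, 2L, 1L), 4,
                dimnames = list(des$sample, NULL))
  g <- toy_genotypes(dos, des)
  exact <- exhaustive_gamete_maxima(g, w = 1L)        # all 2520 assignments
  pr <- genome_permutation_threshold(g, w = 1L, n_permutations = 4000L,
                                     gwp = 0.5, mode = "gamete", seed = 6)
  sampled <- pr$maxima$gamete
  # sampled maxima live on the exhaustive support
  expect_true(all(vapply(sampled, function(v)
    any(abs(v - exact) < 1e-9), logical(1))))
  # and the two distributions agree (ECDF sup-distance, DKW ~ 0.03)
  qs <- sort(unique(exact))
  F_ex <- vapply(qs, function(q) mean(exact <= q + 1e-12), numeric(1))
  F_sa <- vapply(qs, function(q) mean(sampled <= q + 1e-12), numeric(1))
  expect_lt(max(abs(F_ex - F_sa)), 0.05)
})

test_that("individual-mode permutations preserve gamete pairs", {
  des <- study_design(c("h1", "h2", "l1", "l2"), c("high", "high", "low", "low"),
                      c(1, 2, 1, 2))
  dos <- matrix(c(2L, 1L, 0L, 1L, 1L, 2L, 0L, 0L), 4,
                dimnames = list(des$sample, NULL))
  g <- toy_genotypes(dos, des)
  # exhaustive individual-level null: all 4! assignments of samples to slots
  perms <- all_permutations(4)
  exact <- apply(perms, 1, function(ord) {
    d <- g$dosage[ord, , drop = FALSE]
    rownames(d) <- des$sample
    g2 <- genotype_matrix(d, g$map, des)
    max(windowed_theta(locus_variance_components(g2), 1L)$theta, na.rm = TRUE)
  })
  pr <- genome_permutation_threshold(g, w = 1L, n_permutations = 2000L,
                                     gwp = 0.5, mode = "individual", seed = 3)
  expect_true(all(vapply(pr$maxima$individual, function(v)
    any(abs(v - exact) < 1e-9), logical(1))))
  expect_equal(mean(pr$maxima$individual), mean(exact), tolerance = 0.05)
})

test_that("permutation p-values are uniform under an exchangeable null", {
  # samples drawn iid from one population (no drift between cells):
  # the permutation null is exact here, so the observed genome maximum is
  # a uniform draw among the permutation maxima
  set.seed(14)
  des <- balanced_design(5)
  pvals <- replicate(40, {
    dos <- matrix(rbinom(20 * 30, 2, 0.5), 20,
                  dimnames = list(des$sample, NULL))
    g <- toy_genotypes(dos, des)
    obs <- max(windowed_theta(locus_variance_components(g), 3L)$theta,
               na.rm = TRUE)
    pr <- genome_permutation_threshold(g, w = 3L, n_permutations = 200L,
                                       gwp = 0.5, mode = "gamete",
                                       seed = sample.int(1e6, 1))
    (1 + sum(pr$maxima$gamete >= obs)) / 201
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("signature calls are strict, sorted and threshold-aware", {
  tr <- structure(data.frame(chrom = c("chr2", "chr1", "chr1"),
                             pos = c(50L, 300L, 100L),
                             id = c("a", "b", "c"),
                             theta = c(0.9, 0.4, 0.8)),
                  class = c("theta_track", "data.frame"), w = 1L)
  sig <- call_signatures(tr, 0.5)
  expect_equal(sig$id, c("c", "a"))                  # sorted by chrom, pos
  expect_equal(nrow(call_signatures(tr, 0.9)), 0L)   # strict: 0.9 not > 0.9
  expect_equal(call_signatures(tr, 0.8)$id, "a")     # 0.8 itself excluded
  expect_equal(nrow(call_signatures(tr[0, ], 0.5)), 0L)
  expect_equal(nrow(call_signatures(tr, 2)), 0L)
  expect_error(call_signatures(tr, Inf), "finite")
})

test_that("pairwise Fst summary hits the exact endpoints", {
  map <- data.frame(chrom = "chr1", pos = (1:4) * 10L)
  cells <- data.frame(line = rep(c("high", "low"), each = 2),
                      replicate = rep(1:2, 2))
  same <- frequency_table(matrix(0.4, 4, 4), matrix(50, 4, 4), cells, map)
  expect_equal(pairwise_fst_summary(same)$fst, rep(0, 3))
  div <- frequency_table(rbind(matrix(1, 2, 4), matrix(0, 2, 4)),
                         matrix(50, 4, 4), cells, map)
  expect_equal(pairwise_fst_summary(div)$fst, rep(1, 3))
})

test_that("across-replicate Fst falls below within-replicate Fst under drift", {
  wins <- vapply(1:8, function(s) {
    res <- small_sim(seed = 400 + s, loci = 120, n_chrom = 1,
                     gens_sel = 0, gens_total = 15)
    fst <- pairwise_fst_summary(estimate_allele_frequency(res$sim$reads))
    fst$fst[3] < mean(fst$fst[1:2])
  }, logical(1))
  expect_gte(sum(wins), 7)
})

test_that("theta stays at most 1 and windows skip unusable loci", {
  res <- small_sim(seed = 27, loci = 100, n_chrom = 1)
  comp <- locus_variance_components(res$sim$genotypes)
  tr <- windowed_theta(comp, 7L)
  expect_true(all(tr$theta <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(!is.na(tr$theta)))
})
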