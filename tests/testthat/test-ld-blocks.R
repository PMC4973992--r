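test_that("r_squared matches hand arithmetic and edge cases", {
  expect_equal(r_squared(gamete_table(c(0.5, 0, 0, 0.5))), 1)
  expect_equal(r_squared(gamete_table(c(0.25, 0.25, 0.25, 0.25))), 0)
  t3 <- gamete_table(c(0.4, 0.1, 0.1, 0.4))
  expect_equal(t3$D, 0.15)
  expect_equal(r_squared(t3), 0.36)
  expect_warning(r2 <- r_squared(gamete_table(c(0.5, 0.5, 0, 0),
                                              monomorphic = TRUE)),
                 "monomorphic")
  expect_true(is.na(r2))
  expect_error(gamete_table(c(0.5, 0.5, 0.5, 0)), "sum to 1")
})

test_that("EM equals direct gamete counting when phase is unambiguous", {
  # no double heterozygotes: AB/AB, AB/ab, ab/ab, Ab/Ab samples
  h <- haplos_from_counts(6, 2, 2, 6)
  set.seed(1)
  pairs <- matrix(sample(nrow(h)), ncol = 2)
  g1 <- h[pairs[, 1], 1] + h[pairs[, 2], 1]
  g2 <- h[pairs[, 1], 2] + h[pairs[, 2], 2]
  # keep only phase-unambiguous samples
  keep <- !(g1 == 1 & g2 == 1)
  em <- em_gamete_frequencies(g1[keep], g2[keep])
  direct <- count_gametes_phased_subset(h, pairs, keep)
  expect_equal(unname(em$p), unname(direct), tolerance = 1e-9)
})

test_that("EM recovers phased truth within 0.02 at n = 100", {
  set.seed(7)
  p_true <- c(AB = 0.45, Ab = 0.15, aB = 0.1, ab = 0.3)
  for (rep in 1:5) {
    hap <- sample(1:4, 200, replace = TRUE, prob = p_true)
    alle <- cbind(c(1, 1, 0, 0)[hap], c(1, 0, 1, 0)[hap])
    g1 <- alle[seq(1, 200, 2), 1] + alle[seq(2, 200, 2), 1]
    g2 <- alle[seq(1, 200, 2), 2] + alle[seq(2, 200, 2), 2]
    em <- em_gamete_frequencies(g1, g2)
    phased <- c(mean(hap == 1), mean(hap == 2), mean(hap == 3), mean(hap == 4))
    expect_lt(max(abs(em$p - phased)), 0.02)
  }
})

test_that("complete LD gives p_AB = p_ab = 0.5 and R^2 = 1", {
  g <- rep(0:2, times = c(5, 6, 5))
  em <- em_gamete_frequencies(g, g)
  expect_equal(unname(em$p["AB"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(em$p["ab"]), 0.5, tolerance = 1e-8)
  expect_equal(em$r2, 1, tolerance = 1e-8)
})

test_that("EM on fully simulated data agrees with simulator phase", {
  res <- small_sim(seed = 13, loci = 30, n_chrom = 1)
  g <- res$sim$genotypes
  h <- attr(g, "haplotypes")
  for (j in c(3, 10, 20)) {
    em <- em_gamete_frequencies(g$dosage[, j], g$dosage[, j + 1])
    direct <- thetascan:::count_gametes_phased(h[, j], h[, j + 1])
    # only 40 gametes here: phase resolution of double heterozygotes is
    # itself stochastic, so agreement is loose at this sample size
    expect_lt(max(abs(em$p - direct$p)), 0.12)
  }
})

test_that("LD decay profile finds the window and honours the MAF filter", {
  # duplicated column: separation-1 R^2 = 1
  des <- balanced_design(10)
  set.seed(3)
  base_col <- rbinom(40, 2, 0.5)
  dos <- matrix(rep(base_col, 4), 40,
                dimnames = list(des$sample, NULL))
  g <- toy_genotypes(dos, des)
  lp <- suppressWarnings(ld_decay_profile(g, separations = 1:2))
  expect_equal(lp$profile$median_r2[1], 1)
  # independent loci at large n: median R^2 near the 1/(2n) sampling floor
  set.seed(4)
  dos2 <- matrix(rbinom(200 * 40, 2, 0.5), 200,
                 dimnames = list(sprintf("high_1_%03d", 1:200), NULL))
  des2 <- study_design(rownames(dos2), rep(c("high", "low"), each = 100),
                       rep(1:2, times = 100))
  g2 <- toy_genotypes(dos2, des2)
  lp2 <- ld_decay_profile(g2, separations = 1:4)
  expect_lt(lp2$profile$median_r2[1], 0.05)
  expect_equal(lp2$w, 3L)     # minimum window
  expect_equal(lp2$ld25_snp, 1L)
  # MAF filter removes rare loci
  dos3 <- dos2; dos3[, 1] <- c(1L, rep(0L, 199))
  g3 <- toy_genotypes(dos3, des2)
  lp3 <- ld_decay_profile(g3, separations = 1)
  # one of the 40 loci fails MAF > 10%: 39 remain, 38 adjacent pairs
  expect_equal(lp3$profile$n_pairs[1], 38L)
})

test_that("four-gamete blocks split exactly at four-gamete pairs", {
  map2 <- data.frame(chrom = "chr1", pos = c(100L, 200L))
  # three gametes only: same block
  h3 <- haplos_from_counts(4, 0, 2, 2)
  b3 <- four_gamete_blocks(h3, mgf = 0.05, map = map2)
  expect_equal(nrow(b3), 1L)
  expect_equal(b3$n_loci, 2L)
  # four gametes at .4/.3/.2/.1: boundary at mgf .09, none at .11
  h4 <- haplos_from_counts(4, 3, 2, 1)
  expect_equal(nrow(four_gamete_blocks(h4, mgf = 0.09, map = map2)), 2L)
  expect_equal(nrow(four_gamete_blocks(h4, mgf = 0.11, map = map2)), 1L)
})

test_that("blocks are deterministic, shift-equivariant, and MGF-monotone", {
  res <- small_sim(seed = 17, loci = 80, n_chrom = 1)
  g <- res$sim$genotypes
  b1 <- four_gamete_blocks(g, mgf = 0.0625)
  b2 <- four_gamete_blocks(g, mgf = 0.0625)
  expect_equal(as.data.frame(b1), as.data.frame(b2))
  # shifting all positions shifts all block coordinates identically
  g_shift <- genotype_matrix(g$dosage,
                             transform(g$map, pos = pos + 1000L,
                                       id = paste0(id, "s")), g$design)
  b_shift <- four_gamete_blocks(g_shift, mgf = 0.0625)
  expect_equal(b_shift$start, b1$start + 1000L)
  expect_equal(b_shift$end, b1$end + 1000L)
  # a larger MGF never yields a smaller median block span
  meds <- vapply(c(0.05, 0.1, 0.15, 0.2), function(m)
    attr(four_gamete_blocks(g, mgf = m), "median_bp"), numeric(1))
  expect_true(all(diff(meds) >= 0))
  # boundary verification: each new block opens on four-gamete evidence
  # against a member of the closed block
  blocks <- four_gamete_blocks(g, mgf = 0.09)
  poly <- which(apply(g$dosage, 2, function(v) {
    m <- mean(v); m > 0 && m < 2
  }))
  if (nrow(blocks) > 1) {
    for (k in seq_len(nrow(blocks) - 1L)) {
      prev_members <- poly[g$map$pos[poly] >= blocks$start[k] &
                             g$map$pos[poly] <= blocks$end[k]]
      opener <- poly[g$map$pos[poly] == blocks$start[k + 1L]]
      four <- vapply(prev_members, function(i)
        min(em_gamete_frequencies(g$dosage[, i], g$dosage[, opener])$p) > 0.09,
        logical(1))
      expect_true(any(four))
    }
  }
})

test_that("spine MGF search reaches the coverage target or warns", {
  # perfect-LD data: no four-gamete pair at any MGF, full coverage at once
  des <- balanced_design(5)
  set.seed(9)
  col <- rbinom(20, 2, 0.5)
  g <- toy_genotypes(matrix(rep(col, 5), 20,
                            dimnames = list(des$sample, NULL)), des)
  sp <- spine_mgf_search(g)
  expect_equal(sp$mgf, 0.05)
  expect_equal(sp$coverage, 1)
  # simulated line data: either target reached or a warning raised
  res <- small_sim(seed = 23, loci = 60, n_chrom = 1)
  sp2 <- tryCatch(spine_mgf_search(res$sim$genotypes, coverage_target = 0.9),
                  warning = function(w) w)
  if (inherits(sp2, "warning")) {
    expect_match(conditionMessage(sp2), "unreachable")
  } else {
    expect_gte(sp2$coverage, 0.9)
  }
  # a stricter target can only raise the returned MGF
  g2 <- res$sim$genotypes
  m_low <- suppressWarnings(spine_mgf_search(g2, coverage_target = 0.5)$mgf)
  m_high <- suppressWarnings(spine_mgf_search(g2, coverage_target = 0.95)$mgf)
  expect_gte(m_high, m_low)
})

test_that("R^2 between independent loci sits at its sampling floor", {
  # phased gametes: the familiar E[R^2] ~ 1/N floor for N haplotypes;
  # unphased EM estimates carry the double-heterozygote phase noise on
  # top, giving E[R^2] ~ 1/(n-1) for n diploid samples
  set.seed(11)
  N <- 120
  r2_ph <- replicate(300, {
    t <- thetascan:::count_gametes_phased(rbinom(N, 1, 0.5), rbinom(N, 1, 0.5))
    t$r2
  })
  r2_ph <- r2_ph[!is.na(r2_ph)]
  se <- stats::sd(r2_ph) / sqrt(length(r2_ph))
  expect_lt(abs(mean(r2_ph) - 1 / N), 3 * se)
  n <- 60
  r2s <- replicate(300, {
    em <- em_gamete_frequencies(rbinom(n, 2, 0.5), rbinom(n, 2, 0.5))
    em$r2
  })
  r2s <- r2s[!is.na(r2s)]
  se2 <- stats::sd(r2s) / sqrt(length(r2s))
  expect_lt(abs(mean(r2s) - 1 / (n - 1)), 3 * se2)
})
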