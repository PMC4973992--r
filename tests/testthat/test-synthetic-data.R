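test_that("sim_config validates fields and names the offender", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(heritability = 1.5), "heritability")
  expect_error(sim_config(recombination_rate = -1e-8), "recombination_rate")
  expect_error(sim_config(families_per_line = 1), "families_per_line")
  expect_error(sim_config(n_causal_loci = 1e6), "n_causal_loci")
  expect_error(sim_config(read_error_rate = 1), "read_error_rate")
  expect_error(sim_config(n_generations_selected = 61,
                          n_generations_total = 60),
               "n_generations_selected")
})

test_that("sim_config round-trips through the flat key-value file", {
  cfg <- sim_config(n_chromosomes = 3, loci_per_chromosome = 11,
                    effect_sizes = c(1, -0.5), n_causal_loci = 2, seed = 9)
  p <- tempfile(fileext = ".dcf")
  write_sim_config(cfg, p)
  cfg2 <- read_sim_config(p)
  expect_equal(cfg2, cfg)
})

test_that("founder haplotypes are homozygous lines, polymorphic, deterministic", {
  cfg <- sim_config(n_chromosomes = 2, loci_per_chromosome = 100, seed = 3)
  f1 <- simulate_founders(cfg)
  f2 <- simulate_founders(cfg)
  expect_identical(f1$haplotypes, f2$haplotypes)   # seed fixed
  expect_equal(dim(f1$haplotypes), c(8L, 200L))
  cs <- colSums(f1$haplotypes)
  expect_true(all(cs >= 1 & cs <= 7))              # every locus polymorphic
  for (cc in unique(f1$map$chrom))
    expect_true(all(diff(f1$map$pos[f1$map$chrom == cc]) > 0))
})

test_that("two founders give pooled frequency exactly 0.5 at every locus", {
  cfg <- sim_config(n_founders = 2, n_chromosomes = 1,
                    loci_per_chromosome = 50, seed = 4)
  f <- simulate_founders(cfg)
  expect_true(all(colMeans(f$haplotypes) == 0.5))
})

test_that("zero recombination leaves base haplotypes as intact founder copies", {
  cfg <- sim_config(n_chromosomes = 2, loci_per_chromosome = 40,
                    recombination_rate = 0, n_base = 20, families_per_line = 5,
                    n_generations_intercross = 3, seed = 5)
  f <- simulate_founders(cfg)
  b <- simulate_magic_base(f, cfg)
  for (cc in unique(b$map$chrom)) {
    idx <- which(b$map$chrom == cc)
    for (r in seq_len(nrow(b$haplo))) {
      match_any <- any(apply(f$haplotypes[, idx, drop = FALSE], 1,
                             function(fh) all(fh == b$haplo[r, idx])))
      expect_true(match_any)
    }
  }
})

test_that("MAGIC base shows all four gametes at some adjacent pair", {
  cfg <- sim_config(n_chromosomes = 1, loci_per_chromosome = 80, n_base = 50,
                    n_generations_intercross = 3, seed = 6)
  b <- simulate_magic_base(simulate_founders(cfg), cfg)
  four <- vapply(seq_len(ncol(b$haplo) - 1L), function(j) {
    g <- paste(b$haplo[, j], b$haplo[, j + 1L])
    length(unique(g)) == 4L
  }, logical(1))
  expect_true(any(four))
})

test_that("base blocks are smaller than blocks after drift at matched MGF", {
  # drift prunes gametes: the four-gamete rule finds fewer breakpoints in
  # the drifted lines, hence larger blocks (brute-force block calling on
  # the emitted phased haplotypes)
  res <- small_sim(seed = 11, loci = 150, n_chrom = 1, gens_sel = 0,
                   gens_total = 25)
  base <- simulate_magic_base(simulate_founders(res$cfg), res$cfg)
  hb_base <- four_gamete_blocks(base$haplo, mgf = 0.0625, map = base$map)
  hsel <- attr(res$sim$genotypes, "haplotypes")
  hb_sel <- four_gamete_blocks(hsel, mgf = 0.0625,
                               map = res$sim$genotypes$map)
  expect_lt(attr(hb_base, "median_bp"), attr(hb_sel, "median_bp"))
})

test_that("selection experiment is seed-deterministic and well-formed", {
  r1 <- small_sim(seed = 21)$sim
  r2 <- small_sim(seed = 21)$sim
  expect_identical(r1$genotypes$dosage, r2$genotypes$dosage)
  expect_identical(r1$reads$nr, r2$reads$nr)
  d <- r1$genotypes$dosage
  expect_equal(nrow(d), 40L)
  expect_true(all(d %in% 0:2))
  expect_equal(as.vector(table(r1$design$line)), c(20L, 20L))
})

test_that("frequency trajectories stay in [0,1]; drift has no directional trend", {
  deltas <- numeric(0)
  for (s in 1:5) {
    res <- small_sim(seed = 100 + s, n_causal = 5L, effect = 0,
                     gens_sel = 10L, gens_total = 10L)
    tr <- res$sim$truth$trajectories
    expect_true(all(tr >= 0 & tr <= 1, na.rm = TRUE))
    deltas <- c(deltas, as.vector(tr[, , , dim(tr)[4]] - tr[, , , 1]))
  }
  # drift-only: mean per-experiment frequency change centred on zero
  expect_lt(abs(mean(deltas)), 3 * stats::sd(deltas) / sqrt(length(deltas)))
})

test_that("strong selection drives divergent causal trajectories", {
  res <- small_sim(seed = 31, n_causal = 1L, effect = 1, heritability = 0.5,
                   gens_sel = 15L, gens_total = 15L)
  tr <- res$sim$truth$trajectories
  last <- dim(tr)[4]
  for (r in 1:2)
    expect_gt(tr[1, "high", r, last], tr[1, "low", r, last])
})

test_that("between-line Fst grows with generations under drift", {
  fst_at <- function(gens, seed) {
    res <- small_sim(seed = seed, loci = 100, n_chrom = 1, gens_sel = 0,
                     gens_total = gens)
    freqs <- estimate_allele_frequency(res$sim$reads)
    mean(pairwise_fst_summary(freqs)$fst[1:2])
  }
  wins <- vapply(1:5, function(s)
    fst_at(30, 300 + s) > fst_at(4, 300 + s), logical(1))
  expect_gte(sum(wins), 4)
})

test_that("simulate_reads respects the binomial/Poisson model", {
  des <- balanced_design(2)
  d <- matrix(0L, nrow(des), 6, dimnames = list(des$sample, NULL))
  g <- toy_genotypes(d, des)
  r0 <- simulate_reads(g, mean_depth = 8, read_error_rate = 0, seed = 2)
  expect_true(all(r0$nr == 0L))                       # no error, dosage 0
  expect_true(all(r0$nr <= r0$total))                 # reads conserved
  # error rate recovered in the large-count limit
  d1 <- matrix(0L, 1, 1, dimnames = list("high_1_01", NULL))
  des1 <- study_design("high_1_01", "high", 1)
  g1 <- toy_genotypes(d1, des1)
  r1 <- simulate_reads(g1, mean_depth = 1e6, read_error_rate = 0.003, seed = 3)
  expect_equal(r1$nr[1, 1] / r1$total[1, 1], 0.003, tolerance = 0.1)
  expect_error(simulate_reads(g, mean_depth = -1), "mean_depth")
})

test_that("heterozygote miscall rate at depth 5 matches the binomial model", {
  des <- study_design(sprintf("high_1_%02d", 1:50), rep("high", 50), rep(1, 50))
  set.seed(42)
  n_loci <- 400
  total <- matrix(5L, 50, n_loci, dimnames = list(des$sample, NULL))
  nr <- matrix(rbinom(50 * n_loci, 5L, 0.5), 50, n_loci,
               dimnames = list(des$sample, NULL))
  rc <- read_count_matrix(nr, total,
                          data.frame(chrom = "chr1",
                                     pos = seq_len(n_loci) * 10L), des)
  called <- call_genotypes(rc)
  miscall <- mean(called$dosage != 1L)
  expect_equal(miscall, het_miscall_rate(5), tolerance = 0.08)
})
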