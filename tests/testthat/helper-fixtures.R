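# Shared fixtures and independent oracles, all built in code.

# balanced design: 2 lines x 2 replicates x n samples
balanced_design <- function(n = 10L, lines = c("high", "low"), reps = 1:2) {
  grid <- expand.grid(k = seq_len(n), replicate = reps, line = lines,
                      stringsAsFactors = FALSE)
  study_design(sprintf("%s_%d_%02d", grid$line, grid$replicate, grid$k),
               grid$line, grid$replicate)
}

# genotype matrix from an explicit dosage table (loci in columns)
toy_genotypes <- function(dosage, design, chrom = "chr1",
                          pos = seq_len(ncol(dosage)) * 100L) {
  rownames(dosage) <- design$sample
  genotype_matrix(dosage, data.frame(chrom = chrom, pos = pos), design)
}

# small drift-only or selected dataset used across tests
small_sim <- function(seed = 1L, loci = 200L, effect = 0, n_causal = 0L,
                      gens_sel = 10L, gens_total = 12L, families = 6L,
                      n_chrom = 2L, heritability = 0.3, n_seq = 10L) {
  cfg <- sim_config(n_chromosomes = n_chrom, loci_per_chromosome = loci,
                    n_base = 60L, families_per_line = families,
                    n_generations_intercross = 4L,
                    n_generations_selected = gens_sel,
                    n_generations_total = gens_total,
                    n_causal_loci = n_causal, effect_sizes = effect,
                    heritability = heritability,
                    n_sequenced_per_line = n_seq, seed = seed)
  list(cfg = cfg, sim = simulate_experiment(cfg))
}

# ---------------------------------------------------------------------------
# Independent oracle: textbook balanced nested ANOVA on gamete indicators,
# written from group means (a completely different route than the package's
# pooled-sum implementation). Balanced designs only.
brute_force_components <- function(dosage, design) {
  lines <- unique(as.character(design$line))
  reps <- unique(as.character(design$replicate))
  a <- length(lines); b <- length(reps)
  n <- nrow(design) / (a * b)   # samples per cell
  g <- 2
  out <- matrix(NA_real_, ncol(dosage), 4,
                dimnames = list(colnames(dosage),
                                c("sigma_L", "sigma_RL", "sigma_SRL", "sigma_G")))
  for (l in seq_len(ncol(dosage))) {
    # gamete values y[i,j,k,m]
    y <- array(NA_real_, c(a, b, n, g))
    for (i in seq_len(a)) for (j in seq_len(b)) {
      rows <- which(design$line == lines[i] & design$replicate == reps[j])
      for (k in seq_along(rows)) {
        d <- dosage[rows[k], l]
        y[i, j, k, ] <- c(as.integer(d >= 1), as.integer(d == 2))
      }
    }
    m_ijk <- apply(y, c(1, 2, 3), mean)
    m_ij <- apply(y, c(1, 2), mean)
    m_i <- apply(y, 1, mean)
    m <- mean(y)
    SS_G <- sum((y - array(rep(m_ijk, g), c(a, b, n, g)))^2)
    SS_S <- g * sum((m_ijk - array(rep(m_ij, n), c(a, b, n)))^2)
    SS_R <- g * n * sum((m_ij - matrix(rep(m_i, b), a, b))^2)
    SS_L <- g * n * b * sum((m_i - m)^2)
    MS_G <- SS_G / (a * b * n * (g - 1))
    MS_S <- SS_S / (a * b * (n - 1))
    MS_R <- SS_R / (a * (b - 1))
    MS_L <- SS_L / (a - 1)
    sG <- MS_G
    sS <- (MS_S - sG) / g
    sR <- (MS_R - sG - g * sS) / (g * n)
    sL <- (MS_L - sG - g * sS - g * n * sR) / (g * n * b)
    out[l, ] <- c(sL, sR, sS, sG)
  }
  out
}

# enumerate all distinct gamete-level label assignments for a design of
# 4 cells x 1 sample x 2 gametes (8 gametes) and return the max windowed
# theta of each -- the exhaustive permutation oracle
exhaustive_gamete_maxima <- function(genotypes, w = 1L) {
  design <- genotypes$design
  Y <- thetascan:::gamete_matrix(genotypes)
  stopifnot(nrow(Y) == 8L)
  maxima <- numeric(0)
  slots <- 1:8
  combs1 <- utils::combn(8, 2)
  for (c1 in seq_len(ncol(combs1))) {
    s1 <- combs1[, c1]; r1 <- setdiff(slots, s1)
    combs2 <- utils::combn(r1, 2)
    for (c2 in seq_len(ncol(combs2))) {
      s2 <- combs2[, c2]; r2 <- setdiff(r1, s2)
      combs3 <- utils::combn(r2, 2)
      for (c3 in seq_len(ncol(combs3))) {
        s3 <- combs3[, c3]; s4 <- setdiff(r2, s3)
        ord <- c(s1, s2, s3, s4)
        # rebuild dosages: consecutive gamete pairs form the new samples
        d <- Y[ord[seq(1, 8, 2)], , drop = FALSE] +
          Y[ord[seq(2, 8, 2)], , drop = FALSE]
        rownames(d) <- design$sample
        g2 <- genotype_matrix(d, genotypes$map, design)
        comp <- locus_variance_components(g2)
        tr <- windowed_theta(comp, w)
        maxima <- c(maxima, max(tr$theta, na.rm = TRUE))
      }
    }
  }
  maxima
}

# write a small two-gene GFF3 fixture; returns the path
write_toy_gff <- function(path = tempfile(fileext = ".gff3")) {
  lines <- c(
    "##gff-version 3",
    "##sequence-region chr1 1 200000",
    # plus-strand two-exon gene with UTRs
    "chr1\ttoy\tgene\t20001\t30000\t.\t+\t.\tID=gene1;gene_id=gene1",
    "chr1\ttoy\tmRNA\t20001\t30000\t.\t+\t.\tID=tx1;Parent=gene1",
    "chr1\ttoy\texon\t20001\t21000\t.\t+\t.\tID=ex1;Parent=tx1",
    "chr1\ttoy\texon\t29001\t30000\t.\t+\t.\tID=ex2;Parent=tx1",
    "chr1\ttoy\tfive_prime_UTR\t20001\t20200\t.\t+\t.\tID=u1;Parent=tx1",
    # minus-strand single-exon gene, TSS at 50000
    "chr1\ttoy\tgene\t45001\t50000\t.\t-\t.\tID=gene2;gene_id=gene2",
    "chr1\ttoy\tmRNA\t45001\t50000\t.\t-\t.\tID=tx2;Parent=gene2",
    "chr1\ttoy\texon\t45001\t50000\t.\t-\t.\tID=ex3;Parent=tx2",
    # plus-strand gene with a short (100 bp) intron
    "chr1\ttoy\tgene\t100001\t102100\t.\t+\t.\tID=gene3;gene_id=gene3",
    "chr1\ttoy\tmRNA\t100001\t102100\t.\t+\t.\tID=tx3;Parent=gene3",
    "chr1\ttoy\texon\t100001\t101000\t.\t+\t.\tID=ex4;Parent=tx3",
    "chr1\ttoy\texon\t101101\t102100\t.\t+\t.\tID=ex5;Parent=tx3")
  writeLines(lines, path)
  path
}

# direct phased counting restricted to kept samples (oracle helper)
count_gametes_phased_subset <- function(h, pairs, keep) {
  rows <- as.vector(t(pairs[keep, ]))
  tab <- thetascan:::count_gametes_phased(h[rows, 1], h[rows, 2])
  tab$p
}

# all n! permutations, one per row (tiny n only)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))))
}

# phased haplotype matrix realising given two-locus gamete counts
haplos_from_counts <- function(nAB, nAb, naB, nab) {
  h <- rbind(matrix(rep(c(1, 1), nAB), ncol = 2, byrow = TRUE),
             matrix(rep(c(1, 0), nAb), ncol = 2, byrow = TRUE),
             matrix(rep(c(0, 1), naB), ncol = 2, byrow = TRUE),
             matrix(rep(c(0, 0), nab), ncol = 2, byrow = TRUE))
  storage.mode(h) <- "integer"
  h
}
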