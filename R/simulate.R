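#' Simulate fully inbred founder haplotypes
#'
#' Generates `n_founders` homozygous founder lines over a SNP map. Every
#' locus is polymorphic across founders (minor allele carried by at least
#' one founder). A fraction `founder_ld_fraction` of adjacent locus pairs
#' receive independent allele patterns, so all four two-locus gametes are
#' typically present among founders already -- the property of a
#' multi-parent cross that keeps ancestral haplotype blocks small; the
#' remaining pairs copy a correlated pattern (shared ancestral haplotype).
#'
#' @param config a [sim_config()].
#' @return A `founder_haplotypes` object: `haplotypes` (founders x loci 0/1
#'   matrix, one row per inbred line) and `map` (chrom, pos, id).
#' @export
simulate_founders <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  nf <- config$n_founders
  map <- make_locus_map(config)
  L <- nrow(map)
  H <- matrix(0L, nf, L)
  draw_pattern <- function() {
    repeat {
      p <- stats::runif(1, 0.15, 0.85)
      v <- as.integer(stats::runif(nf) < p)
      s <- sum(v)
      if (s >= 1L && s <= nf - 1L) return(v)
    }
  }
  flip_pattern <- function(v) {
    # with two founders the only polymorphic neighbours are the copy and
    # the complement; with more, flip single founders until polymorphic
    if (nf == 2L) {
      if (stats::runif(1) < 0.5) return(v) else return(1L - v)
    }
    repeat {
      w <- v
      f <- sample.int(nf, 1L)
      w[f] <- 1L - w[f]
      s <- sum(w)
      if (s >= 1L && s <= nf - 1L) return(w)
    }
  }
  for (c in seq_len(config$n_chromosomes)) {
    idx <- which(map$chrom == chrom_name(c))
    H[, idx[1L]] <- draw_pattern()
    for (j in idx[-1L]) {
      H[, j] <- if (stats::runif(1) < config$founder_ld_fraction)
        draw_pattern() else flip_pattern(H[, j - 1L])
    }
  }
  rownames(H) <- paste0("founder", seq_len(nf))
  structure(list(haplotypes = H, map = map), class = "founder_haplotypes")
}

chrom_name <- function(i) paste0("chr", i)

make_locus_map <- function(config) {
  maps <- lapply(seq_len(config$n_chromosomes), function(c) {
    pos <- sort(sample.int(as.integer(config$chromosome_length),
                           config$loci_per_chromosome))
    data.frame(chrom = chrom_name(c), pos = pos, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  map$id <- paste0(map$chrom, "_", map$pos)
  map
}

# One meiosis: recombine two parental haplotypes into a gamete.
# Crossover count per chromosome is Poisson in its genetic length
# (recombination_rate * chromosome_length Morgans); positions uniform in bp.
meiosis <- function(hapA, hapB, chrom_loci, chrom_pos, genetic_length, bp_length) {
  gam <- hapA
  for (c in seq_along(chrom_loci)) {
    idx <- chrom_loci[[c]]
    k <- stats::rpois(1L, genetic_length)
    start <- sample.int(2L, 1L) - 1L
    if (k == 0L) {
      if (start == 1L) gam[idx] <- hapB[idx]
    } else {
      xo <- sort(stats::runif(k, 0, bp_length))
      seg <- findInterval(chrom_pos[[c]], xo)
      strand <- (start + seg) %% 2L
      sel <- strand == 1L
      if (any(sel)) gam[idx[sel]] <- hapB[idx[sel]]
    }
  }
  gam
}

# Per-chromosome locus indices/positions, precomputed once per map.
chrom_split <- function(map) {
  chroms <- unique(map$chrom)
  list(loci = lapply(chroms, function(c) which(map$chrom == c)),
       pos = lapply(chroms, function(c) map$pos[map$chrom == c]),
       chroms = chroms)
}

# Batch meioses through the compiled kernel: `parents` is a 2-column
# matrix of 1-based haplotype row indices (A strand, B strand) in `pop`,
# one row per gamete to produce. Loci must be grouped by chromosome in
# map order (they are, by construction).
meiosis_batch <- function(pop, parents, map, glen, bp_length) {
  chroms <- unique(map$chrom)
  starts <- c(0L, cumsum(vapply(chroms, function(c) sum(map$chrom == c),
                                integer(1))))
  meiosis_batch_core(pop, parents - 1L, as.numeric(map$pos), starts,
                     glen, bp_length)
}

#' Intercross founders into a MAGIC base population
#'
#' Builds a base population of `n_base` diploids whose genomes are mosaics
#' of founder segments: founder haplotypes are distributed round-robin over
#' the first generation (so all founders contribute), followed by
#' `n_generations_intercross` generations of random mating with Poisson
#' crossovers.
#'
#' @param founders output of [simulate_founders()].
#' @param config the same [sim_config()].
#' @return A `haplo_population`: `haplo` (2*n_base x loci 0/1 matrix; rows
#'   2i-1, 2i are individual i) and `map`.
#' @export
simulate_magic_base <- function(founders, config) {
  validate_sim_config(config)
  if (!inherits(founders, "founder_haplotypes"))
    stop("founders must come from simulate_founders()")
  set.seed(config$seed + 1L)
  map <- founders$map
  glen <- config$recombination_rate * config$chromosome_length
  N <- config$n_base
  # generation 0: round-robin founder gametes, shuffled pairing
  gidx <- sample(rep_len(seq_len(config$n_founders), 2L * N))
  pop <- founders$haplotypes[gidx, , drop = FALSE]
  for (g in seq_len(config$n_generations_intercross)) {
    par <- t(vapply(seq_len(N), function(i) sample.int(N, 2L), integer(2)))
    parents <- matrix(0L, 2L * N, 2L)
    parents[seq(1L, 2L * N, 2L), ] <- cbind(2L * par[, 1L] - 1L, 2L * par[, 1L])
    parents[seq(2L, 2L * N, 2L), ] <- cbind(2L * par[, 2L] - 1L, 2L * par[, 2L])
    pop <- meiosis_batch(pop, parents, map, glen, config$chromosome_length)
  }
  rownames(pop) <- paste0("base", rep(seq_len(N), each = 2L), "_", rep(1:2, N))
  structure(list(haplo = pop, map = map), class = "haplo_population")
}

# Additive trait of diploid individuals from a 2n x L haplotype matrix.
trait_genetic <- function(haplo, causal_idx, effects) {
  if (length(causal_idx) == 0L) return(numeric(nrow(haplo) / 2L))
  dos <- haplo[seq(1L, nrow(haplo), by = 2L), causal_idx, drop = FALSE] +
    haplo[seq(2L, nrow(haplo), by = 2L), causal_idx, drop = FALSE]
  as.numeric(dos %*% effects)
}

#' Run the replicated bidirectional selection experiment
#'
#' For each replicate an independent sample of base individuals founds a
#' high and a low line of `families_per_line` breeding pairs. Each
#' generation every family produces `offspring_per_family` offspring; an
#' additive polygenic trait (causal dosages times effects plus Gaussian
#' environmental noise scaled to the base-population heritability) is
#' scored, and within-family truncation selection keeps the two extreme
#' offspring per family (highest in the high line, lowest in the low line).
#' Mating is rotational: the first pick of family f pairs with the second
#' pick of family f+1 (circular), so every family contributes to the next
#' generation and effective size stays near its maximum. After
#' `n_generations_selected` generations selection is relaxed (picks become
#' random) until `n_generations_total`. Finally `n_sequenced_per_line`
#' individuals per line x replicate are drawn as the sequenced sample.
#'
#' @param base a `haplo_population` from [simulate_magic_base()].
#' @param config the same [sim_config()].
#' @return A list: `genotypes` (a `genotype_matrix` of all sequenced
#'   samples, with phased haplotypes in attribute `"haplotypes"`), `truth`
#'   (a `truth_set`: causal locus ids, effect directions, and realized
#'   frequency trajectories `[causal, line, replicate, generation]`), and
#'   `design` (the [study_design()]).
#' @export
simulate_selection_experiment <- function(base, config) {
  validate_sim_config(config)
  if (!inherits(base, "haplo_population"))
    stop("base must come from simulate_magic_base()")
  N <- nrow(base$haplo) / 2L
  Fm <- config$families_per_line
  if (N < 2L * Fm)
    stop("base population too small: need >= 2 * families_per_line individuals")
  map <- base$map
  glen <- config$recombination_rate * config$chromosome_length
  set.seed(config$seed + 2L)
  # causal loci drawn among loci with common variation in the base
  bfreq <- colMeans(base$haplo)
  eligible <- which(pmin(bfreq, 1 - bfreq) >= 0.1)
  if (length(eligible) < config$n_causal_loci) eligible <- seq_len(ncol(base$haplo))
  causal_idx <- sort(sample(eligible, config$n_causal_loci))
  effects <- rep_len(config$effect_sizes, config$n_causal_loci)
  vg <- stats::var(trait_genetic(base$haplo, causal_idx, effects))
  h2 <- config$heritability
  sigma_e <- if (is.na(vg) || vg == 0 || h2 == 0) 1 else if (h2 == 1) 0 else
    sqrt(vg * (1 - h2) / h2)
  env_only <- (h2 == 0)

  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$n_replicates)
  gens <- config$n_generations_total
  traj <- array(NA_real_,
                dim = c(config$n_causal_loci, 2L, config$n_replicates, gens + 1L),
                dimnames = list(map$id[causal_idx], c("high", "low"),
                                paste0("rep", seq_len(config$n_replicates)),
                                paste0("gen", 0:gens)))
  dosage_all <- NULL; haplo_all <- NULL
  samp_names <- character(0); samp_line <- character(0); samp_rep <- integer(0)

  for (r in seq_len(config$n_replicates)) {
    set.seed(rep_seeds[r])
    founders_r <- sample.int(N, 4L * Fm)        # independent base sample
    lines <- list(high = founders_r[seq_len(2L * Fm)],
                  low = founders_r[2L * Fm + seq_len(2L * Fm)])
    for (ln in c("high", "low")) {
      ids <- lines[[ln]]
      # breeding stock `cur`: 4 haplotype rows per family
      # (sire strands 1:2, dam strands 3:4)
      rows <- as.vector(vapply(ids, function(i) c(2L * i - 1L, 2L * i),
                               integer(2)))
      cur <- base$haplo[rows, , drop = FALSE]
      traj[, ln, r, 1L] <- causal_freq(cur, causal_idx)
      opf <- config$offspring_per_family
      n_off <- Fm * opf
      fam_of_off <- rep(seq_len(Fm), each = opf)
      # per-offspring gamete parent rows within `cur` (constant layout)
      pA <- cbind(4L * fam_of_off - 3L, 4L * fam_of_off - 2L)  # sire gamete
      pB <- cbind(4L * fam_of_off - 1L, 4L * fam_of_off)       # dam gamete
      parents <- matrix(0L, 2L * n_off, 2L)
      parents[seq(1L, 2L * n_off, 2L), ] <- pA
      parents[seq(2L, 2L * n_off, 2L), ] <- pB
      for (g in seq_len(gens)) {
        selecting <- g <= config$n_generations_selected
        off <- meiosis_batch(cur, parents, map, glen, config$chromosome_length)
        tg <- trait_genetic(off, causal_idx, effects)
        trait <- (if (env_only) 0 else tg) +
          (if (sigma_e > 0) stats::rnorm(length(tg), 0, sigma_e) else 0)
        # within-family picks: two extremes per family (or random when relaxed)
        pick1 <- integer(Fm); pick2 <- integer(Fm)
        for (f in seq_len(Fm)) {
          members <- (f - 1L) * opf + seq_len(opf)
          ranked <- if (!selecting) sample(members) else
            members[order(trait[members], decreasing = (ln == "high"))]
          pick1[f] <- ranked[1L]; pick2[f] <- ranked[2L]
        }
        # rotational mating: pick1 of family f with pick2 of family f+1
        new_rows <- unlist(lapply(seq_len(Fm), function(f) {
          a <- pick1[f]; b <- pick2[if (f == Fm) 1L else f + 1L]
          c(2L * a - 1L, 2L * a, 2L * b - 1L, 2L * b)
        }))
        cur <- off[new_rows, , drop = FALSE]
        traj[, ln, r, g + 1L] <- causal_freq(cur, causal_idx)
        if (g == gens) {
          # sequenced sample drawn from the final offspring pool
          n_off <- Fm * opf
          sel <- sample.int(n_off, min(config$n_sequenced_per_line, n_off))
          h <- off[as.vector(rbind(2L * sel - 1L, 2L * sel)), , drop = FALSE]
          d <- h[seq(1L, nrow(h), 2L), , drop = FALSE] +
            h[seq(2L, nrow(h), 2L), , drop = FALSE]
          nm <- sprintf("%s_%d_%02d", ln, r, seq_along(sel))
          rownames(d) <- nm
          rownames(h) <- paste0(rep(nm, each = 2L), "_g", rep(1:2, length(sel)))
          dosage_all <- rbind(dosage_all, d)
          haplo_all <- rbind(haplo_all, h)
          samp_names <- c(samp_names, nm)
          samp_line <- c(samp_line, rep(ln, length(sel)))
          samp_rep <- c(samp_rep, rep(r, length(sel)))
        }
      }
    }
  }

  design <- study_design(samp_names, samp_line, samp_rep)
  gmat <- genotype_matrix(dosage_all, map, design)
  attr(gmat, "haplotypes") <- haplo_all
  truth <- structure(list(causal_locus_ids = map$id[causal_idx],
                          causal_index = causal_idx,
                          effect_directions = sign(effects + (effects == 0)),
                          effects = effects,
                          trajectories = traj),
                     class = "truth_set")
  list(genotypes = gmat, truth = truth, design = design)
}

# mean causal allele frequency over the breeding-stock haplotype rows
causal_freq <- function(stock, causal_idx) {
  if (length(causal_idx) == 0L) return(numeric(0))
  colMeans(stock[, causal_idx, drop = FALSE])
}

#' Simulate shallow sequencing read counts
#'
#' Per sample and locus, total reads are Poisson(`mean_depth`) and
#' non-reference reads are Binomial(total, p) with
#' p = (dosage/2)(1-e) + (1-dosage/2)e for per-read error rate e.
#'
#' @param genotypes a `genotype_matrix` with dosages in \{0,1,2\}.
#' @param mean_depth mean reads per sample per site.
#' @param read_error_rate per-read allele flip probability.
#' @param seed integer seed.
#' @return A `read_count_matrix` (see [read_count_matrix()]).
#' @export
simulate_reads <- function(genotypes, mean_depth = 5, read_error_rate = 0.003,
                           seed = 1L) {
  if (mean_depth < 0) stop("mean_depth must be >= 0")
  if (read_error_rate < 0 || read_error_rate >= 1)
    stop("read_error_rate must lie in [0, 1)")
  set.seed(seed)
  d <- genotypes$dosage
  n <- length(d)
  total <- matrix(stats::rpois(n, mean_depth), nrow(d), ncol(d))
  p <- d / 2
  p_err <- p * (1 - read_error_rate) + (1 - p) * read_error_rate
  nr <- matrix(stats::rbinom(n, as.vector(total), as.vector(p_err)),
               nrow(d), ncol(d))
  nr[is.na(d)] <- NA_integer_; total[is.na(d)] <- 0L
  dimnames(total) <- dimnames(nr) <- dimnames(d)
  read_count_matrix(nr, total, genotypes$map, genotypes$design)
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: founders -> MAGIC base -> selection experiment ->
#' read counts, all under one master seed.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes`, `reads`, `truth`, `design`, `founders`,
#'   `base`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  founders <- simulate_founders(config)
  base <- simulate_magic_base(founders, config)
  sel <- simulate_selection_experiment(base, config)
  reads <- simulate_reads(sel$genotypes, config$mean_depth,
                          config$read_error_rate, seed = config$seed + 3L)
  list(genotypes = sel$genotypes, reads = reads, truth = sel$truth,
       design = sel$design, founders = founders, base = base)
}

#' Write the truth set as TSV
#' @param truth a `truth_set`.
#' @param path file path.
#' @export
write_truthset <- function(truth, path) {
  df <- data.frame(locus = truth$causal_locus_ids,
                   effect = truth$effects,
                   direction = truth$effect_directions)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
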