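#' EM estimate of two-locus gamete frequencies from unphased genotypes
#'
#' The classical iterative (EM) estimator: only the double-heterozygote
#' class has ambiguous phase; starting from linkage equilibrium (product
#' of allele frequencies) the expected cis fraction of double
#' heterozygotes is updated until the largest frequency change falls below
#' `tol` (default 1e-10) or `max_iter` iterations. Pairs with missing
#' genotypes use complete cases. On data with no double heterozygotes the
#' estimate equals direct gamete counting after a single step.
#'
#' @param g1,g2 integer dosage vectors (0/1/2, NA allowed) at the two loci,
#'   or `g1` may be a 3x3 genotype count table (rows = dosage at locus 1).
#' @param tol convergence tolerance on gamete frequencies.
#' @param max_iter iteration cap.
#' @return A `gamete_table`: `p` (named AB, Ab, aB, ab where A/B are the
#'   non-reference alleles), `D`, `r2`, `n` (samples used), `monomorphic`
#'   flag (TRUE when either locus has no variation; `r2` is then NA).
#' @export
em_gamete_frequencies <- function(g1, g2 = NULL, tol = 1e-10, max_iter = 1000L) {
  if (is.matrix(g1)) {
    if (!all(dim(g1) == c(3L, 3L))) stop("genotype count table must be 3x3")
    n_tab <- g1
  } else {
    ok <- !is.na(g1) & !is.na(g2)
    if (!any(ok)) stop("need at least one sample with calls at both loci")
    n_tab <- table(factor(g1[ok], levels = 0:2), factor(g2[ok], levels = 0:2))
    n_tab <- matrix(as.numeric(n_tab), 3, 3)
  }
  n <- sum(n_tab)
  if (n < 1) stop("need at least one sample with calls at both loci")
  # allele counts of the non-reference alleles
  pA <- sum(n_tab * matrix(0:2, 3, 3)) / (2 * n)
  pB <- sum(n_tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  mono <- pA %in% c(0, 1) || pB %in% c(0, 1)
  # phase-known haplotype contributions (A = non-ref allele locus 1)
  base_AB <- 2 * n_tab[3, 3] + n_tab[3, 2] + n_tab[2, 3]
  base_Ab <- 2 * n_tab[3, 1] + n_tab[3, 2] + n_tab[2, 1]
  base_aB <- 2 * n_tab[1, 3] + n_tab[1, 2] + n_tab[2, 3]
  base_ab <- 2 * n_tab[1, 1] + n_tab[1, 2] + n_tab[2, 1]
  ndh <- n_tab[2, 2]
  f <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  for (it in seq_len(max_iter)) {
    cis <- f["AB"] * f["ab"]
    trans <- f["Ab"] * f["aB"]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    f_new <- c(base_AB + ndh * w, base_Ab + ndh * (1 - w),
               base_aB + ndh * (1 - w), base_ab + ndh * w) / (2 * n)
    names(f_new) <- names(f)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  gamete_table(f, n, monomorphic = mono)
}

#' Gamete table constructor
#'
#' @param p named frequencies (AB, Ab, aB, ab) summing to 1.
#' @param n number of samples behind the estimate.
#' @param monomorphic flag: R^2 undefined.
#' @return A `gamete_table` with `D` and `r2` filled in.
#' @export
gamete_table <- function(p, n = NA_integer_, monomorphic = FALSE) {
  if (abs(sum(p) - 1) > 1e-9) stop("gamete frequencies must sum to 1")
  names(p) <- c("AB", "Ab", "aB", "ab")
  pA <- p["AB"] + p["Ab"]; pB <- p["AB"] + p["aB"]
  D <- unname(p["AB"] - pA * pB)
  denom <- unname(pA * (1 - pA) * pB * (1 - pB))
  r2 <- if (monomorphic || denom <= 0) NA_real_ else D^2 / denom
  structure(list(p = p, D = D, r2 = r2, n = n, monomorphic = monomorphic),
            class = "gamete_table")
}

#' Squared allele-frequency correlation between two loci
#'
#' `R^2 = D^2 / (pA qA pB qB)` with `D = p_AB - pA pB`; undefined (NA,
#' with a warning) when any allele marginal is 0.
#'
#' @param table a `gamete_table`.
#' @return scalar R^2 in [0, 1] or NA.
#' @export
r_squared <- function(table) {
  if (!inherits(table, "gamete_table")) stop("expected a gamete_table")
  if (is.na(table$r2)) warning("R^2 undefined: a locus is monomorphic")
  table$r2
}

#' @export
print.gamete_table <- function(x, ...) {
  cat("gamete_table: ", paste(sprintf("%s=%.4f", names(x$p), x$p),
                              collapse = " "),
      sprintf("; D=%.4f R2=%s n=%s\n", x$D,
              ifelse(is.na(x$r2), "NA", sprintf("%.4f", x$r2)), x$n))
  invisible(x)
}

# Direct gamete counting on phased haplotypes (rows = haplotypes) --
# the oracle the EM must match when phase is unambiguous, and the
# estimator used for inbred founder pools where gametes are observable.
count_gametes_phased <- function(h1, h2) {
  ok <- !is.na(h1) & !is.na(h2)
  h1 <- h1[ok]; h2 <- h2[ok]
  n <- length(h1)
  p <- c(AB = sum(h1 == 1 & h2 == 1), Ab = sum(h1 == 1 & h2 == 0),
         aB = sum(h1 == 0 & h2 == 1), ab = sum(h1 == 0 & h2 == 0)) / n
  mono <- all(h1 == h1[1]) || all(h2 == h2[1])
  gamete_table(p, n / 2, monomorphic = mono)
}

#' LD decay profile and scan-window calibration
#'
#' Computes pairwise R^2 (EM-based) for locus pairs at fixed SNP-rank
#' separations within chromosomes, restricted to loci with minor allele
#' frequency above `maf_min` (default 10%). For each separation the
#' R^2 distribution is summarised (median, fractions below 0.25 and 0.50,
#' median bp distance). The recommended scan window is the smallest
#' separation whose median R^2 drops below 0.25 (the LD_25 distance),
#' forced odd by rounding up.
#'
#' @param genotypes a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.10).
#' @param separations SNP-rank separations to profile (default 1:15).
#' @param max_pairs_per_sep random cap on pairs per separation.
#' @param seed seed for pair subsampling.
#' @return An `ld_profile`: `profile` data frame, `ld25_snp` (separation),
#'   `ld25_bp` (median bp at that separation), `w` (recommended odd
#'   window).
#' @export
ld_decay_profile <- function(genotypes, maf_min = 0.10, separations = 1:15,
                             max_pairs_per_sep = 2000L, seed = 1L) {
  d <- genotypes$dosage
  maf_ok <- apply(d, 2, function(x) {
    p <- mean(x, na.rm = TRUE) / 2
    !is.na(p) && pmin(p, 1 - p) > maf_min
  })
  keep <- which(maf_ok)
  if (length(keep) < 2L) stop("fewer than two loci pass the MAF filter")
  map <- genotypes$map
  set.seed(seed)
  rows <- lapply(separations, function(s) {
    pairs <- NULL
    for (cc in unique(map$chrom)) {
      idx <- keep[map$chrom[keep] == cc]
      if (length(idx) > s)
        pairs <- rbind(pairs, cbind(idx[seq_len(length(idx) - s)],
                                    idx[(s + 1):length(idx)]))
    }
    if (is.null(pairs)) return(NULL)
    if (nrow(pairs) > max_pairs_per_sep)
      pairs <- pairs[sample.int(nrow(pairs), max_pairs_per_sep), , drop = FALSE]
    r2 <- vapply(seq_len(nrow(pairs)), function(i) {
      em_gamete_frequencies(d[, pairs[i, 1]], d[, pairs[i, 2]])$r2
    }, numeric(1))
    bp <- abs(map$pos[pairs[, 2]] - map$pos[pairs[, 1]])
    r2 <- r2[!is.na(r2)]
    if (!length(r2)) return(NULL)
    data.frame(separation = s, n_pairs = length(r2),
               median_r2 = stats::median(r2),
               frac_lt_25 = mean(r2 < 0.25), frac_lt_50 = mean(r2 < 0.50),
               median_bp = stats::median(bp))
  })
  prof <- do.call(rbind, rows)
  if (is.null(prof)) stop("no qualifying locus pairs at any separation")
  below <- prof$separation[prof$median_r2 < 0.25]
  if (length(below)) {
    ld25 <- min(below)
  } else {
    warning("median R^2 never falls below 0.25 within profiled separations; ",
            "using the largest separation")
    ld25 <- max(prof$separation)
  }
  w <- if (ld25 %% 2L == 1L) ld25 else ld25 + 1L
  w <- max(w, 3L)
  structure(list(profile = prof, ld25_snp = ld25,
                 ld25_bp = prof$median_bp[prof$separation == ld25][1],
                 w = as.integer(w)),
            class = "ld_profile")
}

#' @export
print.ld_profile <- function(x, ...) {
  cat("ld_profile: LD_25 at separation", x$ld25_snp, "SNPs (~",
      round(x$ld25_bp), "bp); recommended window w =", x$w, "\n")
  print(x$profile, row.names = FALSE)
  invisible(x)
}
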