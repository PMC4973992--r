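#' Windowed theta track
#'
#' The scan statistic at a focal SNP is the ratio of sums over a window of
#' `w` consecutive usable loci centred on the focal SNP: window sum of the
#' between-line component over the window sum of all four components
#' (ratio-of-sums, not mean of per-locus ratios). Usable loci are those
#' with a defined, nonzero component total; monomorphic or unscorable loci
#' are skipped and windows are built over the remaining loci in rank
#' order, keeping the focal SNP central. Focal SNPs closer than (w-1)/2
#' usable loci to a chromosome end are not scored. `w = 1` reduces to the
#' per-locus theta exactly.
#'
#' @param components a `locus_components` from
#'   [locus_variance_components()].
#' @param w odd window size in SNPs (default 7).
#' @return A `theta_track` data frame: `chrom`, `pos`, `id`, `theta` per
#'   focal SNP, with `w` as an attribute.
#' @export
windowed_theta <- function(components, w = 7L) {
  w <- as.integer(w)
  if (w < 1L || w %% 2L == 0L) stop("window size w must be odd and >= 1")
  usable <- !is.na(components$denom) & components$denom != 0 &
    !is.na(components$sigma_L)
  comp <- components[usable, , drop = FALSE]
  h <- (w - 1L) %/% 2L
  res <- lapply(unique(comp$chrom), function(cc) {
    x <- comp[comp$chrom == cc, , drop = FALSE]
    n <- nrow(x)
    if (n < w) return(NULL)
    csn <- cumsum(x$sigma_L)
    csd <- cumsum(x$denom)
    wn <- csn[w:n] - c(0, csn)[1:(n - w + 1L)]
    wd <- csd[w:n] - c(0, csd)[1:(n - w + 1L)]
    focal <- (h + 1L):(n - h)
    data.frame(chrom = cc, pos = x$pos[focal], id = x$id[focal],
               theta = ifelse(wd > 0, wn / wd, NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      id = character(0), theta = numeric(0))
  attr(out, "w") <- w
  class(out) <- c("theta_track", "data.frame")
  out
}

# Assemble the inputs of the compiled kernel from a genotype matrix:
# complete-case polymorphic loci only (the usable set is then invariant
# under permutation of design labels).
perm_inputs <- function(genotypes, design) {
  design <- design_match(design, rownames(genotypes$dosage))
  Y <- gamete_matrix(genotypes)
  complete <- colSums(is.na(Y)) == 0L
  poly <- complete
  cs <- colSums(Y[, complete, drop = FALSE])
  poly[complete] <- cs > 0L & cs < nrow(Y)
  Yp <- Y[, poly, drop = FALSE]
  ec <- ems_constants(design)
  chrom_codes <- as.integer(factor(genotypes$map$chrom,
                                   levels = unique(genotypes$map$chrom))) - 1L
  list(Y = Yp, keep = poly, chrom = chrom_codes[poly], ec = ec,
       map = genotypes$map[poly, , drop = FALSE])
}

#' Genome-wide permutation threshold for the windowed theta scan
#'
#' Design labels are shuffled once genome-wide per permutation -- either at
#' gamete level (each allele copy independently receives a design slot) or
#' at individual level (samples keep their two gametes together,
#' preserving the within-individual covariance). After each shuffle the
#' windowed theta is evaluated at every focal SNP and the genome-wide
#' maximum recorded. The critical value at genome-wide p-value `gwp` is
#' the ceiling(gwp * n)-th largest recorded maximum. With `mode = "both"`
#' the larger critical value of the two permutation schemes is used.
#'
#' Only complete-case polymorphic loci enter the permutation scan, so the
#' scored locus set is identical in every permutation.
#'
#' @param genotypes a [genotype_matrix()].
#' @param design optional [study_design()].
#' @param w odd window size.
#' @param n_permutations number of permutations per mode.
#' @param gwp genome-wide p-value in (0, 1).
#' @param mode "gamete", "individual" or "both".
#' @param seed integer seed.
#' @return A `permutation_result`: per-mode maxima vectors, per-mode
#'   critical values, and the final `critical_theta`.
#' @export
genome_permutation_threshold <- function(genotypes, design = genotypes$design,
                                         w = 7L, n_permutations = 2000L,
                                         gwp = 0.01,
                                         mode = c("both", "gamete", "individual"),
                                         seed = 1L) {
  mode <- match.arg(mode)
  if (gwp <= 0 || gwp > 1) stop("gwp must lie in (0, 1]")
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  if (n_permutations < 1 / gwp)
    warning("n_permutations < 1/gwp: the requested quantile is the sample maximum")
  pi <- perm_inputs(genotypes, design)
  ec <- pi$ec
  if (ec$n_gametes < ec$n_samples) stop("fewer gametes than design labels")
  g_s <- as.numeric(table(ec$samp))
  n_c <- as.numeric(table(ec$cell_of_samp[ec$samp]))
  n_l <- as.numeric(table(ec$line_of_cell[ec$cell_of_samp[ec$samp]]))
  run_mode <- function(m, s) {
    set.seed(s)
    perm_max_theta_core(pi$Y, ec$samp - 1L, ec$cell_of_samp - 1L,
                        ec$line_of_cell - 1L, g_s, n_c, n_l,
                        as.numeric(ec$df), as.numeric(ec$coef),
                        pi$chrom, as.integer(w), as.integer(n_permutations),
                        if (m == "gamete") 0L else 1L)
  }
  modes <- if (mode == "both") c("gamete", "individual") else mode
  maxima <- list()
  crit <- numeric(0)
  for (i in seq_along(modes)) {
    mx <- run_mode(modes[i], seed + i - 1L)
    maxima[[modes[i]]] <- mx
    crit[modes[i]] <- critical_from_maxima(mx, gwp)
  }
  structure(list(maxima = maxima, critical_by_mode = crit,
                 critical_theta = max(crit), n_permutations = n_permutations,
                 mode = mode, gwp = gwp, w = w),
            class = "permutation_result")
}

# k-th largest recorded maximum with k = ceiling(gwp * n)
critical_from_maxima <- function(maxima, gwp) {
  k <- ceiling(gwp * length(maxima))
  k <- min(max(k, 1L), length(maxima))
  sort(maxima, decreasing = TRUE)[k]
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation_result:", x$n_permutations, "permutations, mode", x$mode,
      "; critical theta at GWp", x$gwp, "=", signif(x$critical_theta, 5), "\n")
  invisible(x)
}

#' Call signatures of selection
#'
#' Focal SNPs whose windowed theta strictly exceeds the threshold, sorted
#' by chromosome and position.
#'
#' @param theta_track a [windowed_theta()] track.
#' @param threshold critical theta (e.g. from
#'   [genome_permutation_threshold()], or a `permutation_result`).
#' @return A `signature_calls` data frame: `chrom`, `pos`, `id`, `theta`,
#'   `threshold`.
#' @export
call_signatures <- function(theta_track, threshold) {
  if (inherits(threshold, "permutation_result"))
    threshold <- threshold$critical_theta
  if (!is.finite(threshold)) stop("threshold must be finite")
  hit <- !is.na(theta_track$theta) & theta_track$theta > threshold
  out <- theta_track[hit, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  out$threshold <- if (nrow(out)) threshold else numeric(0)
  rownames(out) <- NULL
  class(out) <- c("signature_calls", "data.frame")
  out
}

#' Genome-wide average Fst between the line pair
#'
#' Per-locus two-population theta computed from pooled line frequencies
#' (reads as allele samples; one-level ANOVA, no replicate stratum),
#' averaged genome-wide as a ratio of sums. Within-replicate values
#' contrast the high and low line of one replicate; the across-replicate
#' value first averages each line's SNP frequencies over its replicates --
#' so loci drifting in opposite directions in the two replicates cancel
#' before Fst is computed.
#'
#' @param freqs a `frequency_table` from [estimate_allele_frequency()]
#'   with both lines in every replicate.
#' @return A data frame with one row per scope (each replicate, then
#'   `across`) and columns `scope`, `fst`, `n_loci`.
#' @export
pairwise_fst_summary <- function(freqs) {
  cells <- freqs$cells
  lines <- unique(cells$line)
  if (length(lines) != 2L) stop("pairwise Fst needs exactly two lines")
  reps <- unique(cells$replicate)
  row_of <- function(l, r) which(cells$line == l & cells$replicate == r)
  out <- lapply(reps, function(r) {
    i1 <- row_of(lines[1], r); i2 <- row_of(lines[2], r)
    if (length(i1) != 1L || length(i2) != 1L)
      stop("frequency table incomplete for replicate ", r)
    fst2 <- fst_ratio_of_sums(freqs$freq[i1, ], freqs$freq[i2, ],
                              freqs$n_reads[i1, ], freqs$n_reads[i2, ])
    data.frame(scope = paste0("replicate", r), fst = fst2$fst,
               n_loci = fst2$n_loci, stringsAsFactors = FALSE)
  })
  # across replicates: average frequencies per line over replicates first
  f_line <- lapply(lines, function(l) {
    rows <- which(cells$line == l)
    colMeans(freqs$freq[rows, , drop = FALSE])
  })
  n_line <- lapply(lines, function(l) {
    rows <- which(cells$line == l)
    colSums(freqs$n_reads[rows, , drop = FALSE])
  })
  acr <- fst_ratio_of_sums(f_line[[1]], f_line[[2]], n_line[[1]], n_line[[2]])
  rbind(do.call(rbind, out),
        data.frame(scope = "across", fst = acr$fst, n_loci = acr$n_loci,
                   stringsAsFactors = FALSE))
}

# Two-population intra-class correlation from pooled frequencies p1, p2
# with allele sample sizes n1, n2 (read totals), combined over loci as a
# ratio of sums. Plug-in estimator: the between-line mean square is not
# noise-corrected, so exactly equal tables give exactly 0 and divergent
# fixation gives exactly 1; the small upward bias is O(1/reads per cell).
fst_ratio_of_sums <- function(p1, p2, n1, n2) {
  ok <- !is.na(p1) & !is.na(p2) & n1 > 1 & n2 > 1
  p1 <- p1[ok]; p2 <- p2[ok]; n1 <- n1[ok]; n2 <- n2[ok]
  poly <- (p1 + p2) > 0 & (p1 + p2) < 2
  p1 <- p1[poly]; p2 <- p2[poly]; n1 <- n1[poly]; n2 <- n2[poly]
  if (!length(p1)) return(list(fst = NA_real_, n_loci = 0L))
  N <- n1 + n2
  pbar <- (n1 * p1 + n2 * p2) / N
  MSB <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2          # df = 1
  SSW <- n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)
  MSW <- SSW / (N - 2)
  nc <- (N - (n1^2 + n2^2) / N)                            # df = 1
  sb <- MSB / nc
  sw <- MSW
  list(fst = sum(sb) / sum(sb + sw), n_loci = length(p1))
}

#' End-to-end theta scan
#'
#' Convenience wrapper: variance components, windowed theta, permutation
#' threshold and signature calls in one step.
#'
#' @inheritParams genome_permutation_threshold
#' @return list with `components`, `track`, `perm`, `signatures`.
#' @export
theta_scan <- function(genotypes, design = genotypes$design, w = 7L,
                       n_permutations = 2000L, gwp = 0.01,
                       mode = "both", seed = 1L) {
  comp <- locus_variance_components(genotypes, design)
  track <- windowed_theta(comp, w)
  perm <- genome_permutation_threshold(genotypes, design, w = w,
                                       n_permutations = n_permutations,
                                       gwp = gwp, mode = mode, seed = seed)
  sig <- call_signatures(track, perm)
  list(components = comp, track = track, perm = perm, signatures = sig)
}

#' Write a theta track or signature table as TSV
#' @param x a `theta_track` or `signature_calls`.
#' @param path file path.
#' @export
write_track <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
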