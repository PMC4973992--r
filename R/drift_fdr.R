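#' Count divergently fixed/lost loci within and across replicates
#'
#' A locus is counted for a replicate when the two lines are fixed for
#' alternate alleles there (non-reference frequency exactly 1 in one line
#' and 0 in the other: divergent fixation). The across-replicates count
#' requires divergent fixation in the same direction in both replicates.
#' `mode = "either_line"` instead counts loci where at least one line of
#' the pair is monomorphic (a looser reading of "fixed or lost").
#' Genome-wide Fst for each scope comes from [pairwise_fst_summary()].
#'
#' @param freqs a `frequency_table` with both lines in each replicate.
#' @param mode "divergent" (default) or "either_line".
#' @return A `fixation_counts` data frame: `scope`, `n_fixed`, `fst`.
#' @export
count_fixed_lost <- function(freqs, mode = c("divergent", "either_line")) {
  mode <- match.arg(mode)
  cells <- freqs$cells
  lines <- unique(cells$line)
  if (length(lines) != 2L) stop("need exactly two lines")
  reps <- unique(cells$replicate)
  fst <- pairwise_fst_summary(freqs)
  per_rep <- lapply(reps, function(r) {
    f1 <- freqs$freq[cells$line == lines[1] & cells$replicate == r, ]
    f2 <- freqs$freq[cells$line == lines[2] & cells$replicate == r, ]
    ok <- !is.na(f1) & !is.na(f2)
    if (mode == "divergent") {
      dir <- ifelse(ok & f1 == 1 & f2 == 0, 1L,
                    ifelse(ok & f1 == 0 & f2 == 1, -1L, 0L))
    } else {
      dir <- ifelse(ok & (f1 %in% c(0, 1) | f2 %in% c(0, 1)) & f1 != f2,
                    sign(f1 - f2), 0L)
      dir[!ok] <- 0L
    }
    dir
  })
  n_within <- vapply(per_rep, function(d) sum(d != 0L), numeric(1))
  n_across <- if (length(reps) >= 2L)
    sum(per_rep[[1]] != 0L & per_rep[[1]] == per_rep[[2]]) else NA_real_
  out <- data.frame(
    scope = c(paste0("replicate", reps), "across"),
    n_fixed = c(n_within, n_across),
    fst = fst$fst[match(c(paste0("replicate", reps), "across"), fst$scope)])
  class(out) <- c("fixation_counts", "data.frame")
  out
}

#' Drift regression and false discovery rate of fixed/lost alleles
#'
#' Fits `Lost = b0 + b1 * Fst + e` by ordinary least squares to the
#' per-scope (Fst, count) points. Under drift alone the count of fixed or
#' lost alleles is proportional to the genome-wide Fst and the intercept
#' is zero; the fitted intercept `b0` therefore estimates the number of
#' alleles fixed by selection, and `FDR = (N - b0)/N` is, per scope, the
#' fraction of fixed/lost alleles attributable to selection. FDRs are
#' clamped to [0, 1] with a warning and also reported rounded to the
#' nearest percent.
#'
#' @param points data frame with columns `fst` and `n_fixed` (a
#'   `fixation_counts` works directly), one row per scope.
#' @return A `drift_fit`: `b0`, `b1`, `se_b0`, and a `table` with per-scope
#'   `fdr` and `fdr_pct`.
#' @export
drift_regression <- function(points) {
  pts <- as.data.frame(points)
  if (!all(c("fst", "n_fixed") %in% names(pts)))
    stop("points must have columns fst and n_fixed")
  pts <- pts[!is.na(pts$fst) & !is.na(pts$n_fixed), , drop = FALSE]
  if (nrow(pts) < 3L) stop("need at least 3 (Fst, count) points")
  if (length(unique(pts$fst)) < 2L)
    stop("need at least 2 distinct Fst values to fit the drift line")
  fit <- stats::lm(n_fixed ~ fst, data = pts)
  b0 <- unname(coef(fit)[1]); b1 <- unname(coef(fit)[2])
  se_b0 <- suppressWarnings(summary(fit)$coefficients[1, 2])
  fdr <- (pts$n_fixed - b0) / pts$n_fixed
  clamped <- pmin(pmax(fdr, 0), 1)
  if (any(fdr != clamped))
    warning("FDR outside [0, 1] clamped (intercept exceeds a count)")
  tab <- data.frame(scope = if (!is.null(pts$scope)) pts$scope else
    paste0("point", seq_len(nrow(pts))),
    fst = pts$fst, n_fixed = pts$n_fixed,
    fdr = clamped, fdr_pct = round(100 * clamped))
  structure(list(b0 = b0, b1 = b1, se_b0 = se_b0, table = tab, fit = fit),
            class = "drift_fit")
}

#' @export
print.drift_fit <- function(x, ...) {
  cat(sprintf("drift_fit: b0 = %.0f +/- %.0f (alleles fixed by selection), b1 = %.0f per unit Fst\n",
              x$b0, x$se_b0, x$b1))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Heterozygote miscall probability at a given depth
#'
#' With `depth` reads from a true heterozygote, each read samples either
#' allele with probability 1/2; the genotype is miscalled as a homozygote
#' exactly when all reads agree: `2 * (1/2)^depth`. At the 5x depth
#' typical of shallow designs this is 6.25% -- the dominant genotyping
#' error, which inflates the within-sample gamete variance (denominator)
#' but leaves between-line frequency contrasts unbiased.
#'
#' @param depth read count (>= 1).
#' @return probability in (0, 1].
#' @export
het_miscall_rate <- function(depth) {
  if (any(depth < 1)) stop("depth must be >= 1")
  2 * 0.5^depth
}
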