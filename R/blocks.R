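#' Four-gamete-rule haplotype blocks
#'
#' Partitions each chromosome into haplotype blocks separated by evidence
#' of historical recombination. Scanning left to right, the incoming locus
#' is compared with every locus already in the open block; a gamete is
#' "observed" when its estimated frequency exceeds the minor gamete
#' frequency threshold `mgf`. When all four gametes are observed against
#' any block member, at least one recombination event must separate the
#' pair: the block closes and the incoming locus starts a new one.
#'
#' Gamete frequencies come from the EM estimator for unphased genotype
#' input, or from direct counting for phased haplotype input (e.g. pooled
#' inbred founder lines, or simulator truth). Only polymorphic loci are
#' scanned: a monomorphic locus can never show four gametes.
#'
#' @param x a [genotype_matrix()], or a phased 0/1 haplotype matrix (rows =
#'   haplotypes) with `map` supplied.
#' @param mgf minor gamete frequency threshold (default 0.09).
#' @param map locus map (chrom, pos) -- required for matrix input.
#' @return A `haplotype_blocks` data frame: `chrom`, `start`, `end` (bp of
#'   first/last member SNP), `n_loci`, with attributes `mgf` and
#'   `median_bp` (median block span among multi-SNP blocks).
#' @export
four_gamete_blocks <- function(x, mgf = 0.09, map = NULL) {
  UseMethod("four_gamete_blocks")
}

#' @export
four_gamete_blocks.genotype_matrix <- function(x, mgf = 0.09, map = NULL) {
  d <- x$dosage
  poly <- apply(d, 2, function(v) {
    m <- mean(v, na.rm = TRUE); !is.na(m) && m > 0 && m < 2
  })
  min_g <- function(i, j) {
    t <- em_gamete_frequencies(d[, i], d[, j])
    min(t$p)
  }
  fgr_blocks(x$map, which(poly), min_g, mgf)
}

#' @export
four_gamete_blocks.matrix <- function(x, mgf = 0.09, map = NULL) {
  if (is.null(map)) stop("phased matrix input needs a locus map")
  poly <- apply(x, 2, function(v) {
    m <- mean(v, na.rm = TRUE); !is.na(m) && m > 0 && m < 1
  })
  min_g <- function(i, j) min(count_gametes_phased(x[, i], x[, j])$p)
  fgr_blocks(map, which(poly), min_g, mgf)
}

# Greedy left-to-right block extension over the polymorphic loci `idx`
# (map row indices). min_g(i, j) returns the smallest of the four gamete
# frequencies for a locus pair; a cache makes repeated calls (e.g. the
# MGF grid search) cheap.
fgr_blocks <- function(map, idx, min_g, mgf, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  lookup <- function(i, j) {
    key <- paste0(i, "_", j)
    v <- cache[[key]]
    if (is.null(v)) {
      v <- min_g(i, j)
      cache[[key]] <- v
    }
    v
  }
  blocks <- list()
  for (cc in unique(map$chrom)) {
    ci <- idx[map$chrom[idx] == cc]
    if (!length(ci)) next
    members <- ci[1L]
    for (j in ci[-1L]) {
      recomb <- FALSE
      for (i in members) {       # earliest member first: most diverged
        if (lookup(i, j) > mgf) { recomb <- TRUE; break }
      }
      if (recomb) {
        blocks[[length(blocks) + 1L]] <-
          data.frame(chrom = cc, start = map$pos[members[1L]],
                     end = map$pos[members[length(members)]],
                     n_loci = length(members), stringsAsFactors = FALSE)
        members <- j
      } else members <- c(members, j)
    }
    blocks[[length(blocks) + 1L]] <-
      data.frame(chrom = cc, start = map$pos[members[1L]],
                 end = map$pos[members[length(members)]],
                 n_loci = length(members), stringsAsFactors = FALSE)
  }
  out <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_loci = integer(0))
  attr(out, "mgf") <- mgf
  multi <- out$n_loci > 1L
  attr(out, "median_bp") <- if (any(multi))
    stats::median(out$end[multi] - out$start[multi] + 1L) else NA_real_
  attr(out, "cache") <- cache
  class(out) <- c("haplotype_blocks", "data.frame")
  out
}

#' Search the MGF grid for a near-continuous block spine
#'
#' Raising the minor gamete frequency threshold makes recombination
#' evidence stricter and blocks larger; this search returns the smallest
#' MGF on a grid (0.05 to 0.25 by 0.01) for which at least
#' `coverage_target` of the scanned SNPs fall inside multi-SNP blocks (the
#' "near continuous spine"). If the target is unreachable on the grid the
#' best-covering MGF is returned with a warning.
#'
#' @inheritParams four_gamete_blocks
#' @param coverage_target fraction of SNPs that must sit in multi-SNP
#'   blocks (default 0.95).
#' @param grid MGF grid to scan.
#' @return list: `mgf`, `blocks`, `coverage`, and the full `grid_coverage`
#'   table.
#' @export
spine_mgf_search <- function(x, coverage_target = 0.95,
                             grid = seq(0.05, 0.25, by = 0.01), map = NULL) {
  if (inherits(x, "genotype_matrix")) {
    d <- x$dosage; map <- x$map
    poly <- apply(d, 2, function(v) {
      m <- mean(v, na.rm = TRUE); !is.na(m) && m > 0 && m < 2
    })
    min_g <- function(i, j) min(em_gamete_frequencies(d[, i], d[, j])$p)
  } else {
    if (is.null(map)) stop("phased matrix input needs a locus map")
    poly <- apply(x, 2, function(v) {
      m <- mean(v, na.rm = TRUE); !is.na(m) && m > 0 && m < 1
    })
    min_g <- function(i, j) min(count_gametes_phased(x[, i], x[, j])$p)
  }
  idx <- which(poly)
  if (!length(idx)) stop("no polymorphic loci to scan")
  cache <- new.env(parent = emptyenv())
  best <- NULL; cov_tab <- NULL
  for (m in sort(grid)) {
    b <- fgr_blocks(map, idx, min_g, m, cache = cache)
    cov <- sum(b$n_loci[b$n_loci > 1L]) / sum(b$n_loci)
    cov_tab <- rbind(cov_tab, data.frame(mgf = m, coverage = cov))
    if (is.null(best) || cov > best$coverage)
      best <- list(mgf = m, blocks = b, coverage = cov)
    if (cov >= coverage_target)
      return(list(mgf = m, blocks = b, coverage = cov,
                  grid_coverage = cov_tab))
  }
  warning(sprintf(
    "spine coverage target %.2f unreachable on the MGF grid; best %.3f at mgf %.2f",
    coverage_target, best$coverage, best$mgf))
  list(mgf = best$mgf, blocks = best$blocks, coverage = best$coverage,
       grid_coverage = cov_tab)
}

#' Export haplotype blocks as BED (0-based half-open)
#' @param blocks a `haplotype_blocks` table.
#' @param path output path.
#' @export
write_blocks_bed <- function(blocks, path) {
  bed <- data.frame(chrom = blocks$chrom, start = blocks$start - 1L,
                    end = blocks$end, name = paste0("HB", seq_len(nrow(blocks))),
                    score = blocks$n_loci)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
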