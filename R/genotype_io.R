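#' Genotype matrix container
#'
#' Dosage of the non-reference allele (0, 1, 2 or NA) per sample x locus,
#' together with the locus map and the [study_design()]. Positions must be
#' strictly increasing within each chromosome.
#'
#' @param dosage integer matrix, samples in rows (rownames = sample ids),
#'   loci in columns.
#' @param map data frame with columns `chrom`, `pos` and optionally `id`,
#'   `ref`, `alt`, one row per locus.
#' @param design a [study_design()] covering all samples.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosage, map, design) {
  dosage <- as.matrix(dosage)
  if (ncol(dosage) != nrow(map)) stop("dosage columns must match map rows")
  if (is.null(map$id)) map$id <- paste0(map$chrom, "_", map$pos)
  if (is.null(map$ref)) map$ref <- "A"
  if (is.null(map$alt)) map$alt <- "T"
  check_map_sorted(map)
  if (!all(dosage %in% c(0L, 1L, 2L, NA)))
    stop("dosages must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "integer"
  colnames(dosage) <- map$id
  if (is.null(rownames(dosage))) stop("dosage must carry sample rownames")
  design <- design_match(design, rownames(dosage))
  structure(list(dosage = dosage, map = map, design = design),
            class = "genotype_matrix")
}

check_map_sorted <- function(map) {
  for (c in unique(map$chrom)) {
    p <- map$pos[map$chrom == c]
    if (any(diff(p) <= 0))
      stop("locus positions must be strictly increasing within chromosome ", c)
  }
  invisible(map)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "loci on", length(unique(x$map$chrom)), "chromosome(s);",
      sum(is.na(x$dosage)), "missing calls\n")
  invisible(x)
}

#' Read count matrix container
#'
#' Non-reference (`nr`) and total read counts per sample x locus; the raw
#' material for pooled allele-frequency estimation and genotype calling.
#'
#' @param nr,total integer matrices (samples x loci), `0 <= nr <= total`.
#' @param map locus map as in [genotype_matrix()].
#' @param design a [study_design()].
#' @return A `read_count_matrix` object.
#' @export
read_count_matrix <- function(nr, total, map, design) {
  nr <- as.matrix(nr); total <- as.matrix(total)
  if (!identical(dim(nr), dim(total))) stop("nr and total must match in shape")
  if (is.null(rownames(nr))) rownames(nr) <- rownames(total)
  if (ncol(nr) != nrow(map)) stop("count columns must match map rows")
  bad <- which(!is.na(nr) & (nr < 0 | nr > total))
  if (length(bad)) stop("read counts violate 0 <= nr <= total")
  if (is.null(map$id)) map$id <- paste0(map$chrom, "_", map$pos)
  check_map_sorted(map)
  storage.mode(nr) <- "integer"; storage.mode(total) <- "integer"
  colnames(nr) <- colnames(total) <- map$id
  design <- design_match(design, rownames(nr))
  structure(list(nr = nr, total = total, map = map, design = design),
            class = "read_count_matrix")
}

#' @export
print.read_count_matrix <- function(x, ...) {
  cat("read_count_matrix:", nrow(x$nr), "samples x", ncol(x$nr),
      "loci; mean depth", round(mean(x$total), 2), "\n")
  invisible(x)
}

dosage_to_gt <- function(d) {
  gt <- matrix("./.", nrow(d), ncol(d), dimnames = dimnames(d))
  gt[!is.na(d) & d == 0L] <- "0/0"
  gt[!is.na(d) & d == 1L] <- "0/1"
  gt[!is.na(d) & d == 2L] <- "1/1"
  gt
}

gt_to_dosage <- function(gt) {
  clean <- gsub("\\|", "/", gt)
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  d[clean %in% c("0/0")] <- 0L
  d[clean %in% c("0/1", "1/0")] <- 1L
  d[clean %in% c("1/1")] <- 2L
  unknown <- !(clean %in% c("0/0", "0/1", "1/0", "1/1", "./.", "."))
  if (any(unknown))
    stop("unsupported genotype strings in VCF: ",
         paste(unique(clean[unknown]), collapse = ", "))
  d
}

#' Write genotypes to VCF v4.2
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output path (plain-text `.vcf`).
#' @export
write_vcf <- function(genotypes, path) {
  map <- genotypes$map
  d <- genotypes$dosage
  rr <- GenomicRanges::GRanges(map$chrom, IRanges::IRanges(map$pos, width = 1L))
  names(rr) <- map$id
  samples <- rownames(d)
  hdr <- VariantAnnotation::VCFHeader(samples = samples)
  VariantAnnotation::geno(hdr) <- S4Vectors::DataFrame(
    Number = "1", Type = "String", Description = "Genotype", row.names = "GT")
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    fileformat = S4Vectors::DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
  v <- VariantAnnotation::VCF(
    rowRanges = rr,
    colData = S4Vectors::DataFrame(Samples = seq_along(samples),
                                   row.names = samples),
    exptData = list(header = hdr),
    geno = S4Vectors::SimpleList(GT = t(dosage_to_gt(d))))
  VariantAnnotation::ref(v) <- Biostrings::DNAStringSet(map$ref)
  VariantAnnotation::alt(v) <- Biostrings::DNAStringSetList(as.list(map$alt))
  VariantAnnotation::fixed(v)$QUAL <- rep(NA_real_, nrow(map))
  VariantAnnotation::fixed(v)$FILTER <- rep(".", nrow(map))
  VariantAnnotation::writeVcf(v, path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Only the GT field is used; genotypes are treated as unphased dosages of
#' the first ALT allele. Sample names must resolve against the design
#' sheet. Non-monotone positions within a chromosome are rejected.
#'
#' @param path VCF path (plain or bgzipped).
#' @param design a [study_design()] naming every VCF sample.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, design) {
  v <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(v)
  map <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                    pos = GenomicRanges::start(rr),
                    id = names(rr),
                    ref = as.character(VariantAnnotation::ref(v)),
                    alt = vapply(as.list(VariantAnnotation::alt(v)),
                                 function(a) as.character(a)[1], character(1)),
                    stringsAsFactors = FALSE)
  if (nrow(map) == 0L) {
    d <- matrix(integer(0), nrow = nrow(design), ncol = 0,
                dimnames = list(design$sample, NULL))
    return(genotype_matrix(d, map[, c("chrom", "pos", "id", "ref", "alt")], design))
  }
  gt <- VariantAnnotation::geno(v)$GT
  d <- t(gt_to_dosage(gt))
  genotype_matrix(d, map, design)
}

#' Read / write read counts as long-format TSV
#'
#' Columns: `chrom`, `pos`, `sample`, `nr_reads`, `total_reads`.
#'
#' @param path TSV path.
#' @param design a [study_design()].
#' @return `read_readcounts` returns a [read_count_matrix()].
#' @export
read_readcounts <- function(path, design) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "sample", "nr_reads", "total_reads")
  if (!all(need %in% names(x)))
    stop("read-count table must have columns: ", paste(need, collapse = ", "))
  loc <- unique(x[, c("chrom", "pos")])
  loc <- loc[order(loc$chrom, loc$pos), ]
  loc$id <- paste0(loc$chrom, "_", loc$pos)
  samples <- unique(x$sample)
  li <- match(paste0(x$chrom, "_", x$pos), loc$id)
  si <- match(x$sample, samples)
  nr <- matrix(0L, length(samples), nrow(loc),
               dimnames = list(samples, loc$id))
  total <- nr
  nr[cbind(si, li)] <- as.integer(x$nr_reads)
  total[cbind(si, li)] <- as.integer(x$total_reads)
  read_count_matrix(nr, total, loc, design)
}

#' @rdname read_readcounts
#' @param reads a [read_count_matrix()].
#' @export
write_readcounts <- function(reads, path) {
  long <- data.frame(
    chrom = rep(reads$map$chrom, each = nrow(reads$nr)),
    pos = rep(reads$map$pos, each = nrow(reads$nr)),
    sample = rep(rownames(reads$nr), ncol(reads$nr)),
    nr_reads = as.vector(reads$nr),
    total_reads = as.vector(reads$total))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pooled allele frequencies per line x replicate
#'
#' The non-reference allele frequency of each design cell (line x
#' replicate) is the ratio of summed non-reference reads to summed total
#' reads over the cell's samples -- a read-pooling estimator. Cells with no
#' reads at a locus are flagged missing (NA).
#'
#' @param reads a [read_count_matrix()].
#' @param design optional [study_design()]; defaults to the one attached to
#'   `reads`.
#' @return A `frequency_table`: `freq` and `n_reads` matrices (cells x
#'   loci), `cells` (line, replicate), and the locus `map`.
#' @export
estimate_allele_frequency <- function(reads, design = reads$design) {
  design <- design_match(design, rownames(reads$nr))
  cell <- interaction(design$line, design$replicate, drop = TRUE, sep = "|")
  nr <- rowsum(ifelse(is.na(reads$nr), 0L, reads$nr), cell)
  tot <- rowsum(reads$total, cell)
  freq <- nr / tot
  freq[tot == 0] <- NA_real_
  cells <- do.call(rbind, strsplit(rownames(nr), "|", fixed = TRUE))
  frequency_table(freq, tot,
                  data.frame(line = cells[, 1], replicate = cells[, 2],
                             stringsAsFactors = FALSE),
                  reads$map)
}

#' Frequency table container
#'
#' @param freq,n_reads matrices (cells x loci).
#' @param cells data frame with `line`, `replicate` per row of `freq`.
#' @param map locus map.
#' @return A `frequency_table`.
#' @export
frequency_table <- function(freq, n_reads, cells, map) {
  freq <- as.matrix(freq)
  if (any(freq < 0 - 1e-12 | freq > 1 + 1e-12, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  rownames(freq) <- paste(cells$line, cells$replicate, sep = "|")
  structure(list(freq = freq, n_reads = as.matrix(n_reads),
                 cells = cells, map = map),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("frequency_table:", nrow(x$freq), "line x replicate cells,",
      ncol(x$freq), "loci\n")
  invisible(x)
}

#' Call genotypes from read counts
#'
#' Dosage 0 when only reference reads reach `min_reads_per_allele`, 2 when
#' only non-reference reads do, 1 when both alleles are supported, NA when
#' neither is (in particular when there are no reads). With the default
#' threshold of one read an observed two-allele locus is never converted
#' into a homozygote; with shallow depth true heterozygotes are still
#' miscalled as homozygotes whenever one allele goes unsampled (see
#' [het_miscall_rate()]).
#'
#' @param reads a [read_count_matrix()].
#' @param min_reads_per_allele minimum reads to accept an allele (default 1).
#' @return A [genotype_matrix()].
#' @export
call_genotypes <- function(reads, min_reads_per_allele = 1L) {
  nr <- reads$nr; total <- reads$total
  ref <- total - nr
  d <- matrix(NA_integer_, nrow(nr), ncol(nr), dimnames = dimnames(nr))
  has_nr <- !is.na(nr) & nr >= min_reads_per_allele
  has_ref <- !is.na(nr) & ref >= min_reads_per_allele
  d[has_nr & has_ref] <- 1L
  d[has_nr & !has_ref] <- 2L
  d[!has_nr & has_ref] <- 0L
  # cells with reads but neither allele reaching the threshold stay NA
  genotype_matrix(d, reads$map, reads$design)
}

#' Locus filters for shallow multi-sample sequencing
#'
#' Two screens applied to summed counts over all samples: (1) a depth cap
#' removing loci whose total reads exceed `depth_cap_multiple` times the
#' expected total (possible copy-number artifacts); (2) an error screen
#' removing loci whose pooled non-reference reads fall below `error_rate`
#' of pooled total reads (indistinguishable from sequencing error).
#'
#' @param reads a [read_count_matrix()].
#' @param expected_depth expected per-sample depth.
#' @param error_rate assumed per-read error rate (default 0.003).
#' @param depth_cap_multiple multiple of the expected total depth at which
#'   a locus is discarded (default 4).
#' @return list: `reads` (filtered [read_count_matrix()]) and `report`
#'   (data frame of per-rule removal counts).
#' @export
filter_loci <- function(reads, expected_depth, error_rate = 0.003,
                        depth_cap_multiple = 4) {
  if (expected_depth <= 0) stop("expected_depth must be > 0")
  tot <- colSums(reads$total)
  nrv <- colSums(ifelse(is.na(reads$nr), 0L, reads$nr))
  cap <- depth_cap_multiple * expected_depth * nrow(reads$total)
  rm_depth <- tot > cap
  rm_err <- !rm_depth & (nrv < error_rate * tot)
  keep <- !(rm_depth | rm_err)
  report <- data.frame(rule = c("depth_cap", "error_screen", "retained"),
                       n = c(sum(rm_depth), sum(rm_err), sum(keep)))
  filtered <- read_count_matrix(reads$nr[, keep, drop = FALSE],
                                reads$total[, keep, drop = FALSE],
                                reads$map[keep, , drop = FALSE],
                                reads$design)
  list(reads = filtered, report = report)
}

#' Pool per-line frequency tables into an in-silico base population
#'
#' The pooled non-reference frequency at each locus is the unweighted mean
#' of the per-line frequencies, emulating an equal-contribution pool of the
#' founder lines. With N founder lines the smallest nonzero pooled gamete
#' frequency is 1/(2N) (a single line segregating at 0.5).
#'
#' @param line_tables list of `frequency_table`s, one per founder line
#'   (each with a single cell), all on the same locus map.
#' @return A `frequency_table` with one pooled cell.
#' @export
pool_founder_lines <- function(line_tables) {
  if (length(line_tables) < 2L) stop("need at least two line tables to pool")
  maps <- lapply(line_tables, function(t) t$map$id)
  if (!all(vapply(maps[-1], identical, logical(1), maps[[1]])))
    stop("founder line tables have mismatched locus maps")
  fmat <- do.call(rbind, lapply(line_tables, function(t) t$freq[1, ]))
  nmat <- do.call(rbind, lapply(line_tables, function(t) t$n_reads[1, ]))
  pooled <- colMeans(fmat)
  frequency_table(matrix(pooled, 1), matrix(colSums(nmat), 1),
                  data.frame(line = "pooled", replicate = "insilico"),
                  line_tables[[1]]$map)
}
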