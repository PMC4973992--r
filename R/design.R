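#' Study design for a replicated two-line experiment
#'
#' Describes which selected line and which replicate every sequenced sample
#' belongs to. Each diploid sample contributes two exchangeable gametes to
#' the nested variance decomposition, so the design expands internally to
#' one row per allele copy.
#'
#' @param sample character vector of unique sample identifiers.
#' @param line line label per sample (e.g. "high"/"low"); coerced to factor.
#' @param replicate replicate label per sample; coerced to factor.
#' @return A `study_design` data frame with columns `sample`, `line`,
#'   `replicate`.
#' @examples
#' study_design(paste0("s", 1:4), rep(c("high", "low"), each = 2), c(1, 1, 1, 1))
#' @export
study_design <- function(sample, line, replicate) {
  if (anyDuplicated(sample)) stop("duplicate sample identifiers in design")
  if (length(sample) != length(line) || length(sample) != length(replicate))
    stop("sample, line and replicate must have equal length")
  d <- data.frame(sample = as.character(sample),
                  line = factor(line),
                  replicate = factor(replicate),
                  stringsAsFactors = FALSE)
  if (nlevels(d$line) < 1L || nlevels(d$replicate) < 1L)
    stop("design needs at least one line and one replicate")
  if (any(is.na(d$line)) || any(is.na(d$replicate)))
    stop("design labels must not be missing")
  class(d) <- c("study_design", "data.frame")
  d
}

#' @export
print.study_design <- function(x, ...) {
  cat("study_design:", nrow(x), "samples,",
      nlevels(x$line), "lines x", nlevels(x$replicate), "replicates\n")
  print(table(line = x$line, replicate = x$replicate))
  invisible(x)
}

is_study_design <- function(x) inherits(x, "study_design")

#' Read / write a design sheet
#'
#' The design sheet is a TSV with columns `sample`, `line`, `replicate`.
#'
#' @param path file path.
#' @return `read_design` returns a [study_design()].
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "line", "replicate")
  if (!all(need %in% names(d)))
    stop("design sheet must have columns: ", paste(need, collapse = ", "))
  study_design(d$sample, d$line, d$replicate)
}

#' @rdname read_design
#' @param design a [study_design()].
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Expand a sample-level design to gamete level (two rows per sample).
# Gametes within a sample are exchangeable; their order never matters for
# any statistic in the package.
gamete_design <- function(design) {
  idx <- rep(seq_len(nrow(design)), each = 2L)
  data.frame(sample = design$sample[idx],
             line = design$line[idx],
             replicate = design$replicate[idx],
             gamete = rep(1:2, times = nrow(design)),
             sample_index = idx,
             stringsAsFactors = FALSE)
}

# Match design rows to a vector of sample names, erroring on unknowns.
design_match <- function(design, samples) {
  i <- match(samples, design$sample)
  if (anyNA(i)) stop("samples missing from design sheet: ",
                     paste(samples[is.na(i)], collapse = ", "))
  d <- design[i, , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("study_design", "data.frame")
  d
}
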