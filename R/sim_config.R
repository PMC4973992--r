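#' Configuration for the synthetic selection experiment
#'
#' Collects every knob of the forward-time simulator: the multi-parent
#' (MAGIC) base population, the replicated bidirectional within-family
#' truncation selection, and the shallow read-count sequencing layer.
#' Defaults describe the experimental world the scan is designed for:
#' an 8-founder base, two replicate line pairs, 40 generations of selection
#' within 60 generations total, 10 sequenced individuals per line and
#' replicate, ~5x depth and a 0.3% per-read error rate.
#'
#' @param n_founders number of fully inbred founder lines (default 8).
#' @param n_chromosomes number of chromosomes simulated.
#' @param loci_per_chromosome SNP loci per chromosome.
#' @param chromosome_length chromosome length in bp.
#' @param recombination_rate Morgans per bp (default 1e-8, i.e. 1 cM/Mb).
#' @param n_causal_loci number of trait loci (default 20).
#' @param effect_sizes additive allele effect, scalar or one per causal
#'   locus, in trait units per allele copy.
#' @param heritability narrow-sense h^2 of the trait in the base population.
#' @param n_generations_selected generations with truncation selection on
#'   (default 40).
#' @param n_generations_total total generations bred before sequencing
#'   (default 60); generations beyond `n_generations_selected` use relaxed
#'   (random within-line) mating.
#' @param families_per_line breeding pairs maintained per line (default 25;
#'   with within-family selection this gives an effective size near 100,
#'   which over 60 generations produces within-replicate differentiation of
#'   the magnitude the scan targets).
#' @param offspring_per_family offspring scored per family per generation.
#' @param n_replicates independent replicate line pairs (default 2).
#' @param n_sequenced_per_line individuals sequenced per line x replicate.
#' @param mean_depth mean sequencing depth per sample per site (default 5).
#' @param read_error_rate per-read allele flip probability (default 0.003).
#' @param n_base size of the MAGIC base population.
#' @param n_generations_intercross random-mating generations used to mix the
#'   founders into the MAGIC base (default 10).
#' @param founder_ld_fraction fraction of adjacent locus pairs whose founder
#'   allele patterns are drawn independently (and therefore tend to show all
#'   four gametes already among the founders); the remaining pairs copy a
#'   correlated pattern, emulating shared ancestral haplotypes.
#' @param seed integer master seed; all replicate streams derive from it.
#' @return A validated `sim_config` list.
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, loci_per_chromosome = 50)
#' @export
sim_config <- function(n_founders = 8L,
                       n_chromosomes = 2L,
                       loci_per_chromosome = 2500L,
                       chromosome_length = 1e7,
                       recombination_rate = 1e-8,
                       n_causal_loci = 20L,
                       effect_sizes = 1,
                       heritability = 0.3,
                       n_generations_selected = 40L,
                       n_generations_total = 60L,
                       families_per_line = 25L,
                       offspring_per_family = 4L,
                       n_replicates = 2L,
                       n_sequenced_per_line = 10L,
                       mean_depth = 5,
                       read_error_rate = 0.003,
                       n_base = 240L,
                       n_generations_intercross = 10L,
                       founder_ld_fraction = 0.75,
                       seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_chromosomes = as.integer(n_chromosomes),
              loci_per_chromosome = as.integer(loci_per_chromosome),
              chromosome_length = as.numeric(chromosome_length),
              recombination_rate = as.numeric(recombination_rate),
              n_causal_loci = as.integer(n_causal_loci),
              effect_sizes = as.numeric(effect_sizes),
              heritability = as.numeric(heritability),
              n_generations_selected = as.integer(n_generations_selected),
              n_generations_total = as.integer(n_generations_total),
              families_per_line = as.integer(families_per_line),
              offspring_per_family = as.integer(offspring_per_family),
              n_replicates = as.integer(n_replicates),
              n_sequenced_per_line = as.integer(n_sequenced_per_line),
              mean_depth = as.numeric(mean_depth),
              read_error_rate = as.numeric(read_error_rate),
              n_base = as.integer(n_base),
              n_generations_intercross = as.integer(n_generations_intercross),
              founder_ld_fraction = as.numeric(founder_ld_fraction),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field, min = 1L) {
    v <- cfg[[field]]
    if (length(v) != 1L || is.na(v) || v < min)
      stop("invalid sim_config field '", field, "': must be a count >= ", min)
  }
  for (f in c("n_founders", "n_chromosomes", "loci_per_chromosome",
              "n_generations_total", "families_per_line",
              "offspring_per_family", "n_replicates",
              "n_sequenced_per_line", "n_base"))
    chk_count(f)
  chk_count("n_generations_selected", 0L)
  chk_count("n_generations_intercross", 0L)
  chk_count("n_causal_loci", 0L)
  if (cfg$families_per_line < 2L)
    stop("invalid sim_config field 'families_per_line': rotational mating needs >= 2 families")
  if (cfg$offspring_per_family < 2L)
    stop("invalid sim_config field 'offspring_per_family': selection needs >= 2 offspring")
  if (cfg$heritability < 0 || cfg$heritability > 1 || is.na(cfg$heritability))
    stop("invalid sim_config field 'heritability': must lie in [0, 1]")
  if (cfg$recombination_rate < 0)
    stop("invalid sim_config field 'recombination_rate': must be >= 0")
  if (cfg$mean_depth < 0)
    stop("invalid sim_config field 'mean_depth': must be >= 0")
  if (cfg$read_error_rate < 0 || cfg$read_error_rate >= 1)
    stop("invalid sim_config field 'read_error_rate': must lie in [0, 1)")
  if (cfg$chromosome_length <= 0)
    stop("invalid sim_config field 'chromosome_length': must be > 0")
  if (cfg$n_causal_loci > cfg$n_chromosomes * cfg$loci_per_chromosome)
    stop("invalid sim_config field 'n_causal_loci': exceeds total loci")
  if (!length(cfg$effect_sizes) %in% c(1L, max(cfg$n_causal_loci, 1L)))
    stop("invalid sim_config field 'effect_sizes': length must be 1 or n_causal_loci")
  if (cfg$n_generations_selected > cfg$n_generations_total)
    stop("invalid sim_config field 'n_generations_selected': exceeds n_generations_total")
  if (cfg$founder_ld_fraction < 0 || cfg$founder_ld_fraction > 1)
    stop("invalid sim_config field 'founder_ld_fraction': must lie in [0, 1]")
  if (cfg$n_base < 2L * cfg$families_per_line)
    stop("invalid sim_config field 'n_base': need >= 2 * families_per_line individuals")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_founders, "founders;",
      x$n_chromosomes, "chromosomes x", x$loci_per_chromosome, "loci;",
      x$n_replicates, "replicates;",
      x$n_generations_selected, "of", x$n_generations_total,
      "generations selected;", x$n_sequenced_per_line,
      "sequenced/line at", x$mean_depth, "x\n")
  invisible(x)
}

#' Write / read a simulator configuration as a flat key-value file
#'
#' Uses Debian-control (DCF) formatting, one `key: value` per line.
#'
#' @param cfg a [sim_config()].
#' @param path file path.
#' @export
write_sim_config <- function(cfg, path) {
  flat <- vapply(cfg, function(v) paste(format(v, digits = 17), collapse = ","),
                 character(1))
  write.dcf(matrix(flat, nrow = 1, dimnames = list(NULL, names(cfg))), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  m <- read.dcf(path)
  vals <- lapply(colnames(m), function(k) {
    v <- strsplit(m[1, k], ",")[[1]]
    as.numeric(v)
  })
  names(vals) <- colnames(m)
  do.call(sim_config, vals)
}
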