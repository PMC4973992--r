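#' Pipeline configuration
#'
#' One object driving the full scan: input paths (or an in-memory
#' simulation config), scan, block and filter parameters, and the seed.
#'
#' @param outdir output directory (created if absent).
#' @param vcf,readcounts,design,gff optional input paths; when
#'   `simulate` is given, inputs are generated instead.
#' @param simulate optional [sim_config()] to generate the inputs.
#' @param w window size, or NA to calibrate from the LD decay profile.
#' @param n_permutations,gwp,perm_mode scan parameters.
#' @param mgf minor gamete frequency, or NA for [spine_mgf_search()].
#' @param expected_depth,error_rate,depth_cap_multiple locus filters
#'   (applied when read counts are the input).
#' @param overwrite allow writing into a non-empty outdir.
#' @param seed integer master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, vcf = NULL, readcounts = NULL,
                            design = NULL, gff = NULL, simulate = NULL,
                            w = NA, n_permutations = 2000L, gwp = 0.01,
                            perm_mode = "both", mgf = NA,
                            expected_depth = 5, error_rate = 0.003,
                            depth_cap_multiple = 4, overwrite = FALSE,
                            seed = 1L) {
  if (gwp <= 0 || gwp >= 1) stop("gwp must lie in (0, 1)")
  structure(list(outdir = outdir, vcf = vcf, readcounts = readcounts,
                 design = design, gff = gff, simulate = simulate, w = w,
                 n_permutations = as.integer(n_permutations), gwp = gwp,
                 perm_mode = perm_mode, mgf = mgf,
                 expected_depth = expected_depth, error_rate = error_rate,
                 depth_cap_multiple = depth_cap_multiple,
                 overwrite = overwrite, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full selection-scan pipeline
#'
#' Stages, in order: obtain genotypes (simulate, read a VCF, or call from
#' read counts after locus filtering), calibrate the window size from the
#' LD decay profile (unless fixed), run the windowed theta scan with
#' genome-wide permutation threshold, partition haplotype blocks, annotate
#' signatures by gene region (when gene models are given), count
#' fixed/lost alleles and fit the drift FDR, and export Manhattan-plot
#' data. Every artifact is written under `outdir` and listed with an MD5
#' checksum in the returned manifest; runs are deterministic given the
#' seed. A stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return list: `manifest` (file, md5), plus the in-memory `scan`,
#'   `blocks`, `fdr`, `window`, and (if annotated) `annotation` results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  else if (length(list.files(out)) && !config$overwrite)
    stop("outdir not empty; pass overwrite = TRUE to reuse it")
  log <- function(...) message("[thetascan] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  artifacts <- character(0)
  emit <- function(obj, name, writer = write_track) {
    p <- file.path(out, name)
    writer(obj, p)
    artifacts <<- c(artifacts, p)
    p
  }

  # --- inputs -------------------------------------------------------------
  reads <- NULL
  geno <- stage("input", {
    if (!is.null(config$simulate)) {
      log("simulating dataset (seed %d)", config$simulate$seed)
      sim <- simulate_experiment(config$simulate)
      reads <- sim$reads
      emit(sim$design, "design.tsv", write_design)
      emit(sim$genotypes, "genotypes.vcf", write_vcf)
      emit(sim$reads, "readcounts.tsv", write_readcounts)
      emit(sim$truth, "truthset.tsv", write_truthset)
      emit(config$simulate, "sim_config.dcf", write_sim_config)
      sim$genotypes
    } else if (!is.null(config$vcf)) {
      des <- read_design(config$design)
      read_vcf(config$vcf, des)
    } else if (!is.null(config$readcounts)) {
      des <- read_design(config$design)
      rc <- read_readcounts(config$readcounts, des)
      flt <- filter_loci(rc, config$expected_depth, config$error_rate,
                         config$depth_cap_multiple)
      log("locus filters: %s", paste(flt$report$rule, flt$report$n,
                                     sep = "=", collapse = ", "))
      emit(flt$report, "filter_report.tsv",
           function(x, p) utils::write.table(x, p, sep = "\t",
                                             quote = FALSE, row.names = FALSE))
      reads <- flt$reads
      call_genotypes(flt$reads)
    } else stop("no input: give simulate, vcf or readcounts")
  })
  if (is.null(reads))  # genotype-only input: exact allele counts stand in for reads
    reads <- stage("reads", {
      d <- geno$dosage
      tot <- matrix(2L, nrow(d), ncol(d), dimnames = dimnames(d))
      tot[is.na(d)] <- 0L
      nr <- d; nr[is.na(d)] <- NA_integer_
      read_count_matrix(nr, tot, geno$map, geno$design)
    })

  # --- window calibration -------------------------------------------------
  wcal <- stage("window", {
    if (!is.na(config$w)) {
      log("window fixed at w = %d", as.integer(config$w))
      list(w = as.integer(config$w), profile = NULL)
    } else {
      lp <- ld_decay_profile(geno, seed = config$seed)
      log("LD_25 at %d SNPs; window w = %d", lp$ld25_snp, lp$w)
      emit(lp$profile, "ld_profile.tsv",
           function(x, p) utils::write.table(x, p, sep = "\t",
                                             quote = FALSE, row.names = FALSE))
      list(w = lp$w, profile = lp)
    }
  })

  # --- scan ---------------------------------------------------------------
  scan <- stage("scan", {
    if (config$gwp * config$n_permutations < 1)
      warning("gwp finer than 1/n_permutations; threshold is the sample max")
    log("scanning: w = %d, %d permutations, GWp = %g, mode = %s",
        wcal$w, config$n_permutations, config$gwp, config$perm_mode)
    theta_scan(geno, w = wcal$w, n_permutations = config$n_permutations,
               gwp = config$gwp, mode = config$perm_mode, seed = config$seed)
  })
  log("critical theta = %.5f; %d signatures", scan$perm$critical_theta,
      nrow(scan$signatures))
  emit(scan$track, "theta_track.tsv")
  emit(scan$signatures, "signatures.tsv")

  # --- blocks -------------------------------------------------------------
  blocks <- stage("blocks", {
    if (!is.na(config$mgf)) four_gamete_blocks(geno, mgf = config$mgf)
    else {
      sp <- spine_mgf_search(geno)
      log("spine MGF = %.2f (coverage %.2f)", sp$mgf, sp$coverage)
      sp$blocks
    }
  })
  emit(blocks, "blocks.bed", write_blocks_bed)

  # --- annotation ---------------------------------------------------------
  annot <- NULL
  if (!is.null(config$gff)) {
    annot <- stage("annotation", {
      idx <- build_region_index(config$gff)
      a <- assign_ss_to_regions(scan$signatures, idx)
      emit(a$assignments, "ss_regions.tsv",
           function(x, p) utils::write.table(x, p, sep = "\t",
                                             quote = FALSE, row.names = FALSE))
      list(index = idx, assignment = a,
           density = region_density(a, idx))
    })
  }

  # --- drift FDR ----------------------------------------------------------
  fdr <- stage("fdr", {
    freqs <- estimate_allele_frequency(reads)
    fx <- count_fixed_lost(freqs)
    fit <- if (nrow(fx) >= 3L && length(unique(fx$fst)) >= 2L)
      drift_regression(fx) else NULL
    emit(fx, "fixation_counts.tsv",
         function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE))
    list(counts = fx, fit = fit)
  })

  # --- manhattan export ---------------------------------------------------
  mh <- stage("manhattan", export_manhattan(scan$track, scan$perm$critical_theta,
                                            file.path(out, "manhattan.tsv")))
  artifacts <- c(artifacts, file.path(out, "manhattan.tsv"))

  manifest <- data.frame(file = basename(artifacts),
                         md5 = unname(tools::md5sum(artifacts)),
                         row.names = NULL)
  utils::write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(manifest = manifest, scan = scan, blocks = blocks, fdr = fdr,
       window = wcal$w, annotation = annot)
}

#' Manhattan-plot data export
#'
#' Per focal SNP: cumulative genome coordinate (chromosome offsets laid
#' end to end), theta, and an above-threshold flag; the threshold is the
#' horizontal cutoff line of the plot.
#'
#' @param theta_track a [windowed_theta()] track.
#' @param threshold critical theta.
#' @param path optional TSV output path.
#' @return data frame: `chrom`, `pos`, `genome_pos`, `theta`,
#'   `significant`.
#' @export
export_manhattan <- function(theta_track, threshold, path = NULL) {
  if (nrow(theta_track) == 0L) stop("empty theta track")
  chroms <- unique(theta_track$chrom)
  offsets <- c(0, cumsum(vapply(chroms, function(cc)
    max(theta_track$pos[theta_track$chrom == cc]), numeric(1))))
  names(offsets) <- c(chroms, "end")
  df <- data.frame(chrom = theta_track$chrom, pos = theta_track$pos,
                   genome_pos = theta_track$pos +
                     offsets[match(theta_track$chrom, chroms)],
                   theta = theta_track$theta,
                   significant = !is.na(theta_track$theta) &
                     theta_track$theta > threshold)
  attr(df, "threshold") <- threshold
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

#' Render a Manhattan plot of the theta track
#'
#' Base-graphics scatter of windowed theta against the cumulative genome
#' coordinate, chromosomes in alternating shades, threshold as a
#' horizontal line, significant focal SNPs highlighted.
#'
#' @param mh output of [export_manhattan()].
#' @param path optional PNG path; when NULL, draws on the active device.
#' @export
plot_manhattan <- function(mh, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 1400, height = 500)
    on.exit(grDevices::dev.off())
  }
  cols <- c("grey30", "grey60")[1 + (match(mh$chrom, unique(mh$chrom)) %% 2)]
  graphics::plot(mh$genome_pos, mh$theta, pch = 16, cex = 0.4, col = cols,
                 xlab = "genome position (bp)", ylab = expression(theta),
                 main = "windowed theta scan")
  graphics::abline(h = attr(mh, "threshold"), col = "red", lty = 2)
  if (any(mh$significant))
    graphics::points(mh$genome_pos[mh$significant], mh$theta[mh$significant],
                     pch = 16, cex = 0.5, col = "red")
  invisible(mh)
}
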