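#' Build the gene-region index from gene models
#'
#' Partitions every gene (plus its promoter) into the region classes used
#' to classify signatures: `promoter` (10 kb upstream of the TSS,
#' strand-aware), `exon` (exonic bases that are not UTR), `utr`, `jr`
#' (intron-exon junction: intronic bases within 150 bp of an exon
#' boundary, multi-exon genes only -- the territory of splice sites and
#' most branch points) and `injr` (remaining, deeper intron). Exons are
#' unioned across transcripts; the TSS is the 5'-most transcribed base.
#' Bases claimed by several classes within a gene resolve by precedence
#' exon > utr > jr > injr. The intergenic complement covers everything
#' outside gene bodies and promoters.
#'
#' @param gene_models path to a GFF3/GTF file, or a `GRanges` with
#'   metadata columns `type` (gene/exon/UTR records) and `gene_id`.
#' @param promoter_size bp upstream of the TSS (default 10000).
#' @param junction_size bp of intron flanking each exon boundary
#'   (default 150).
#' @return A `region_index`: `regions` (GRanges; `gene_id`, `region`),
#'   `intergenic` (GRanges), `class_sizes` (bp per class, unioned across
#'   genes), `genes` (gene bodies with TSS).
#' @export
build_region_index <- function(gene_models, promoter_size = 10000L,
                               junction_size = 150L) {
  seq_regions <- NULL
  if (is.character(gene_models)) {
    gr <- rtracklayer::import(gene_models)
    # rtracklayer drops the ##sequence-region pragma; recover chrom lengths
    hdr <- grep("^##sequence-region", readLines(gene_models, n = 500L),
                value = TRUE)
    if (length(hdr)) {
      parts <- strsplit(trimws(hdr), "\\s+")
      seq_regions <- stats::setNames(
        vapply(parts, function(x) as.numeric(x[4]), numeric(1)),
        vapply(parts, function(x) x[2], character(1)))
    }
  } else gr <- gene_models
  typ <- tolower(as.character(gr$type))
  gid <- gene_id_of(gr)
  genes <- gr[typ == "gene"]
  genes_id <- gid[typ == "gene"]
  if (!length(genes)) stop("no gene records in the gene models")
  exons <- gr[typ == "exon"]
  exons_id <- gid[typ == "exon"]
  utrs <- gr[typ %in% c("five_prime_utr", "three_prime_utr", "utr")]
  utrs_id <- gid[typ %in% c("five_prime_utr", "three_prime_utr", "utr")]

  region_list <- list()
  keep_genes <- logical(length(genes))
  tss <- integer(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    id <- genes_id[i]
    if (is.na(id) || is.na(as.character(BiocGenerics::strand(g)))) {
      warning("skipping malformed gene record ", i)
      next
    }
    keep_genes[i] <- TRUE
    minus <- as.character(BiocGenerics::strand(g)) == "-"
    tss[i] <- if (minus) BiocGenerics::end(g) else BiocGenerics::start(g)
    ex <- GenomicRanges::reduce(exons[exons_id == id])
    ut <- GenomicRanges::reduce(utrs[utrs_id == id])
    if (!length(ex)) ex <- GenomicRanges::granges(g)  # exonless model: body
    exonic <- GenomicRanges::reduce(c(ex, ut))
    introns <- GenomicRanges::setdiff(GenomicRanges::granges(g), exonic)
    exon_cls <- GenomicRanges::setdiff(ex, ut)
    if (length(exonic) > 1L && length(introns)) {
      flanks <- c(GenomicRanges::flank(exonic, junction_size, start = TRUE),
                  GenomicRanges::flank(exonic, junction_size, start = FALSE))
      jr <- GenomicRanges::intersect(introns, GenomicRanges::reduce(flanks))
      injr <- GenomicRanges::setdiff(introns, jr)
    } else {
      jr <- GenomicRanges::GRanges()
      injr <- introns
      if (length(exonic) == 1L) injr <- GenomicRanges::GRanges()
    }
    prom <- GenomicRanges::promoters(GenomicRanges::granges(g),
                                     upstream = promoter_size, downstream = 0)
    prom <- GenomicRanges::trim(restrict_min1(prom))
    add <- function(x, cls) {
      if (!length(x)) return(NULL)
      x$gene_id <- id; x$region <- cls; x
    }
    region_list[[length(region_list) + 1L]] <- do.call(c, Filter(Negate(is.null), list(
      add(prom, "promoter"), add(exon_cls, "exon"), add(ut, "utr"),
      add(jr, "jr"), add(injr, "injr"))))
  }
  regions <- do.call(c, region_list)
  bodies <- GenomicRanges::reduce(GenomicRanges::granges(genes[keep_genes]))
  proms <- GenomicRanges::reduce(
    GenomicRanges::granges(regions[regions$region == "promoter"]))
  genome <- genome_extent(gr, seq_regions)
  intergenic <- GenomicRanges::setdiff(genome,
                                       GenomicRanges::reduce(c(bodies, proms)),
                                       ignore.strand = TRUE)
  cls_size <- vapply(c("promoter", "exon", "utr", "jr", "injr"), function(cl)
    sum(BiocGenerics::width(GenomicRanges::reduce(
      GenomicRanges::granges(regions[regions$region == cl]),
      ignore.strand = TRUE))), numeric(1))
  cls_size["intergenic"] <- sum(BiocGenerics::width(intergenic))
  gb <- GenomicRanges::granges(genes[keep_genes])
  gb$gene_id <- genes_id[keep_genes]
  gb$tss <- tss[keep_genes]
  structure(list(regions = regions, intergenic = intergenic,
                 class_sizes = cls_size, genes = gb,
                 promoter_size = promoter_size,
                 junction_size = junction_size),
            class = "region_index")
}

restrict_min1 <- function(gr) {
  BiocGenerics::start(gr) <- pmax(BiocGenerics::start(gr), 1L)
  gr
}

gene_id_of <- function(gr) {
  md <- S4Vectors::mcols(gr)
  id <- if ("gene_id" %in% names(md)) as.character(md$gene_id) else
    rep(NA_character_, length(gr))
  if ("Parent" %in% names(md)) {
    par <- vapply(md$Parent, function(p)
      if (length(p)) as.character(p)[1] else NA_character_, character(1))
    # resolve transcript parents to their gene
    if ("ID" %in% names(md)) {
      own <- as.character(md$ID)
      gene_of <- stats::setNames(id, own)
      resolved <- id
      need <- is.na(resolved) & !is.na(par)
      resolved[need] <- id[match(par[need], own)]
      still <- is.na(resolved) & !is.na(par)
      grandpar <- par[match(par, own)]
      resolved[still] <- gene_of[grandpar[still]]
      id <- resolved
    } else id[is.na(id)] <- par[is.na(id)]
  }
  if (all(is.na(id)) && "ID" %in% names(md)) id <- as.character(md$ID)
  id
}

genome_extent <- function(gr, seq_regions = NULL) {
  sl <- GenomeInfoDb::seqlengths(gr)
  chroms <- GenomeInfoDb::seqlevels(gr)
  ends <- vapply(chroms, function(cc) {
    if (!is.null(seq_regions) && cc %in% names(seq_regions))
      return(seq_regions[[cc]])
    if (!is.na(sl[cc])) return(as.numeric(sl[cc]))
    max(BiocGenerics::end(gr[GenomicRanges::seqnames(gr) == cc]))
  }, numeric(1))
  GenomicRanges::GRanges(chroms, IRanges::IRanges(1L, as.integer(ends)))
}

#' @export
print.region_index <- function(x, ...) {
  cat("region_index:", length(x$genes), "genes;",
      "class sizes (bp):\n")
  print(x$class_sizes)
  invisible(x)
}

#' Assign signature calls to genes and regions
#'
#' Each call is mapped to every overlapping gene's region (precedence
#' exon > utr > jr > injr > promoter within a gene); a call inside several
#' overlapping genes yields several records. Calls outside all genes and
#' promoters are labelled intergenic.
#'
#' @param calls a `signature_calls` table (needs `chrom`, `pos`).
#' @param index a [build_region_index()] result.
#' @return A `region_assignment`: `assignments` (call, gene, region rows)
#'   and `gene_region_counts` (genes x region count matrix).
#' @export
assign_ss_to_regions <- function(calls, index) {
  precedence <- c("exon", "utr", "jr", "injr", "promoter")
  if (nrow(calls) == 0L) {
    return(structure(list(
      assignments = data.frame(call = integer(0), chrom = character(0),
                               pos = integer(0), gene_id = character(0),
                               region = character(0)),
      gene_region_counts = matrix(0L, 0, length(precedence),
                                  dimnames = list(NULL, precedence))),
      class = "region_assignment"))
  }
  pts <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(pts, index$regions, ignore.strand = TRUE)
  df <- data.frame(call = S4Vectors::queryHits(hits),
                   gene_id = index$regions$gene_id[S4Vectors::subjectHits(hits)],
                   region = index$regions$region[S4Vectors::subjectHits(hits)],
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    df$rank <- match(df$region, precedence)
    df <- df[order(df$call, df$gene_id, df$rank), ]
    df <- df[!duplicated(df[, c("call", "gene_id")]), ]
    df$rank <- NULL
  }
  outside <- setdiff(seq_len(nrow(calls)), df$call)
  if (length(outside))
    df <- rbind(df, data.frame(call = outside, gene_id = NA_character_,
                               region = "intergenic", stringsAsFactors = FALSE))
  df <- df[order(df$call), ]
  df$chrom <- calls$chrom[df$call]
  df$pos <- calls$pos[df$call]
  rownames(df) <- NULL
  genic <- df[!is.na(df$gene_id), , drop = FALSE]
  counts <- table(factor(genic$gene_id), factor(genic$region, levels = precedence))
  counts <- array(as.integer(counts), dim = dim(counts),
                  dimnames = dimnames(counts))
  structure(list(assignments = df[, c("call", "chrom", "pos", "gene_id", "region")],
                 gene_region_counts = counts),
            class = "region_assignment")
}

#' Signature density per region class
#'
#' Count of assigned signatures in each class divided by the genome-wide
#' (unioned) size of that class, scaled to signatures per Mb. Small
#' classes with many hits -- typically junctions -- surface as the densest
#' even when their raw counts trail the introns.
#'
#' @param assignment a [assign_ss_to_regions()] result.
#' @param index the matching [build_region_index()].
#' @return data frame: `region`, `n`, `size_bp`, `per_mb` (NA when a class
#'   has zero size).
#' @export
region_density <- function(assignment, index) {
  classes <- names(index$class_sizes)
  n <- vapply(classes, function(cl)
    sum(assignment$assignments$region == cl), numeric(1))
  size <- index$class_sizes[classes]
  per_mb <- ifelse(size > 0, n / (size / 1e6), NA_real_)
  if (any(size == 0 & n > 0))
    warning("signatures assigned to a zero-size region class")
  data.frame(region = classes, n = n, size_bp = as.numeric(size),
             per_mb = per_mb, row.names = NULL)
}

#' Correlations between per-gene signature counts across regions
#'
#' Pearson correlation of region count vectors across genes, with
#' two-sided permutation p-values (gene labels of one vector shuffled).
#' Constant vectors give NA with a warning.
#'
#' @param counts genes x regions count matrix (e.g.
#'   `gene_region_counts` from [assign_ss_to_regions()]).
#' @param n_permutations permutations for the p-values (default 10000).
#' @param seed integer seed.
#' @return list: `correlation` and `p_value` matrices.
#' @export
region_count_correlations <- function(counts, n_permutations = 10000L,
                                      seed = 1L) {
  if (nrow(counts) < 3L) stop("need counts for at least 3 genes")
  set.seed(seed)
  k <- ncol(counts)
  cors <- matrix(NA_real_, k, k, dimnames = list(colnames(counts),
                                                 colnames(counts)))
  pvals <- cors
  diag(cors) <- 1
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    x <- counts[, a]; y <- counts[, b]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("constant count vector: correlation undefined for ",
              colnames(counts)[a], "-", colnames(counts)[b])
      next
    }
    r <- stats::cor(x, y)
    perm <- replicate(n_permutations, stats::cor(x, sample(y)))
    p <- (1 + sum(abs(perm) >= abs(r))) / (n_permutations + 1)
    cors[a, b] <- cors[b, a] <- r
    pvals[a, b] <- pvals[b, a] <- p
  }
  list(correlation = cors, p_value = pvals)
}
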