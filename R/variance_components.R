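#' Per-locus nested variance components of allele indicators
#'
#' Decomposes the 0/1 non-reference allele indicator of every gamete into
#' nested strata -- Line, Replicate within Line, Sample within Replicate x
#' Line, and Gamete within Sample -- by method of moments: sums of squares
#' at each stratum are equated to their expectations under the random
#' model, with standard Henderson-type coefficients that support unbalanced
#' cells (missing calls are dropped per locus, complete-case). Negative
#' component estimates are retained, not truncated: truncation would bias
#' the intra-class correlation upward under the null.
#'
#' Gametes of unphased heterozygotes are exchangeable, and every quantity
#' here depends only on per-sample allele counts, so the arbitrary
#' within-sample gamete order is irrelevant.
#'
#' With a single replicate per line the replicate stratum has no degrees of
#' freedom; its component is fixed at zero and the decomposition reduces to
#' the classical two-level line/sample/gamete estimator (which cannot
#' separate drift from selection -- the reason the scan wants replicates).
#'
#' @param genotypes a [genotype_matrix()].
#' @param design optional [study_design()]; defaults to the attached one.
#' @return A `locus_components` data frame: per locus `sigma_L`,
#'   `sigma_RL`, `sigma_SRL`, `sigma_G`, their sum `denom`, the single-locus
#'   `theta` (NA for monomorphic loci), plus `chrom`, `pos`, `id`.
#' @export
locus_variance_components <- function(genotypes, design = genotypes$design) {
  design <- design_match(design, rownames(genotypes$dosage))
  Y <- gamete_matrix(genotypes)
  gd <- gamete_design(design)
  comp <- gamete_components(Y, gd)
  out <- data.frame(chrom = genotypes$map$chrom, pos = genotypes$map$pos,
                    id = genotypes$map$id,
                    sigma_L = comp$sigma_L, sigma_RL = comp$sigma_RL,
                    sigma_SRL = comp$sigma_SRL, sigma_G = comp$sigma_G,
                    stringsAsFactors = FALSE)
  out$denom <- out$sigma_L + out$sigma_RL + out$sigma_SRL + out$sigma_G
  out$theta <- ifelse(is.na(out$denom) | out$denom == 0, NA_real_,
                      out$sigma_L / out$denom)
  class(out) <- c("locus_components", "data.frame")
  out
}

# Split unphased dosages into a gametes x loci 0/1 matrix (rows 2i-1, 2i
# belong to sample i; heterozygote order arbitrary).
gamete_matrix <- function(genotypes) {
  d <- genotypes$dosage
  g1 <- matrix(NA_integer_, nrow(d), ncol(d))
  g2 <- g1
  g1[!is.na(d)] <- as.integer(d[!is.na(d)] >= 1L)
  g2[!is.na(d)] <- as.integer(d[!is.na(d)] == 2L)
  Y <- matrix(NA_integer_, 2L * nrow(d), ncol(d))
  Y[seq(1L, 2L * nrow(d), 2L), ] <- g1
  Y[seq(2L, 2L * nrow(d), 2L), ] <- g2
  colnames(Y) <- colnames(d)
  Y
}

# Vectorised unbalanced nested ANOVA over all loci.
# Y: gametes x loci 0/1 (NA allowed); gd: gamete-level design.
gamete_components <- function(Y, gd) {
  samp <- factor(gd$sample_index)
  cell <- factor(paste(gd$line, gd$replicate, sep = "|"))
  line <- factor(gd$line)
  samp_cell <- cell[!duplicated(samp)][order(unique(samp))]
  # group sums of values and of observation counts
  M <- !is.na(Y)
  Yz <- Y; Yz[!M] <- 0L
  Ts <- rowsum(Yz, samp); Ns <- rowsum(M + 0L, samp)
  cell_of_samp <- tapply(as.character(cell), samp, `[`, 1L)[rownames(Ts)]
  line_of_samp <- tapply(as.character(line), samp, `[`, 1L)[rownames(Ts)]
  Tc <- rowsum(Ts, cell_of_samp); Nc <- rowsum(Ns, cell_of_samp)
  line_of_cell <- tapply(line_of_samp, cell_of_samp, `[`, 1L)[rownames(Tc)]
  Tl <- rowsum(Tc, line_of_cell); Nl <- rowsum(Nc, line_of_cell)
  Tt <- colSums(Tl); Nt <- colSums(Nl)

  safe_ratio <- function(num, den) ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)
  U_S <- colSums(safe_ratio(Ts^2, Ns))
  U_C <- colSums(safe_ratio(Tc^2, Nc))
  U_L <- colSums(safe_ratio(Tl^2, Nl))
  U_T <- safe_ratio(Tt^2, Nt)
  sumsq <- Tt  # 0/1 data: sum of squares = sum

  SS_G <- sumsq - U_S
  SS_S <- U_S - U_C
  SS_R <- U_C - U_L
  SS_L <- U_L - U_T

  n_samp_obs <- colSums(Ns > 0)
  n_cell_obs <- colSums(Nc > 0)
  n_line_obs <- colSums(Nl > 0)
  df_G <- Nt - n_samp_obs
  df_S <- n_samp_obs - n_cell_obs
  df_R <- n_cell_obs - n_line_obs
  df_L <- n_line_obs - 1L

  # Henderson-type EMS coefficients from per-locus group sizes
  grpsum <- function(X2, grp) rowsum(X2, grp)
  Ns2_c <- grpsum(Ns^2, cell_of_samp)
  q_S_C <- colSums(safe_ratio(Ns2_c, Nc))
  Ns2_l <- grpsum(Ns^2, line_of_samp)
  q_S_L <- colSums(safe_ratio(Ns2_l, Nl))
  q_S_T <- safe_ratio(colSums(Ns^2), Nt)
  Nc2_l <- grpsum(Nc^2, line_of_cell)
  q_R_L <- colSums(safe_ratio(Nc2_l, Nl))
  q_R_T <- safe_ratio(colSums(Nc^2), Nt)
  q_L_T <- safe_ratio(colSums(Nl^2), Nt)

  div <- function(num, den) ifelse(den > 0, num / ifelse(den > 0, den, 1), NA_real_)
  MS_G <- div(SS_G, df_G)
  MS_S <- div(SS_S, df_S)
  MS_R <- div(SS_R, df_R)
  MS_L <- div(SS_L, df_L)

  cS <- div(Nt - q_S_C, df_S)
  cRS <- div(q_S_C - q_S_L, df_R)
  cR <- div(Nt - q_R_L, df_R)
  cLS <- div(q_S_L - q_S_T, df_L)
  cLR <- div(q_R_L - q_R_T, df_L)
  cL <- div(Nt - q_L_T, df_L)

  sigma_G <- ifelse(df_G > 0, MS_G, 0)
  sigma_S <- ifelse(df_S > 0, (MS_S - sigma_G) / cS, 0)
  sigma_R <- ifelse(df_R > 0, (MS_R - sigma_G - cRS * sigma_S) / cR, 0)
  sigma_L <- ifelse(df_L > 0,
                    (MS_L - sigma_G - cLS * sigma_S -
                       ifelse(df_R > 0, cLR * sigma_R, 0)) / cL,
                    NA_real_)
  # loci with no between-line information at all are unusable
  unusable <- df_L < 1L | Nt == 0
  sigma_L[unusable] <- NA_real_
  list(sigma_L = sigma_L, sigma_RL = sigma_R, sigma_SRL = sigma_S,
       sigma_G = sigma_G)
}

# Design-level permutation-invariant EMS constants for COMPLETE balanced
# data (used by the compiled permutation kernel, where group sizes never
# change because labels are shuffled, not dropped).
ems_constants <- function(design) {
  gd <- gamete_design(design)
  n <- nrow(gd)
  samp <- as.integer(factor(gd$sample_index, levels = unique(gd$sample_index)))
  cell_lab <- paste(gd$line, gd$replicate, sep = "|")
  cell <- as.integer(factor(cell_lab, levels = unique(cell_lab)))
  line <- as.integer(factor(gd$line, levels = unique(gd$line)))
  cell_of_samp <- cell[!duplicated(samp)]
  line_of_cell <- line[!duplicated(cell)]
  g_s <- as.vector(table(samp))
  N_c <- as.vector(table(cell))
  N_l <- as.vector(table(line))
  S <- length(g_s); C <- length(N_c); L <- length(N_l)
  df <- c(G = n - S, S = S - C, R = C - L, L = L - 1L)
  q_S_C <- sum(rowsum(g_s^2, cell_of_samp) / N_c)
  q_S_L <- sum(rowsum(g_s^2, line_of_cell[cell_of_samp]) / N_l)
  q_S_T <- sum(g_s^2) / n
  q_R_L <- sum(rowsum(N_c^2, line_of_cell) / N_l)
  q_R_T <- sum(N_c^2) / n
  q_L_T <- sum(N_l^2) / n
  coef <- c(cS = (n - q_S_C) / max(df["S"], 1),
            cRS = (q_S_C - q_S_L) / max(df["R"], 1),
            cR = (n - q_R_L) / max(df["R"], 1),
            cLS = (q_S_L - q_S_T) / max(df["L"], 1),
            cLR = (q_R_L - q_R_T) / max(df["L"], 1),
            cL = (n - q_L_T) / max(df["L"], 1))
  names(coef) <- c("cS", "cRS", "cR", "cLS", "cLR", "cL")
  list(samp = samp, cell_of_samp = cell_of_samp,
       line_of_cell = line_of_cell, df = df, coef = coef,
       n_gametes = n, n_samples = S, n_cells = C, n_lines = L)
}
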