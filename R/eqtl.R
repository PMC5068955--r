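# Allele-dosage eQTL scan. Per (SNP, gene) pair the model is ordinary
# least squares of expression on dosage + covariates + intercept; the
# dosage coefficient's two-sided t-test is reported. The scan is
# vectorized by the Frisch-Waugh-Lovell step: expression and dosage are
# residualized against [1, covariates] once, after which every pair's
# beta, SE and t statistic follow from cross-products. This is exact OLS
# (identical estimates, SEs and dfs), verified against lm() in the tests.

#' SNP quality control on a dosage matrix
#'
#' @param dosage SNP x sample matrix of dosages in [0, 2].
#' @param genotype_counts optional matrix/data.frame with columns
#'   (AA, Aa, aa) of hard genotype counts per SNP (rownames = SNP IDs);
#'   Hardy-Weinberg equilibrium is tested (1-df chi-squared
#'   goodness-of-fit) only when supplied.
#' @param r2 optional named vector of imputation quality r-squared.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param call_min minimum call rate over samples (default 0.99).
#' @param hwe_p_min HWE p-value threshold (default 1e-5).
#' @param r2_min imputation quality threshold (default 0.3).
#' @return list with `dosage` (filtered) and `report` (snp, maf,
#'   call_rate, hwe_p, r2, fail_reasons, kept).
#' @export
snp_qc <- function(dosage, genotype_counts = NULL, r2 = NULL,
                   maf_min = 0.01, call_min = 0.99, hwe_p_min = 1e-5,
                   r2_min = 0.3) {
  snps <- rownames(dosage)
  call_rate <- rowMeans(!is.na(dosage))
  freq <- rowMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  hwe_p <- rep(NA_real_, length(snps))
  if (!is.null(genotype_counts)) {
    gc <- as.matrix(genotype_counts)[snps, , drop = FALSE]
    hwe_p <- apply(gc, 1L, hwe_pvalue)
  }
  r2v <- rep(NA_real_, length(snps))
  if (!is.null(r2)) r2v <- unname(r2[snps])
  reasons <- mapply(function(m, cr, hp, r) {
    rs <- character(0)
    if (!is.na(m) && m < maf_min) rs <- c(rs, "maf")
    if (cr < call_min) rs <- c(rs, "call_rate")
    if (!is.na(hp) && hp < hwe_p_min) rs <- c(rs, "hwe")
    if (!is.na(r) && r < r2_min) rs <- c(rs, "imputation_r2")
    paste(rs, collapse = ";")
  }, maf, call_rate, hwe_p, r2v)
  kept <- reasons == ""
  if (!any(kept)) warning("no SNPs pass QC")
  list(dosage = dosage[kept, , drop = FALSE],
       report = data.frame(snp = snps, maf = maf, call_rate = call_rate,
                           hwe_p = hwe_p, r2 = r2v, fail_reasons = reasons,
                           kept = kept, row.names = NULL))
}

#' Hardy-Weinberg 1-df chi-squared goodness-of-fit p-value
#' @param counts numeric vector (AA, Aa, aa) of genotype counts.
#' @return p-value.
#' @export
hwe_pvalue <- function(counts) {
  n <- sum(counts)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (any(expd == 0)) return(1)
  x2 <- sum((counts - expd)^2 / expd)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

# residualize rows of y (variables x samples) against [1, covariates]
residualize <- function(y, covariates = NULL) {
  n <- ncol(y)
  X <- cbind(rep(1, n), covariates)
  q <- qr(X)
  if (q$rank < ncol(X)) stop("covariate matrix not of full rank")
  t(qr.resid(q, t(y)))
}

#' Dosage eQTL scan (OLS with covariates)
#'
#' @param dosage SNP x sample matrix.
#' @param em gene x sample matrix.
#' @param covariates optional sample x covariate matrix (shared sample
#'   IDs; rows matched by name when available).
#' @param snp_positions,gene_positions optional position tables
#'   (id, chrom, start, end); when both are given each record is
#'   classified cis/trans via [classify_cis_trans()].
#' @param window cis window in bp (default 1e6).
#' @param genomewide_p significance flag threshold (default 5e-8; a
#'   report column, not a filter).
#' @param min_samples minimum shared samples (default 30).
#' @return data.frame (snp, gene, beta, se, t, p, df, class,
#'   flag_genomewide). SNPs with zero residual variance are skipped and
#'   listed in attribute `skipped`.
#' @export
fit_eqtl <- function(dosage, em, covariates = NULL,
                     snp_positions = NULL, gene_positions = NULL,
                     window = 1e6, genomewide_p = 5e-8, min_samples = 30) {
  samples <- intersect(colnames(dosage), colnames(em))
  if (length(samples) < min_samples)
    stop("need at least ", min_samples, " shared samples")
  G <- dosage[, samples, drop = FALSE]
  Y <- em[, samples, drop = FALSE]
  C <- NULL
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (!is.null(rownames(C))) C <- C[samples, , drop = FALSE]
  }
  n <- length(samples)
  k <- if (is.null(C)) 0L else ncol(C)
  df <- n - k - 2L

  Gr <- residualize(G, C)
  Yr <- residualize(Y, C)
  gg <- rowSums(Gr^2)
  skipped <- rownames(G)[gg < 1e-12]
  ok <- gg >= 1e-12
  if (length(skipped)) warning(length(skipped),
                               " SNPs with zero residual variance skipped")
  Gr <- Gr[ok, , drop = FALSE]; gg <- gg[ok]
  yy <- rowSums(Yr^2)
  num <- Yr %*% t(Gr)                              # genes x snps
  beta <- sweep(num, 2L, gg, `/`)
  rss <- yy - beta * num       # genes x snps; yy recycles down columns
  rss[rss < 0] <- 0
  se <- sqrt(sweep(rss / df, 2L, gg, `/`))
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df = df)

  out <- data.frame(snp = rep(colnames(beta), each = nrow(beta)),
                    gene = rep(rownames(beta), times = ncol(beta)),
                    beta = as.vector(beta), se = as.vector(se),
                    t = as.vector(tstat), p = as.vector(p), df = df,
                    stringsAsFactors = FALSE)
  out$class <- "unclassified"
  if (!is.null(snp_positions) && !is.null(gene_positions)) {
    out$class <- classify_cis_trans(
      snp_positions[match(out$snp, snp_positions$id), , drop = FALSE],
      gene_positions[match(out$gene, gene_positions$id), , drop = FALSE],
      window = window)
  }
  out$flag_genomewide <- out$p < genomewide_p
  attr(out, "skipped") <- skipped
  out
}

#' Classify SNP-gene pairs as cis or trans
#'
#' cis iff same chromosome and
#' probe_start - window <= snp_position <= probe_end + window (inclusive
#' at both boundaries); missing positions yield "unclassified".
#'
#' @param snp rows of a SNP position table (id, chrom, start, end).
#' @param gene rows of a gene/probe position table, same length.
#' @param window distance in bp (default 1e6).
#' @return character vector in {"cis", "trans", "unclassified"}.
#' @export
classify_cis_trans <- function(snp, gene, window = 1e6) {
  pos <- snp$start
  res <- ifelse(is.na(snp$chrom) | is.na(gene$chrom) | is.na(pos) |
                  is.na(gene$start) | is.na(gene$end), "unclassified",
                ifelse(snp$chrom == gene$chrom &
                         pos >= gene$start - window &
                         pos <= gene$end + window, "cis", "trans"))
  as.character(res)
}

#' Conditional eQTL scan: lead SNP adjusted for a conditioning SNP
#'
#' The conditioning SNP's dosage is appended to the covariates and the
#' lead SNP re-tested against every gene. Collinear dosages (pairwise
#' r^2 = 1) are flagged and return NA records.
#'
#' @param dosage SNP x sample matrix containing both SNPs.
#' @param em gene x sample matrix.
#' @param covariates optional sample x covariate matrix.
#' @param lead_snp,conditioning_snp SNP IDs.
#' @param ... passed to [fit_eqtl()].
#' @return data.frame as [fit_eqtl()] plus a `collinear` flag.
#' @export
conditional_scan <- function(dosage, em, covariates = NULL,
                             lead_snp, conditioning_snp, ...) {
  g1 <- dosage[lead_snp, ]
  g2 <- dosage[conditioning_snp, ]
  r2 <- suppressWarnings(stats::cor(g1, g2))^2
  if (!is.na(r2) && r2 > 1 - 1e-10) {
    warning("lead and conditioning dosages are collinear (r^2 = 1)")
    out <- data.frame(snp = lead_snp, gene = rownames(em),
                      beta = NA_real_, se = NA_real_, t = NA_real_,
                      p = NA_real_, df = NA_integer_,
                      class = "unclassified", flag_genomewide = NA)
    out$collinear <- TRUE
    return(out)
  }
  cov2 <- cbind(covariates,
                conditioning_dosage = g2[
                  if (is.null(covariates)) colnames(em) else rownames(covariates)])
  rownames(cov2) <- if (is.null(covariates)) colnames(em) else rownames(covariates)
  out <- fit_eqtl(dosage[lead_snp, , drop = FALSE], em, covariates = cov2, ...)
  out$collinear <- FALSE
  out
}

#' Trans-target enrichment: are target genes over-represented among hits?
#'
#' Builds the 2x2 table (target vs background) x (p < p_cut vs not) over
#' one record per gene and tests it with the two-sided Fisher exact test
#' (hypergeometric-sum definition) or a chi-squared test.
#'
#' @param records data.frame with columns gene and p (one row per gene,
#'   e.g. one SNP's scan).
#' @param target_genes character vector of target gene IDs.
#' @param p_cut hit threshold (default 0.01).
#' @param test "fisher" (default) or "chisq".
#' @return list with `table` (2x2), `proportions` (target, background),
#'   `odds_ratio` (cross-product), `p`, `test`.
#' @export
trans_set_enrichment <- function(records, target_genes, p_cut = 0.01,
                                 test = c("fisher", "chisq")) {
  test <- match.arg(test)
  if (!length(target_genes)) stop("empty target set")
  if (anyDuplicated(records$gene))
    stop("records must contain one row per gene")
  is_target <- records$gene %in% target_genes
  is_hit <- records$p < p_cut
  tab <- matrix(c(sum(is_target & is_hit), sum(is_target & !is_hit),
                  sum(!is_target & is_hit), sum(!is_target & !is_hit)),
                2, 2, byrow = TRUE,
                dimnames = list(c("target", "background"),
                                c("hit", "no_hit")))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- if (test == "fisher") stats::fisher.test(tab)$p.value
  else stats::chisq.test(tab)$p.value
  list(table = tab,
       proportions = c(target = tab[1, 1] / sum(tab[1, ]),
                       background = tab[2, 1] / sum(tab[2, ])),
       odds_ratio = unname(or), p = p, test = test)
}
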