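# Biweight midcorrelation: each vector x is centred at its median and
# downweighted by w_i = (1 - u_i^2)^2 * 1[|u_i| < 1], u_i = (x_i - med) /
# (9 * MAD). bicor(x, y) is then the cosine of the two weighted, centred
# vectors. Genes with MAD = 0 fall back to Pearson (mean-centred),
# matching the robust estimator's standard degenerate-case handling.

# Returns the transformed rows; rows falling back to Pearson are recorded.
bicor_transform <- function(x) {
  med <- apply(x, 1L, stats::median)
  madv <- apply(x, 1L, stats::mad, constant = 1)
  fallback <- madv == 0
  xc <- x - med
  u <- xc / (9 * madv)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  xt <- xc * w
  if (any(fallback)) {
    xt[fallback, ] <- x[fallback, , drop = FALSE] -
      rowMeans(x[fallback, , drop = FALSE])
  }
  nrm <- sqrt(rowSums(xt^2))
  constant <- nrm == 0
  nrm[constant] <- 1
  list(scaled = xt / nrm, fallback = fallback, constant = constant)
}

#' Correlation matrix (biweight midcorrelation or Pearson)
#'
#' @param em gene x sample matrix (>= 4 samples).
#' @param method "bicor" (default) or "pearson".
#' @return symmetric gene x gene correlation matrix with unit diagonal and
#'   attributes `method`, `fallback_genes` (bicor's MAD = 0 Pearson
#'   fallbacks) and `constant_genes` (rows set to 0, flagged).
#' @export
cor_matrix <- function(em, method = c("bicor", "pearson")) {
  method <- match.arg(method)
  if (ncol(em) < 4) stop("need at least 4 samples")
  if (method == "pearson") {
    cm <- stats::cor(t(em))
    constant <- apply(em, 1L, stats::sd) == 0
    cm[constant, ] <- 0; cm[, constant] <- 0
    fallback <- logical(nrow(em))
  } else {
    tr <- bicor_transform(em)
    cm <- tcrossprod(tr$scaled)
    constant <- tr$constant
    fallback <- tr$fallback & !constant
    if (any(fallback))
      warning(sum(fallback), " genes with MAD = 0 fell back to Pearson")
    if (any(constant)) {
      warning(sum(constant), " constant genes: correlations set to 0")
      cm[constant, ] <- 0; cm[, constant] <- 0
    }
  }
  cm[cm > 1] <- 1; cm[cm < -1] <- -1
  diag(cm) <- 1
  dimnames(cm) <- list(rownames(em), rownames(em))
  attr(cm, "method") <- method
  attr(cm, "fallback_genes") <- rownames(em)[fallback]
  attr(cm, "constant_genes") <- rownames(em)[constant]
  cm
}

#' Biweight midcorrelation between the rows of two matrices
#'
#' Used for kME (gene expression vs module eigengenes).
#' @param x,y matrices with the same number of columns (samples).
#' @param method "bicor" or "pearson".
#' @return nrow(x) x nrow(y) correlation matrix.
#' @export
cor_cross <- function(x, y, method = c("bicor", "pearson")) {
  method <- match.arg(method)
  if (method == "pearson") {
    cc <- stats::cor(t(x), t(y))
    cc[is.na(cc)] <- 0
    return(cc)
  }
  tx <- bicor_transform(x)
  ty <- bicor_transform(y)
  cc <- tcrossprod(tx$scaled, ty$scaled)
  cc[tx$constant, ] <- 0
  cc[, ty$constant] <- 0
  cc[cc > 1] <- 1; cc[cc < -1] <- -1
  dimnames(cc) <- list(rownames(x), rownames(y))
  cc
}

#' Soft-threshold adjacency
#'
#' Unsigned weighted adjacency a_ij = |cor_ij|^beta.
#' @param cm correlation matrix.
#' @param beta soft-threshold power.
#' @return adjacency matrix in [0, 1] with unit diagonal and attribute
#'   `beta`.
#' @export
adjacency_matrix <- function(cm, beta) {
  a <- abs(cm)^beta
  diag(a) <- 1
  attr(a, "beta") <- beta
  attr(a, "method") <- attr(cm, "method")
  a
}

#' Scale-free topology fit for one power
#'
#' Connectivities k_i = sum_{j != i} |cor_ij|^beta are binned into 10
#' equal-occupancy bins of log10(k); log10(frequency) is regressed on
#' log10(mean k per bin); the fit index is R^2 * sign(-slope).
#' @keywords internal
scale_free_fit <- function(abs_cm, beta, n_bins = 10) {
  a <- abs_cm^beta
  diag(a) <- 0
  k <- rowSums(a)
  if (all(k == 0)) stop("all-zero connectivity")
  k <- k[k > 0]
  br <- stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1))
  br <- unique(br)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = nlevels(bin))
  mean_k <- tapply(k, bin, mean)
  ok <- freq > 0 & mean_k > 0
  lx <- log10(mean_k[ok]); ly <- log10(freq[ok])
  if (length(lx) < 3 || stats::sd(lx) == 0)
    return(c(fit = 0, slope = NA_real_, mean_k = mean(k)))
  fit <- stats::lm(ly ~ lx)
  slope <- stats::coef(fit)[["lx"]]
  r2 <- suppressWarnings(summary(fit)$r.squared)
  c(fit = r2 * sign(-slope), slope = slope, mean_k = mean(k))
}

#' Choose a soft-threshold power by approximate scale-free topology
#'
#' @param cm correlation matrix.
#' @param powers candidate powers, sorted ascending (default 1:20).
#' @param r2_target scale-free fit target (default 0.8): the smallest
#'   power reaching it is returned; if none does, the argmax of the fit.
#' @return list with `power` and `table` (power, fit, slope, mean_k).
#' @export
pick_soft_threshold <- function(cm, powers = 1:20, r2_target = 0.8) {
  if (is.unsorted(powers)) stop("powers must be sorted ascending")
  abs_cm <- abs(cm)
  tab <- t(vapply(powers, function(b) scale_free_fit(abs_cm, b),
                  c(fit = 0, slope = 0, mean_k = 0)))
  tab <- data.frame(power = powers, tab, row.names = NULL)
  hit <- which(tab$fit >= r2_target)
  power <- if (length(hit)) tab$power[hit[1L]] else tab$power[which.max(tab$fit)]
  list(power = power, table = tab)
}
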