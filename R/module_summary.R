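#' Module eigengene and variance explained
#'
#' Genes are standardized (mean 0, SD 1 across samples); the eigengene is
#' the first right-singular vector of the standardized gene x sample
#' matrix (unit-norm sample scores) and the variance explained is the
#' first squared singular value over the total. The sign is oriented so
#' that cor(ME, mean standardized expression) >= 0, which keeps
#' cross-species sign comparisons meaningful.
#'
#' @param em gene x sample matrix.
#' @param genes gene IDs (or indices) forming the module; >= 2 required.
#' @return list with `me` (named numeric vector over samples),
#'   `var_explained` in [0, 1] and `dropped` (constant genes, removed
#'   with a warning).
#' @export
eigengene <- function(em, genes) {
  x <- em[genes, , drop = FALSE]
  if (ncol(x) < 3) stop("need at least 3 samples")
  sds <- apply(x, 1L, stats::sd)
  dropped <- rownames(x)[sds == 0]
  if (length(dropped)) {
    warning(length(dropped), " constant genes dropped from module")
    x <- x[sds > 0, , drop = FALSE]
  }
  if (nrow(x) < 2) stop("module needs at least 2 non-constant genes")
  z <- (x - rowMeans(x)) / apply(x, 1L, stats::sd)
  sv <- svd(z, nu = 0, nv = 1)
  me <- sv$v[, 1L]
  if (stats::cor(me, colMeans(z)) < 0) me <- -me
  list(me = stats::setNames(me, colnames(em)),
       var_explained = sv$d[1L]^2 / sum(sv$d^2),
       dropped = dropped)
}

#' Per-module eigengenes, variance explained and the full kME matrix
#'
#' @param em gene x sample matrix.
#' @param ma a `module_assignment` (label 0 = unassigned) or a named
#'   integer vector of labels.
#' @param method correlation estimator for kME ("bicor" default, matching
#'   the network stage).
#' @param species species tag carried into the result.
#' @return object of class `module_summary`: `eigengenes` (sample x
#'   module matrix, columns named by module label), `var_explained`,
#'   `kme` (gene x module matrix over all genes), `sizes`, `species`.
#' @export
module_summary <- function(em, ma, method = c("bicor", "pearson"),
                           species = attr(em, "species")) {
  method <- match.arg(method)
  labels <- if (inherits(ma, "module_assignment")) ma$labels else ma
  labels <- labels[intersect(names(labels), rownames(em))]
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no modules in assignment")
  me <- matrix(NA_real_, ncol(em), length(mods),
               dimnames = list(colnames(em), as.character(mods)))
  ve <- stats::setNames(numeric(length(mods)), as.character(mods))
  for (j in seq_along(mods)) {
    g <- names(labels)[labels == mods[j]]
    if (length(g) < 2) stop("module ", mods[j], " has < 2 genes present")
    eg <- eigengene(em, g)
    me[, j] <- eg$me
    ve[j] <- eg$var_explained
  }
  kme <- cor_cross(em, t(me), method = method)
  structure(list(eigengenes = me, var_explained = ve, kme = kme,
                 sizes = stats::setNames(
                   vapply(mods, function(m) sum(labels == m), integer(1)),
                   as.character(mods)),
                 labels = labels, method = method, species = species),
            class = "module_summary")
}

#' @export
print.module_summary <- function(x, ...) {
  cat("module_summary (", x$species, "): ", length(x$var_explained),
      " modules, ", nrow(x$kme), " genes\n", sep = "")
  print(round(rbind(size = x$sizes, var_explained = x$var_explained), 3))
  invisible(x)
}

#' Table-1-shaped module report
#'
#' One row per module: label, size, percent variance explained by the
#' eigengene, and (if a preservation result is supplied) the consistent
#' gene fraction and permutation p-value.
#'
#' @param ms a `module_summary`.
#' @param pres optional preservation data.frame from
#'   [preservation_report()].
#' @return data.frame sorted by increasing size (largest label first is
#'   the paper's layout; here simply by module label).
#' @export
module_table <- function(ms, pres = NULL) {
  out <- data.frame(module = as.integer(names(ms$sizes)),
                    size = as.integer(ms$sizes),
                    me_pct = round(100 * ms$var_explained, 1),
                    row.names = NULL)
  if (!is.null(pres))
    out <- merge(out, pres[, setdiff(names(pres), "size")], by = "module",
                 all.x = TRUE, sort = TRUE)
  out[order(out$module), , drop = FALSE]
}
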