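# Module detection: average-linkage clustering on a TOM-based distance,
# cut with a dynamic hybrid branch criterion.
#
# The hybrid criterion evaluates every dendrogram branch on three tests:
#   size         >= min_module_size,
#   core scatter <= maxAbsCoreScatter  (mean of the branch core's earliest
#                                       merge heights; a tight core means a
#                                       dense cluster),
#   gap          >= minAbsGap          (height separating the branch's top
#                                       from where it attaches to its
#                                       sibling; a real cluster stands off
#                                       from its surroundings).
# deep_split in 0..4 maps to relative thresholds
# maxCoreScatter = c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1] and
# minGap = (1 - maxCoreScatter) * 3/4, converted to absolute heights by
# anchoring at the 5th percentile of the dissimilarity:
#   maxAbsCoreScatter = d05 + maxCoreScatter * (cut_height - d05)
#   minAbsGap         = minGap * (cut_height - d05).
# Clusters are the maximal qualifying branches; a qualifying branch is
# split only where both of its children spawn qualifying sub-branches.

core_size <- function(branch_size, min_module_size) {
  base <- min_module_size / 2 + 1
  if (base < branch_size) as.integer(base + sqrt(branch_size - base))
  else as.integer(branch_size)
}

#' Cut a dendrogram of genes into modules (dynamic hybrid criterion)
#'
#' @param diss square dissimilarity matrix (e.g. 1 - TOM) or a `dist`.
#' @param min_module_size smallest admissible module (default 50).
#' @param deep_split split sensitivity, 0 (conservative) to 4 (default 3).
#' @param cut_height maximum merge height considered; default
#'   `q05(height) + 0.99 * (max(height) - q05(height))`.
#' @param pam_stage if TRUE, unassigned genes with |kME| >= `pam_kme_min`
#'   to some module eigengene are re-assigned to the best module
#'   (requires `em`). Off by default.
#' @param em gene x sample matrix, only needed for `pam_stage`.
#' @param pam_kme_min minimum |kME| for PAM-stage re-assignment.
#' @param method correlation estimator for the PAM stage.
#' @return object of class `module_assignment`: list with `labels` (named
#'   integer vector, 0 = unassigned; modules numbered by decreasing
#'   size), `sizes`, `tree` (the hclust object) and `params`.
#' @export
cut_modules <- function(diss, min_module_size = 50, deep_split = 3,
                        cut_height = NULL, pam_stage = FALSE, em = NULL,
                        pam_kme_min = 0.3, method = c("bicor", "pearson")) {
  method <- match.arg(method)
  if (inherits(diss, "dist")) diss <- as.matrix(diss)
  if (nrow(diss) != ncol(diss)) stop("dissimilarity must be square")
  n <- nrow(diss)
  genes <- rownames(diss)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  if (!deep_split %in% 0:4) stop("deep_split must be in 0..4")

  labels <- integer(n)
  names(labels) <- genes
  tree <- stats::hclust(stats::as.dist(diss), method = "average")
  if (n < min_module_size) {
    warning("fewer genes than min_module_size: everything unassigned")
    return(new_module_assignment(labels, tree,
                                 list(min_module_size = min_module_size,
                                      deep_split = deep_split)))
  }

  h <- tree$height
  d05 <- stats::quantile(diss[lower.tri(diss)], 0.05, names = FALSE)
  if (is.null(cut_height)) {
    h05 <- stats::quantile(h, 0.05, names = FALSE)
    cut_height <- h05 + 0.99 * (max(h) - h05)
  }
  mcs <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1]
  max_abs_scatter <- d05 + mcs * (cut_height - d05)
  min_abs_gap <- (1 - mcs) * 3 / 4 * (cut_height - d05)

  m <- tree$merge
  n_node <- n - 1L
  size <- integer(n_node)
  members <- vector("list", n_node)      # leaf indices per internal node
  heights_in <- vector("list", n_node)   # sorted internal merge heights
  scatter <- numeric(n_node)
  parent_h <- rep(cut_height, n_node)
  for (i in seq_len(n_node)) {
    for (child in m[i, ]) if (child > 0) parent_h[child] <- h[i]
  }
  node_part <- function(child) if (child < 0) -child else members[[child]]
  node_heights <- function(child) if (child < 0) numeric(0) else heights_in[[child]]
  for (i in seq_len(n_node)) {
    members[[i]] <- c(node_part(m[i, 1]), node_part(m[i, 2]))
    size[i] <- length(members[[i]])
    heights_in[[i]] <- sort(c(node_heights(m[i, 1]), node_heights(m[i, 2]), h[i]))
    cs <- core_size(size[i], min_module_size)
    scatter[i] <- if (cs <= 1) 0 else mean(heights_in[[i]][seq_len(cs - 1L)])
  }

  qualifies <- size >= min_module_size &
    scatter <= max_abs_scatter &
    (parent_h - h) >= min_abs_gap &
    h <= cut_height

  # bottom-up: clusters(node) = union of child clusters unless the node
  # itself qualifies and at most one side produced clusters (absorb)
  clusters <- vector("list", n_node)
  for (i in seq_len(n_node)) {
    cl <- cl_l <- cl_r <- list()
    if (m[i, 1] > 0) cl_l <- clusters[[m[i, 1]]]
    if (m[i, 2] > 0) cl_r <- clusters[[m[i, 2]]]
    if (qualifies[i] && !(length(cl_l) && length(cl_r))) {
      clusters[[i]] <- list(members[[i]])
    } else {
      clusters[[i]] <- c(cl_l, cl_r)
    }
  }
  found <- clusters[[n_node]]
  if (length(found)) {
    ord <- order(-vapply(found, length, integer(1)))
    for (j in seq_along(ord)) labels[found[[ord[j]]]] <- j
  }

  ma <- new_module_assignment(labels, tree,
                              list(min_module_size = min_module_size,
                                   deep_split = deep_split,
                                   cut_height = cut_height,
                                   max_abs_scatter = max_abs_scatter,
                                   min_abs_gap = min_abs_gap))
  if (pam_stage) {
    if (is.null(em)) stop("pam_stage requires the expression matrix `em`")
    ma <- pam_assign(ma, em, pam_kme_min, method)
  }
  ma
}

new_module_assignment <- function(labels, tree = NULL, params = list()) {
  sizes <- table(labels[labels > 0])
  structure(list(labels = labels,
                 sizes = stats::setNames(as.integer(sizes), names(sizes)),
                 n_unassigned = sum(labels == 0),
                 tree = tree, params = params),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat("module_assignment:", length(x$labels), "genes,",
      length(x$sizes), "modules,", x$n_unassigned, "unassigned\n")
  if (length(x$sizes)) print(x$sizes)
  invisible(x)
}

# PAM-like stage: re-assign unassigned genes whose best |kME| passes the
# threshold. Off by default in cut_modules.
pam_assign <- function(ma, em, kme_min, method) {
  if (!length(ma$sizes)) return(ma)
  ms <- module_summary(em, ma, method = method)
  un <- names(ma$labels)[ma$labels == 0]
  if (!length(un)) return(ma)
  k <- ms$kme[un, , drop = FALSE]
  best <- max.col(abs(k), ties.method = "first")
  ok <- abs(k[cbind(seq_along(un), best)]) >= kme_min
  labels <- ma$labels
  labels[un[ok]] <- as.integer(colnames(k)[best[ok]])
  relabel_by_size(labels, ma$tree, c(ma$params, list(pam_stage = TRUE)))
}

relabel_by_size <- function(labels, tree = NULL, params = list()) {
  old <- sort(unique(labels[labels > 0]))
  if (length(old)) {
    sizes <- vapply(old, function(l) sum(labels == l), integer(1))
    new <- integer(max(old))
    new[old[order(-sizes, old)]] <- seq_along(old)
    labels[labels > 0] <- new[labels[labels > 0]]
  }
  new_module_assignment(labels, tree, params)
}

#' Merge modules with highly correlated eigengenes
#'
#' Eigengenes are clustered (average linkage) on 1 - cor(ME_a, ME_b);
#' modules joined below `cut_height` are merged and labels recomputed by
#' decreasing size.
#'
#' @param em gene x sample matrix the assignment refers to.
#' @param ma a `module_assignment`.
#' @param cut_height merge height (default 0.15, i.e. eigengene
#'   correlation above 0.85). `cut_height = 0` never merges.
#' @param method correlation estimator for recomputed summaries.
#' @return a `module_assignment` with merged labels.
#' @export
merge_similar_modules <- function(em, ma, cut_height = 0.15,
                                  method = c("bicor", "pearson")) {
  method <- match.arg(method)
  if (length(ma$sizes) < 2 || cut_height <= 0) return(ma)
  ms <- module_summary(em, ma, method = method)
  me <- ms$eigengenes
  d <- 1 - stats::cor(me)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  grp <- stats::cutree(hc, h = cut_height)
  if (length(unique(grp)) == length(grp)) return(ma)
  labels <- ma$labels
  map <- grp[as.character(labels[labels > 0])]
  labels[labels > 0] <- as.integer(map)
  relabel_by_size(labels, ma$tree,
                  c(ma$params, list(merge_cut_height = cut_height)))
}
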