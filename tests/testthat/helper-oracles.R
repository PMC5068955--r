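# Independent brute-force oracles, deliberately naive and element-wise so
# they share no code path with the implementation.

# biweight midcorrelation of two vectors, straight from the definition
oracle_bicor <- function(x, y) {
  tr <- function(v) {
    u <- (v - median(v)) / (9 * mad(v, constant = 1))
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (v - median(v)) * w
  }
  xt <- tr(x); yt <- tr(y)
  sum(xt * yt) / (sqrt(sum(xt^2)) * sqrt(sum(yt^2)))
}

# TOM by triple loop
oracle_tom <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  out
}

# upper-tail hypergeometric by explicit combinatorial sum
oracle_hyper_tail <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# two-sided Fisher exact p by enumerating all tables with the observed
# margins and summing probabilities <= the observed one
oracle_fisher <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  prob <- function(x) dhyper(x, c1, N - c1, r1)
  p_obs <- prob(a)
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  sum(vapply(xs, prob, numeric(1))[vapply(xs, prob, numeric(1)) <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg from the definition (step-up)
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# adjusted Rand index from the contingency table
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  si <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  ex <- sa * sb / choose(sum(tab), 2)
  (si - ex) / ((sa + sb) / 2 - ex)
}

# small planted-block expression fixture: `blocks` named list of sizes,
# loading per block, plus background noise genes
make_block_expr <- function(blocks, n_background, n_samples, loading = 0.8,
                            seed = 1) {
  set.seed(seed)
  rows <- list()
  labels <- integer(0)
  for (b in seq_along(blocks)) {
    e <- rnorm(n_samples)
    x <- loading * matrix(e, blocks[[b]], n_samples, byrow = TRUE) +
      sqrt(1 - loading^2) * matrix(rnorm(blocks[[b]] * n_samples),
                                   blocks[[b]], n_samples)
    rows[[b]] <- x
    labels <- c(labels, rep(b, blocks[[b]]))
  }
  x <- rbind(do.call(rbind, rows),
             matrix(rnorm(n_background * n_samples), n_background, n_samples))
  labels <- c(labels, rep(0L, n_background))
  rownames(x) <- sprintf("g%04d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%03d", seq_len(n_samples))
  list(expr = x, labels = setNames(labels, rownames(x)))
}
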