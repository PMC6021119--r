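# Independent oracles used to cross-check the package's implementations.
# These deliberately avoid the code paths they verify.

# Brute-force RCBD sums of squares from raw deviations.
brute_rcbd_ss <- function(table, trait) {
  d <- table[table$trait == trait, ]
  d$geno <- paste(d$parent_a, d$parent_b, sep = ":")
  gm <- tapply(d$value, d$geno, mean)
  bm <- tapply(d$value, d$block, mean)
  grand <- mean(d$value)
  ng <- length(gm); nb <- length(bm)
  ss_block <- ng * sum((bm - grand)^2)
  ss_geno <- nb * sum((gm - grand)^2)
  fitted <- gm[d$geno] + bm[as.character(d$block)] - grand
  ss_err <- sum((d$value - fitted)^2)
  list(block = ss_block, geno = ss_geno, error = ss_err,
    total = sum((d$value - grand)^2))
}

# Equality-constrained least squares for the saturated diallel model:
# minimise sum over cells (x_ij - mu - g_i - g_j - s_ij)^2 subject to
# sum_i g_i = 0 and, for each i, sum_j s_ij + s_ii = 0 (self counted twice).
# Solved via the KKT system; independent of the closed-form estimators.
ls_griffing_oracle <- function(M) {
  p <- nrow(M)
  ids <- rownames(M)
  cells <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
  nc <- nrow(cells)
  npar <- 1 + p + nc
  X <- matrix(0, nc, npar)
  for (k in seq_len(nc)) {
    i <- cells[k, 1]; j <- cells[k, 2]
    X[k, 1] <- 1
    X[k, 1 + i] <- X[k, 1 + i] + 1
    X[k, 1 + j] <- X[k, 1 + j] + 1
    X[k, 1 + p + k] <- 1
  }
  y <- M[cells]
  C <- matrix(0, 1 + p, npar)
  C[1, 2:(p + 1)] <- 1
  for (i in seq_len(p)) {
    for (k in seq_len(nc)) {
      if (cells[k, 1] == i || cells[k, 2] == i) {
        w <- if (cells[k, 1] == i && cells[k, 2] == i) 2 else 1
        C[1 + i, 1 + p + k] <- w
      }
    }
  }
  K <- rbind(cbind(crossprod(X), t(C)), cbind(C, matrix(0, nrow(C), nrow(C))))
  rhs <- c(crossprod(X, y), rep(0, nrow(C)))
  theta <- solve(K, rhs)[seq_len(npar)]
  S <- matrix(0, p, p, dimnames = list(ids, ids))
  S[cells] <- theta[(p + 2):npar]
  S[cells[, c(2, 1)]] <- theta[(p + 2):npar]
  list(mu = theta[1], g = stats::setNames(theta[2:(p + 1)], ids), s = S)
}

# Brute-force UPGMA: cluster distance recomputed each step as the plain
# average of *original* pairwise distances across the two member sets
# (a defining property of average linkage), lexicographic tie-break.
brute_upgma_newick <- function(D) {
  labs <- rownames(D)
  n <- nrow(D)
  cl <- lapply(seq_len(n), function(i) i)
  nwk <- labs
  hts <- rep(0, n)
  avg_dist <- function(a, b) mean(D[cl[[a]], cl[[b]], drop = FALSE])
  while (length(cl) > 1) {
    m <- length(cl)
    best <- NULL; bestd <- Inf
    for (a in 1:(m - 1)) for (b in (a + 1):m) {
      dd <- avg_dist(a, b)
      better <- dd < bestd
      if (!better && dd == bestd) {
        cand <- sort(c(min(labs[cl[[a]]]), min(labs[cl[[b]]])))
        cur <- sort(c(min(labs[cl[[best[1]]]]), min(labs[cl[[best[2]]]])))
        better <- cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])
      }
      if (better) { bestd <- dd; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]; h <- bestd / 2
    nwk_new <- sprintf("(%s:%.10g,%s:%.10g)",
      nwk[a], h - hts[a], nwk[b], h - hts[b])
    cl[[a]] <- c(cl[[a]], cl[[b]]); cl[[b]] <- NULL
    nwk[a] <- nwk_new; hts[a] <- h
    nwk <- nwk[-b]; hts <- hts[-b]
  }
  paste0(nwk, ";")
}

# leaf-to-root depth of every tip, for ultrametricity / height comparisons
tip_depths <- function(tree) {
  nh <- ape::node.depth.edgelength(tree)
  stats::setNames(nh[seq_along(tree$tip.label)], tree$tip.label)
}

# root height (max tip depth) plus sorted internal node heights
node_heights <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  total <- max(depth[seq_along(tree$tip.label)])
  sort(total - depth[(length(tree$tip.label) + 1):length(depth)])
}

# random symmetric distance matrix with distinct entries
random_dist <- function(n, seed) {
  set.seed(seed)
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- stats::runif(n * (n - 1) / 2, 0.1, 1)
  D <- D + t(D)
  dimnames(D) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  D
}
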