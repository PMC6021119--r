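#' Simulate a half-diallel phenotype experiment with known ground truth
#'
#' Draws data from the model the Griffing Method 2 analysis assumes:
#' \deqn{y_{ijk} = \mu + g_i + g_j + s_{ij} + \beta_k + \epsilon_{ijk}}
#' with `g_i ~ N(0, sigma2_gca)`, symmetric `s_ij ~ N(0, sigma2_sca)`
#' (selfs `s_ii` drawn from the same distribution), block effects
#' `beta_k ~ N(0, sigma2_block)` and residuals `N(0, sigma2_error)`.
#' Parents are the selfs `y = mu + 2 g_i + s_ii + beta_k + eps`. Defaults
#' mirror a 10-parent, 3-block randomized complete block half-diallel.
#' Draw order per trait: GCA effects, SCA effects (canonical genotype
#' order), block effects, residuals — so a seed fixes the data set exactly.
#'
#' @param p Number of parents (>= 3).
#' @param b Number of blocks (>= 2).
#' @param mu Grand mean.
#' @param sigma2_gca,sigma2_sca,sigma2_block,sigma2_error Variances (>= 0)
#'   of the GCA, SCA, block and residual draws.
#' @param traits Character vector of trait names; each trait is drawn
#'   independently with the same variances.
#' @param seed Optional integer seed.
#' @return List with `phenotypes` (a `diallel_pheno` tibble, parents
#'   `P01`, `P02`, ...) and `truth` (per trait: `mu`, `gca` named vector,
#'   `sca` matrix, `block` effects).
#' @examples
#' sim <- simulate_diallel(p = 4, b = 2, seed = 1)
#' sim$truth$y$gca
#' @export
simulate_diallel <- function(p = 10, b = 3, mu = 100,
                             sigma2_gca = 4, sigma2_sca = 1,
                             sigma2_block = 0.5, sigma2_error = 1,
                             traits = "y", seed = NULL) {
  stopifnot(p >= 3, b >= 2, sigma2_gca >= 0, sigma2_sca >= 0,
    sigma2_block >= 0, sigma2_error >= 0, length(traits) >= 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("P%02d", seq_len(p))
  grid <- genotype_grid(ids)
  ng <- nrow(grid)
  ia <- match(grid$parent_a, ids)
  ib <- match(grid$parent_b, ids)
  truth <- list()
  tabs <- vector("list", length(traits))
  for (ti in seq_along(traits)) {
    g <- stats::rnorm(p, 0, sqrt(sigma2_gca))
    s <- stats::rnorm(ng, 0, sqrt(sigma2_sca))
    beta <- stats::rnorm(b, 0, sqrt(sigma2_block))
    eps <- stats::rnorm(ng * b, 0, sqrt(sigma2_error))
    cellval <- mu + g[ia] + g[ib] + s
    y <- rep(cellval, times = b) + rep(beta, each = ng) + eps
    tabs[[ti]] <- tibble::tibble(
      parent_a = rep(grid$parent_a, times = b),
      parent_b = rep(grid$parent_b, times = b),
      block = rep(seq_len(b), each = ng),
      trait = traits[ti],
      value = y
    )
    S <- matrix(0, p, p, dimnames = list(ids, ids))
    S[cbind(ia, ib)] <- s
    S[cbind(ib, ia)] <- s
    truth[[traits[ti]]] <- list(
      mu = mu, gca = stats::setNames(g, ids), sca = S, block = beta
    )
  }
  list(
    phenotypes = as_diallel_pheno(purrr::list_rbind(tabs), ids),
    truth = truth
  )
}

#' Simulate a cluster-structured SNP panel
#'
#' Generates inbred-like diploid dosages with population structure: each
#' site has an ancestral homozygous dosage (0 or 2); each cluster flips the
#' ancestral state with probability `p_between` (divergence between
#' groups), and each sample flips its cluster's state with probability
#' `p_within` (divergence within groups). Flips toggle 0 and 2, so
#' simulated samples are fully homozygous, as expected for inbred parents;
#' residual heterozygous calls in real data are handled by the readers, not
#' simulated. Missing calls are injected completely at random at
#' `missing_rate`.
#'
#' @param n_samples Number of samples.
#' @param n_sites Number of SNP sites.
#' @param n_clusters Number of groups (<= `n_samples`); samples are
#'   assigned round-robin.
#' @param p_between Per-site probability a cluster deviates from the
#'   ancestral state.
#' @param p_within Per-site probability a sample deviates from its cluster.
#' @param missing_rate Fraction of calls set to missing.
#' @param seed Optional integer seed.
#' @return A [snp_matrix()] (samples `S01`, `S02`, ... on chromosome
#'   `chr1`) with the cluster assignment in attribute `clusters`.
#' @export
simulate_snps <- function(n_samples = 10, n_sites = 1000, n_clusters = 2,
                          p_between = 0.2, p_within = 0.01,
                          missing_rate = 0, seed = NULL) {
  stopifnot(n_samples >= 2, n_sites >= 1, n_clusters >= 1,
    n_clusters <= n_samples,
    p_between >= 0, p_between <= 1, p_within >= 0, p_within <= 1,
    missing_rate >= 0, missing_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("S%02d", seq_len(n_samples))
  cl <- rep(seq_len(n_clusters), length.out = n_samples)
  anc <- sample(c(0L, 2L), n_sites, replace = TRUE)
  clust_dos <- matrix(rep(anc, each = n_clusters), n_clusters, n_sites)
  flip_b <- matrix(stats::runif(n_clusters * n_sites) < p_between,
    n_clusters, n_sites)
  clust_dos[flip_b] <- 2L - clust_dos[flip_b]
  X <- clust_dos[cl, , drop = FALSE]
  flip_w <- matrix(stats::runif(n_samples * n_sites) < p_within,
    n_samples, n_sites)
  X[flip_w] <- 2L - X[flip_w]
  if (missing_rate > 0) {
    X[matrix(stats::runif(length(X)) < missing_rate, nrow(X))] <- NA
  }
  rownames(X) <- ids
  out <- snp_matrix(X, tibble::tibble(
    chrom = "chr1", pos = seq_len(n_sites),
    ref = "A", alt = "G"
  ))
  attr(out, "clusters") <- stats::setNames(cl, ids)
  out
}

#' Write an SNP matrix as a minimal VCF v4.2 file
#'
#' Serializes dosages back to diploid GT calls (`0/0`, `0/1`, `1/1`,
#' `./.`), one biallelic SNP record per site, suitable for round-tripping
#' through [read_snp_vcf()].
#'
#' @param m A [snp_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(m, path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  G <- matrix(gt_code[as.character(m$dosage)], nrow = nrow(m$dosage))
  G[is.na(G)] <- "./."
  body <- cbind(
    m$sites$chrom, m$sites$pos, ".", m$sites$ref, m$sites$alt,
    ".", "PASS", ".", "GT", t(G)
  )
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", m$samples), collapse = "\t"),
    apply(body, 1, paste, collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a diallel phenotype table as CSV
#'
#' @param table A `diallel_pheno` tibble (or compatible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(table, path) {
  readr::write_csv(
    as.data.frame(table)[c("parent_a", "parent_b", "block", "trait", "value")],
    path
  )
  invisible(path)
}
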