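#' Construct an SNP dosage matrix
#'
#' @param dosage Integer matrix, samples x sites, values in {0, 1, 2} (count
#'   of alternate alleles) or `NA` for missing calls; rownames are sample
#'   ids.
#' @param sites Tibble with one row per site: `chrom`, `pos` (1-based,
#'   positive), `ref`, `alt`.
#' @return Object of class `snp_matrix`.
#' @export
snp_matrix <- function(dosage, sites) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) {
    rlang::abort("dosage matrix needs sample ids as rownames")
  }
  if (nrow(sites) != ncol(dosage)) {
    rlang::abort("sites table and dosage columns disagree")
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% 0:2)) {
    rlang::abort("dosages must be 0, 1, 2 or NA")
  }
  if (any(sites$pos <= 0)) rlang::abort("positions must be positive")
  colnames(dosage) <- paste(sites$chrom, sites$pos, sep = "_")
  structure(list(
    dosage = dosage,
    sites = tibble::as_tibble(sites),
    samples = rownames(dosage)
  ), class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat("<snp_matrix> ", length(x$samples), " samples x ", ncol(x$dosage),
    " sites (", sum(is.na(x$dosage)), " missing calls)\n", sep = "")
  invisible(x)
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Loads a VCF (plain or bgzipped) with [vcfR::read.vcfR()], keeps only
#' biallelic single-nucleotide records, and converts GT fields to
#' alternate-allele dosages (0/1/2, `NA` for missing). Multi-allelic and
#' non-SNP (indel) records are skipped; the number skipped is stored in the
#' `n_skipped` attribute and reported via a message.
#'
#' @param path VCF file path.
#' @param samples Optional character vector selecting (and ordering) a
#'   subset of samples; an error lists available ids if any is absent.
#' @return A [snp_matrix()].
#' @export
read_snp_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  is_snp <- nchar(fix[, "REF"]) == 1 & !is.na(fix[, "ALT"]) &
    nchar(fix[, "ALT"]) == 1 & !grepl(",", fix[, "ALT"], fixed = TRUE)
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0) {
    message(n_skipped, " non-SNP or multi-allelic record(s) skipped")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  avail <- colnames(gt)
  if (is.null(samples)) {
    samples <- avail
  } else {
    absent <- setdiff(samples, avail)
    if (length(absent) > 0) {
      rlang::abort(paste0(
        "sample(s) not in VCF: ", paste(absent, collapse = ", "),
        "; available: ", paste(avail, collapse = ", ")
      ))
    }
  }
  gt <- gt[, samples, drop = FALSE]
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- (a1 == "1") + (a2 == "1")
  dos[a1 %in% c(".", "") | a2 %in% c(".", "")] <- NA
  dos <- matrix(as.integer(dos), nrow = nrow(gt),
    dimnames = dimnames(gt))
  out <- snp_matrix(
    dosage = t(dos),
    sites = tibble::tibble(
      chrom = fix[, "CHROM"],
      pos = as.integer(fix[, "POS"]),
      ref = fix[, "REF"],
      alt = fix[, "ALT"]
    )
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Filter SNP sites: complete-case, then polymorphic
#'
#' Drops every site with at least one missing call among the retained
#' samples, then every site at which all samples share the same dosage
#' (monomorphic). Site order is preserved. Counts of sites dropped at each
#' step are stored in attributes `n_dropped_missing` and
#' `n_dropped_monomorphic`.
#'
#' @param m A [snp_matrix()].
#' @return A filtered `snp_matrix`; error if no site survives.
#' @export
filter_snp_sites <- function(m) {
  X <- m$dosage
  if (ncol(X) == 0) rlang::abort("empty SNP matrix")
  has_missing <- colSums(is.na(X)) > 0
  X1 <- X[, !has_missing, drop = FALSE]
  mono <- apply(X1, 2, function(v) length(unique(v)) == 1)
  keep <- !mono
  X2 <- X1[, keep, drop = FALSE]
  if (ncol(X2) == 0) {
    rlang::abort("no site survives filtering (missing-data and monomorphic removal)")
  }
  out <- snp_matrix(X2, m$sites[!has_missing, ][keep, ])
  attr(out, "n_dropped_missing") <- sum(has_missing)
  attr(out, "n_dropped_monomorphic") <- sum(mono)
  out
}

# mean |dosage difference| / 2 across sites, i.e. fraction of allele copies
# differing; equals 1 - IBS for dosage data
dosage_distance_matrix <- function(m) {
  X <- m$dosage
  if (ncol(X) == 0) rlang::abort("no sites available")
  if (anyNA(X)) rlang::abort("missing calls present; run filter_snp_sites() first")
  D <- as.matrix(stats::dist(X, method = "manhattan")) / (2 * ncol(X))
  dimnames(D) <- list(m$samples, m$samples)
  D
}

#' Identity-by-state genetic distance
#'
#' Per pair of samples, per-site identity-by-state for dosages `d_a`, `d_b`
#' is `1 - |d_a - d_b| / 2` (the shared fraction of allele copies); pair
#' IBS is the mean over sites and the genetic distance is `GD = 1 - IBS`.
#'
#' @param m A filtered [snp_matrix()] (no missing calls).
#' @return Symmetric matrix of GD in \[0, 1\] with zero diagonal, sample
#'   ids as dimnames.
#' @export
ibs_distance <- function(m) {
  ibs_site_mean <- 1 - dosage_distance_matrix(m)
  1 - ibs_site_mean
}

#' Hamming (bitwise) genetic distance on dosages
#'
#' Per pair of samples the per-site contribution is `|d_a - d_b| / 2`, the
#' fraction of differing allele copies; the distance is the mean over
#' sites. For diploid dosage data this coincides with `1 - IBS` (see
#' [ibs_distance()]).
#'
#' @inheritParams ibs_distance
#' @return Symmetric matrix in \[0, 1\], sample ids as dimnames.
#' @export
hamming_distance <- function(m) {
  dosage_distance_matrix(m)
}

#' UPGMA clustering of a distance matrix
#'
#' Average-linkage agglomeration: at each step the pair of clusters with
#' the smallest average between-cluster distance is merged at a node of
#' height equal to half that distance, giving an ultrametric rooted tree.
#' Exact ties are broken deterministically by the lexicographically
#' smallest pair of cluster representative labels.
#'
#' @param d Symmetric distance matrix with sample ids as dimnames (or a
#'   `dist` object with labels).
#' @return An [ape::phylo] rooted ultrametric tree.
#' @examples
#' d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
#'   dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(d)
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-12)) {
    rlang::abort("distance matrix must be symmetric")
  }
  n <- nrow(d)
  if (n < 2) rlang::abort("need at least 2 samples")
  labs <- rownames(d)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  D <- unname(d)
  # live clusters: newick fragment, height, size, representative (min) label
  nwk <- labs
  height <- rep(0, n)
  size <- rep(1L, n)
  rep_lab <- labs
  alive <- rep(TRUE, n)
  for (step in seq_len(n - 1)) {
    idx <- which(alive)
    pairs <- which(upper.tri(matrix(0, length(idx), length(idx))), arr.ind = TRUE)
    dij <- D[cbind(idx[pairs[, 1]], idx[pairs[, 2]])]
    dmin <- min(dij)
    cand <- which(dij == dmin)
    if (length(cand) > 1) {
      la <- rep_lab[idx[pairs[cand, 1]]]
      lb <- rep_lab[idx[pairs[cand, 2]]]
      lo <- pmin(la, lb)
      hi <- pmax(la, lb)
      cand <- cand[order(lo, hi)][1]
    }
    i <- idx[pairs[cand, 1]]
    j <- idx[pairs[cand, 2]]
    h <- dmin / 2
    nwk_new <- sprintf("(%s:%.10g,%s:%.10g)",
      nwk[i], h - height[i], nwk[j], h - height[j])
    # UPGMA update: size-weighted average of distances to the merged pair
    idx_other <- setdiff(idx, c(i, j))
    newd <- (size[i] * D[i, idx_other] + size[j] * D[j, idx_other]) /
      (size[i] + size[j])
    D[i, idx_other] <- newd
    D[idx_other, i] <- newd
    nwk[i] <- nwk_new
    height[i] <- h
    size[i] <- size[i] + size[j]
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    alive[j] <- FALSE
  }
  ape::read.tree(text = paste0(nwk[alive], ";"))
}

#' UPGMA tree with locus-bootstrap support values
#'
#' Builds the UPGMA tree from the full SNP matrix, then resamples sites
#' (columns) with replacement `B` times, rebuilding distance and tree each
#' time. The support of each internal node of the original tree is the
#' percentage of bootstrap trees containing the same set of leaves below a
#' node, stored in `node.label`.
#'
#' @param m A filtered [snp_matrix()].
#' @param B Number of bootstrap replicates (>= 1; 1000 in typical use).
#' @param seed Optional integer seed for reproducible resampling.
#' @param distance `"hamming"` (default) or `"ibs"`.
#' @return An [ape::phylo] with integer `node.label` supports in \[0, 100\].
#' @export
bootstrap_upgma <- function(m, B = 1000, seed = NULL,
                            distance = c("hamming", "ibs")) {
  distance <- match.arg(distance)
  if (B < 1) rlang::abort("B must be >= 1")
  distfun <- if (distance == "hamming") hamming_distance else ibs_distance
  tree <- upgma(distfun(m))
  if (!is.null(seed)) set.seed(seed)
  L <- ncol(m$dosage)
  boot <- vector("list", B)
  for (k in seq_len(B)) {
    take <- sample.int(L, L, replace = TRUE)
    mk <- snp_matrix(m$dosage[, take, drop = FALSE], m$sites[take, ])
    boot[[k]] <- upgma(distfun(mk))
  }
  class(boot) <- "multiPhylo"
  counts <- ape::prop.clades(tree, boot, rooted = TRUE)
  counts[is.na(counts)] <- 0
  tree$node.label <- as.character(round(100 * counts / B))
  tree
}

#' Write / read a tree in Newick format
#'
#' Thin wrappers around [ape::write.tree()] and [ape::read.tree()];
#' bootstrap supports stored in `node.label` are serialized as internal
#' node labels.
#'
#' @param tree An [ape::phylo].
#' @param path Output file.
#' @return `write_newick()` returns `path` invisibly; `read_newick()`
#'   returns a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
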