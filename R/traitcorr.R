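#' Number of unique trait pairs
#'
#' @param t Number of traits (>= 2).
#' @return `t (t - 1) / 2`.
#' @examples
#' count_trait_pairs(28)
#' @export
count_trait_pairs <- function(t) {
  if (t < 2) rlang::abort("need at least 2 traits")
  t * (t - 1) / 2
}

#' Bonferroni-corrected critical correlation coefficient
#'
#' The smallest |r| significant at family-wise level `alpha` across `m`
#' two-sided tests of zero correlation with `n` observations each:
#' `r* = t* / sqrt(t*^2 + n - 2)` where `t*` is the upper `alpha / (2 m)`
#' quantile of Student's t with `n - 2` degrees of freedom. Screening
#' `|r| >= r*` is the same decision rule as Bonferroni-adjusting each
#' pair's p-value.
#'
#' @param n Sample size per correlation (>= 4).
#' @param m Number of comparisons (>= 1).
#' @param alpha Family-wise significance level in (0, 1).
#' @return The critical |r|.
#' @examples
#' bonferroni_critical_r(n = 55, m = 378, alpha = 0.05)
#' @export
bonferroni_critical_r <- function(n, m, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    rlang::abort("alpha must be in (0, 1)")
  }
  if (n < 4) rlang::abort("n must be >= 4")
  if (m < 1) rlang::abort("m must be >= 1")
  tstar <- stats::qt(1 - alpha / (2 * m), df = n - 2)
  tstar / sqrt(tstar^2 + n - 2)
}

#' Pairwise Pearson correlations among traits with Bonferroni screening
#'
#' Correlates traits across genotype means (parents and hybrids together,
#' `n = p(p+1)/2` for a complete design), and flags pairs whose |r| reaches
#' the Bonferroni critical value for `m = t(t-1)/2` comparisons. Genotypes
#' missing a trait are dropped pairwise; traits with zero variance give
#' `r = NA` and are flagged `degenerate`.
#'
#' @param x A `diallel_pheno` tibble, or a wide data frame / matrix of
#'   genotypes x traits (numeric columns).
#' @param alpha Family-wise level for the Bonferroni screen.
#' @return Object of class `trait_corr`: list with `r` (t x t matrix),
#'   `pairs` (long tibble `trait_a`, `trait_b`, `r`, `significant`,
#'   `degenerate`), `n`, `m`, `alpha`, `critical_r`.
#' @examples
#' sim <- simulate_diallel(p = 5, b = 3, traits = c("a", "b", "c"), seed = 1)
#' trait_correlations(sim$phenotypes)
#' @export
trait_correlations <- function(x, alpha = 0.05) {
  if (inherits(x, "diallel_pheno")) {
    wide <- genotype_means(x) |>
      tidyr::pivot_wider(
        id_cols = c("parent_a", "parent_b"),
        names_from = "trait", values_from = "mean"
      )
    W <- as.matrix(wide[, -(1:2), drop = FALSE])
  } else {
    W <- as.matrix(as.data.frame(x))
  }
  if (!is.numeric(W)) rlang::abort("trait values must be numeric")
  if (nrow(W) < 3) rlang::abort("need at least 3 genotypes")
  if (ncol(W) < 2) rlang::abort("need at least 2 traits")
  t_ <- ncol(W)
  m <- count_trait_pairs(t_)
  n <- nrow(W)
  degen <- apply(W, 2, function(v) stats::sd(v, na.rm = TRUE) == 0)
  r <- suppressWarnings(stats::cor(W, use = "pairwise.complete.obs"))
  diag(r) <- 1
  crit <- bonferroni_critical_r(n, m, alpha)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  pairs <- tibble::tibble(
    trait_a = colnames(r)[ut[, 1]],
    trait_b = colnames(r)[ut[, 2]],
    r = r[ut],
    degenerate = degen[ut[, 1]] | degen[ut[, 2]]
  )
  pairs$r[pairs$degenerate] <- NA_real_
  pairs$significant <- !pairs$degenerate & abs(pairs$r) >= crit
  structure(list(
    r = r, pairs = pairs, n = n, m = m, alpha = alpha, critical_r = crit
  ), class = "trait_corr")
}

#' @export
print.trait_corr <- function(x, ...) {
  cat("<trait_corr> ", ncol(x$r), " traits, n = ", x$n,
    " genotypes, m = ", x$m, " pairs\n",
    "Bonferroni critical |r| at alpha = ", x$alpha, ": ",
    round(x$critical_r, 4), "\n",
    sum(x$pairs$significant), " significant pair(s)\n", sep = "")
  invisible(x)
}

#' @rdname tidy.diallel_fit
#' @export
tidy.trait_corr <- function(x, ...) x$pairs

#' Correlation heatmap for a `trait_corr` object
#'
#' @param object A `trait_corr`.
#' @param ... Unused.
#' @return A ggplot tile heatmap of r, significant pairs outlined.
#' @export
autoplot.trait_corr <- function(object, ...) {
  lv <- colnames(object$r)
  d <- dplyr::bind_rows(
    object$pairs,
    dplyr::rename(object$pairs, trait_a = "trait_b", trait_b = "trait_a")
  )
  d$trait_a <- factor(d$trait_a, levels = lv)
  d$trait_b <- factor(d$trait_b, levels = lv)
  ggplot2::ggplot(d, ggplot2::aes(.data$trait_a, .data$trait_b,
    fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(
      data = dplyr::filter(d, .data$significant),
      colour = "black", linewidth = 0.4
    ) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
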