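#' Genotype cell means for a half-diallel trait
#'
#' Averages plot observations over blocks into the symmetric p x p matrix
#' of genotype means that Griffing's Method 2 formulas operate on, together
#' with its margins: row totals `x_i.` (each symmetric row summed with the
#' diagonal counted once) and the grand total `x..` over the upper triangle
#' (each genotype once). With this margin convention `x_i. + x_ii` counts
#' the self cross twice, which is what makes the GCA/SCA partition identity
#' hold.
#'
#' @param table A `diallel_pheno` tibble.
#' @param trait Trait name (exact, case-sensitive).
#' @return Object of class `diallel_means`: list with `matrix` (p x p,
#'   dimnames = parent ids), `row_total`, `grand_total`, `b`, `p`, `trait`,
#'   `parents`.
#' @export
cell_means <- function(table, trait) {
  ids <- diallel_parents(table)
  p <- length(ids)
  d <- table[table$trait == trait, ]
  if (nrow(d) == 0) rlang::abort(paste0("trait not found: ", trait))
  blocks <- sort(unique(d$block))
  b <- length(blocks)
  key <- paste(d$parent_a, d$parent_b, sep = "\r")
  grid <- genotype_grid(ids)
  gkey <- paste(grid$parent_a, grid$parent_b, sep = "\r")
  cnt <- table(factor(key, levels = gkey))
  if (any(cnt != b)) {
    missing <- grid[cnt < b, , drop = FALSE]
    rlang::abort(paste0(
      "incomplete design for trait ", trait, ": ",
      sum(cnt < b), " genotype(s) lack observations in some block, e.g. ",
      paste(utils::head(paste0(missing$parent_a, "x", missing$parent_b), 5),
        collapse = ", ")
    ), class = "diallelkit_incomplete_design")
  }
  mns <- tapply(d$value, factor(key, levels = gkey), mean)
  M <- matrix(0, p, p, dimnames = list(ids, ids))
  idx <- cbind(match(grid$parent_a, ids), match(grid$parent_b, ids))
  M[idx] <- mns
  M[idx[, c(2, 1)]] <- mns
  structure(list(
    matrix = M,
    row_total = rowSums(M),
    grand_total = sum(M[upper.tri(M, diag = TRUE)]),
    b = b, p = p, trait = trait, parents = ids
  ), class = "diallel_means")
}

#' Randomized complete block ANOVA for genotypes
#'
#' Two-way decomposition of plot values into block, genotype and error
#' strata, treating each of the p(p+1)/2 diallel genotypes as a level of a
#' single genotype factor (fit with [stats::aov()]). Degrees of freedom are
#' b-1, p(p+1)/2 - 1 and (p(p+1)/2 - 1)(b - 1).
#'
#' @inheritParams cell_means
#' @return Tibble with rows `Blocks`, `Genotypes`, `Error` and columns
#'   `source`, `df`, `ss`, `ms`, `statistic`, `p_value` (F against the
#'   error mean square).
#' @export
rcbd_anova <- function(table, trait) {
  cm <- cell_means(table, trait)       # validates completeness
  if (cm$b < 2) {
    rlang::abort("need at least 2 blocks for an error stratum",
      class = "diallelkit_incomplete_design")
  }
  d <- table[table$trait == trait, ]
  geno <- factor(paste(d$parent_a, d$parent_b, sep = ":"))
  block <- factor(d$block)
  fit <- stats::aov(d$value ~ block + geno)
  sm <- summary(fit)[[1]]
  ss <- sm[["Sum Sq"]]
  df <- sm[["Df"]]
  ms <- ss / df
  f <- c(ms[1] / ms[3], ms[2] / ms[3], NA)
  pv <- c(
    stats::pf(f[1], df[1], df[3], lower.tail = FALSE),
    stats::pf(f[2], df[2], df[3], lower.tail = FALSE),
    NA
  )
  tibble::tibble(
    source = c("Blocks", "Genotypes", "Error"),
    df = df, ss = ss, ms = ms, statistic = f, p_value = pv
  )
}

# Griffing Method 2 sums of squares on the genotype-mean basis.
griffing_ss_means <- function(means) {
  M <- means$matrix
  p <- means$p
  ti <- means$row_total + diag(M)     # x_i. + x_ii
  xdd <- means$grand_total
  ss_gca <- sum(ti^2) / (p + 2) - 4 * xdd^2 / (p * (p + 2))
  ss_sca <- sum(M[upper.tri(M, diag = TRUE)]^2) -
    sum(ti^2) / (p + 2) + 2 * xdd^2 / ((p + 1) * (p + 2))
  c(gca = ss_gca, sca = ss_sca)
}

#' Griffing Method 2 partition of the genotype sum of squares
#'
#' Splits the genotype variation of a half-diallel with parents into
#' general (GCA) and specific (SCA) combining-ability components. On the
#' genotype-mean basis,
#' \deqn{SS'_{GCA} = \frac{1}{p+2}\sum_i (x_{i.}+x_{ii})^2 -
#'   \frac{4}{p(p+2)} x_{..}^2}
#' \deqn{SS'_{SCA} = \sum_{i \le j} x_{ij}^2 -
#'   \frac{1}{p+2}\sum_i (x_{i.}+x_{ii})^2 +
#'   \frac{2}{(p+1)(p+2)} x_{..}^2}
#' each multiplied by the number of blocks `b` to place them on the plot
#' basis of the RCBD error, so that `SS_GCA + SS_SCA` equals the genotype
#' sum of squares from [rcbd_anova()].
#'
#' @param means A `diallel_means` object from [cell_means()].
#' @return Tibble with rows `GCA` (df p-1) and `SCA` (df p(p-1)/2),
#'   columns `source`, `df`, `ss`, `ms`.
#' @export
griffing_partition <- function(means) {
  p <- means$p
  if (p < 3) {
    if (p == 2) {
      rlang::warn("p = 2 leaves 0 df for SCA; partition is degenerate")
    } else {
      rlang::abort("need at least 3 parents")
    }
  }
  ssm <- griffing_ss_means(means)
  df <- c(p - 1, p * (p - 1) / 2)
  ss <- means$b * ssm
  tibble::tibble(
    source = c("GCA", "SCA"),
    df = df, ss = unname(ss), ms = unname(ss) / df
  )
}

#' Full diallel ANOVA table (Blocks, Genotypes, GCA, SCA, Error)
#'
#' Combines [rcbd_anova()] with [griffing_partition()]; all F statistics
#' are against the RCBD error mean square, as in a fixed-effects Model 1
#' analysis.
#'
#' @inheritParams cell_means
#' @return Tibble with columns `source`, `df`, `ss`, `ms`, `statistic`,
#'   `p_value`.
#' @examples
#' sim <- simulate_diallel(p = 5, b = 3, seed = 42)
#' diallel_anova(sim$phenotypes, "y")
#' @export
diallel_anova <- function(table, trait) {
  rc <- rcbd_anova(table, trait)
  gp <- griffing_partition(cell_means(table, trait))
  mse <- rc$ms[rc$source == "Error"]
  dfe <- rc$df[rc$source == "Error"]
  gp$statistic <- gp$ms / mse
  gp$p_value <- stats::pf(gp$statistic, gp$df, dfe, lower.tail = FALSE)
  dplyr::bind_rows(
    rc[rc$source == "Blocks", ],
    rc[rc$source == "Genotypes", ],
    gp,
    rc[rc$source == "Error", ]
  )
}

#' Estimate combining-ability effects (Griffing Method 2 Model 1)
#'
#' \deqn{\hat\mu = \frac{2}{p(p+1)} x_{..}}
#' \deqn{\hat g_i = \frac{1}{p+2}\left(x_{i.} + x_{ii} - \frac{2}{p} x_{..}\right)}
#' \deqn{\hat s_{ij} = x_{ij} - \frac{1}{p+2}(x_{i.}+x_{ii}+x_{j.}+x_{jj})
#'   + \frac{2}{(p+1)(p+2)} x_{..}}
#' The model is saturated: \eqn{\hat\mu + \hat g_i + \hat g_j + \hat s_{ij}}
#' reproduces every off-diagonal cell mean exactly and
#' \eqn{\hat\mu + 2\hat g_i + \hat s_{ii}} every self; effects satisfy
#' \eqn{\sum_i \hat g_i = 0} and \eqn{\sum_j \hat s_{ij} + \hat s_{ii} = 0}.
#'
#' @param means A `diallel_means` object from [cell_means()].
#' @return Object of class `combining_abilities`: list with `mu`, `gca`
#'   (tibble `parent`, `gca`), `sca` (tibble `parent_a`, `parent_b`, `sca`,
#'   selfs included), `trait`, `p`.
#' @export
estimate_effects <- function(means) {
  M <- means$matrix
  p <- means$p
  ids <- means$parents
  ti <- means$row_total + diag(M)
  xdd <- means$grand_total
  mu <- 2 * xdd / (p * (p + 1))
  g <- (ti - 2 * xdd / p) / (p + 2)
  grid <- genotype_grid(ids)
  ia <- match(grid$parent_a, ids)
  ib <- match(grid$parent_b, ids)
  s <- M[cbind(ia, ib)] - (ti[ia] + ti[ib]) / (p + 2) +
    2 * xdd / ((p + 1) * (p + 2))
  structure(list(
    mu = mu,
    gca = tibble::tibble(parent = ids, gca = unname(g)),
    sca = tibble::tibble(parent_a = grid$parent_a, parent_b = grid$parent_b,
      sca = unname(s)),
    trait = means$trait, p = p
  ), class = "combining_abilities")
}

#' @export
print.combining_abilities <- function(x, ...) {
  cat("<combining_abilities> trait:", x$trait, " mu =", signif(x$mu, 6), "\n")
  print(x$gca)
  invisible(x)
}

#' Variance components and GCA/SCA ratios from diallel mean squares
#'
#' From plot-basis mean squares of a Method 2 Model 1 analysis:
#' `sigma2_gca = (MS_GCA - MS_error) / (p + 2)`,
#' `sigma2_sca = MS_SCA - MS_error`, `sigma2_error = MS_error`.
#' Two ratio conventions are returned: `ratio_component =
#' sigma2_gca / sigma2_sca` (the convention that reproduces published
#' GCA/SCA columns computed this way) and Baker's
#' `ratio_baker = 2 sigma2_gca / (2 sigma2_gca + sigma2_sca)`. Negative
#' components are reported as-is with a flag, never truncated here.
#'
#' @param x Either the ANOVA tibble from [diallel_anova()] or a numeric
#'   vector `c(ms_gca, ms_sca, ms_error)`.
#' @param p Number of parents.
#' @return One-row tibble: `sigma2_gca`, `sigma2_sca`, `sigma2_error`,
#'   `ratio_component`, `ratio_baker`, `negative_gca`, `negative_sca`,
#'   `ratio_undefined`.
#' @examples
#' # from published mean squares (p = 10): ratio_component
#' variance_components(c(5.73, 3.26, 0.17), p = 10)
#' @export
variance_components <- function(x, p) {
  if (is.data.frame(x)) {
    ms <- c(
      x$ms[x$source == "GCA"],
      x$ms[x$source == "SCA"],
      x$ms[x$source == "Error"]
    )
    if (length(ms) != 3) rlang::abort("ANOVA table lacks GCA/SCA/Error rows")
  } else {
    ms <- as.numeric(x)
    if (length(ms) != 3) rlang::abort("supply c(ms_gca, ms_sca, ms_error)")
  }
  s2g <- (ms[1] - ms[3]) / (p + 2)
  s2s <- ms[2] - ms[3]
  ratio_comp <- if (s2s > 0) s2g / s2s else NA_real_
  denom <- 2 * s2g + s2s
  ratio_baker <- if (denom != 0) 2 * s2g / denom else NA_real_
  tibble::tibble(
    sigma2_gca = s2g, sigma2_sca = s2s, sigma2_error = ms[3],
    ratio_component = ratio_comp, ratio_baker = ratio_baker,
    negative_gca = s2g < 0, negative_sca = s2s < 0,
    ratio_undefined = s2s <= 0 || denom == 0
  )
}

#' Narrow- and broad-sense heritability from variance components
#'
#' Default component-based formulas:
#' `h2 = 2 s2g / (2 s2g + s2s + s2e)` and
#' `H2 = (2 s2g + s2s) / (2 s2g + s2s + s2e)`. Negative components are
#' clamped to zero (flagged) inside the heritability computation only. The
#' alternative `method = "genotypic"` broad-sense estimate
#' `((MS_gen - MS_e)/b) / ((MS_gen - MS_e)/b + MS_e)` is available when
#' `ms_genotypes` and `b` are supplied.
#'
#' @param vc One-row tibble from [variance_components()].
#' @param method `"components"` (default) or `"genotypic"` for H2.
#' @param ms_genotypes,b Genotypes mean square and block count, needed only
#'   for `method = "genotypic"`.
#' @return One-row tibble `h2`, `H2`, `clamped`, `undefined`.
#' @export
heritabilities <- function(vc, method = c("components", "genotypic"),
                           ms_genotypes = NULL, b = NULL) {
  method <- match.arg(method)
  s2g <- max(vc$sigma2_gca, 0)
  s2s <- max(vc$sigma2_sca, 0)
  s2e <- max(vc$sigma2_error, 0)
  clamped <- (vc$sigma2_gca < 0) || (vc$sigma2_sca < 0)
  tot <- 2 * s2g + s2s + s2e
  if (tot == 0) {
    return(tibble::tibble(h2 = NA_real_, H2 = NA_real_, clamped = clamped,
      undefined = TRUE))
  }
  h2 <- 2 * s2g / tot
  if (method == "genotypic") {
    if (is.null(ms_genotypes) || is.null(b)) {
      rlang::abort("method = 'genotypic' requires ms_genotypes and b")
    }
    s2gen <- max((ms_genotypes - vc$sigma2_error) / b, 0)
    H2 <- s2gen / (s2gen + vc$sigma2_error)
  } else {
    H2 <- (2 * s2g + s2s) / tot
  }
  tibble::tibble(h2 = h2, H2 = H2, clamped = clamped, undefined = FALSE)
}

#' Relative SCA of hybrids as a percentage of the hybrid mean
#'
#' Expresses each hybrid's specific combining ability as
#' `100 * s_ij / mean(hybrid genotype means)` for the trait, so values are
#' comparable across traits measured on different scales.
#'
#' @param ca A `combining_abilities` object.
#' @param table The `diallel_pheno` tibble the effects came from.
#' @param trait Trait name; defaults to the trait stored in `ca`.
#' @return Tibble `parent_a`, `parent_b`, `sca`, `sca_pct`, `undefined`
#'   (hybrids only).
#' @export
sca_percent <- function(ca, table, trait = ca$trait) {
  gm <- genotype_means(table, trait)
  hmean <- mean(gm$mean[!gm$is_self])
  hyb <- ca$sca[ca$sca$parent_a != ca$sca$parent_b, ]
  undefined <- hmean == 0
  hyb$sca_pct <- if (undefined) NA_real_ else 100 * hyb$sca / hmean
  hyb$undefined <- undefined
  hyb
}

#' Mid-parent heterosis of hybrids
#'
#' `Het = 100 * (F1 - MP) / MP`, where `F1` is the hybrid genotype mean and
#' `MP` the average of its two parents' (self) genotype means. Hybrids with
#' `MP = 0` are flagged `undefined` with `het = NA`.
#'
#' @param table A `diallel_pheno` tibble.
#' @param traits Traits to include (default all).
#' @return Tibble `parent_a`, `parent_b`, `trait`, `f1`, `mp`, `het`,
#'   `undefined`.
#' @export
heterosis <- function(table, traits = NULL) {
  gm <- genotype_means(table, traits)
  selfs <- gm[gm$is_self, c("parent_a", "trait", "mean")]
  names(selfs) <- c("parent", "trait", "self_mean")
  hyb <- gm[!gm$is_self, c("parent_a", "parent_b", "trait", "mean")]
  names(hyb)[4] <- "f1"
  hyb <- hyb |>
    dplyr::left_join(dplyr::rename(selfs, parent_a = "parent", pa_mean = "self_mean"),
      by = c("parent_a", "trait")) |>
    dplyr::left_join(dplyr::rename(selfs, parent_b = "parent", pb_mean = "self_mean"),
      by = c("parent_b", "trait"))
  if (anyNA(hyb$pa_mean) || anyNA(hyb$pb_mean)) {
    rlang::abort("some hybrids lack a parental (self) genotype mean")
  }
  hyb |>
    dplyr::mutate(
      mp = (.data$pa_mean + .data$pb_mean) / 2,
      undefined = .data$mp == 0,
      het = dplyr::if_else(.data$undefined, NA_real_,
        100 * (.data$f1 - .data$mp) / .data$mp)
    ) |>
    dplyr::select("parent_a", "parent_b", "trait", "f1", "mp", "het",
      "undefined")
}

#' Fit the full Griffing Method 2 Model 1 analysis for every trait
#'
#' Convenience wrapper running, per trait: [diallel_anova()],
#' [estimate_effects()], [variance_components()], [heritabilities()],
#' [sca_percent()] and [heterosis()]. Use [generics::tidy()] /
#' [generics::glance()] to extract tibbles, or [ggplot2::autoplot()] for a
#' GCA effect plot.
#'
#' @param table A `diallel_pheno` tibble with a complete design.
#' @param traits Traits to fit (default all in the table).
#' @return Object of class `diallel_fit`.
#' @examples
#' sim <- simulate_diallel(p = 5, b = 3, seed = 7)
#' fit <- griffing_analysis(sim$phenotypes)
#' glance(fit)
#' tidy(fit, "gca")
#' @export
griffing_analysis <- function(table, traits = NULL) {
  ids <- diallel_parents(table)
  if (is.null(traits)) traits <- unique(table$trait)
  per_trait <- lapply(traits, function(tr) {
    cm <- cell_means(table, tr)
    an <- diallel_anova(table, tr)
    eff <- estimate_effects(cm)
    vc <- variance_components(an, p = cm$p)
    h <- heritabilities(vc)
    list(
      anova = an, effects = eff, varcomp = vc, herit = h,
      sca_pct = sca_percent(eff, table, tr),
      b = cm$b
    )
  })
  names(per_trait) <- traits
  structure(list(
    traits = per_trait,
    heterosis = heterosis(table, traits),
    parents = ids,
    p = length(ids),
    b = per_trait[[1]]$b,
    table = table
  ), class = "diallel_fit")
}

#' @export
print.diallel_fit <- function(x, ...) {
  cat("<diallel_fit> Griffing Method 2 Model 1: p =", x$p,
    "parents,", x$b, "blocks,", length(x$traits), "trait(s)\n")
  print(glance(x))
  invisible(x)
}
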