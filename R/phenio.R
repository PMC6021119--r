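#' Define the set of diallel parents
#'
#' The parent set fixes the canonical parent order used throughout an
#' analysis: crosses are stored with the lower-index parent first, and
#' all effect tables are reported in this order.
#'
#' @param ids Character vector of unique parent identifiers (length >= 2).
#' @param groups Optional character vector (same length as `ids`, or a named
#'   vector keyed by id) of group labels, e.g. species. Used to form parent
#'   subsets when correlating genetic distance with hybrid performance.
#'
#' @return A tibble of class `parent_set` with columns `id` and `group`.
#' @examples
#' parent_set(c("A", "B", "C"), groups = c("mel", "mel", "ins"))
#' @export
parent_set <- function(ids, groups = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    rlang::abort("parent ids must be unique")
  }
  if (length(ids) < 2) {
    rlang::abort("need at least 2 parents")
  }
  if (is.null(groups)) {
    groups <- rep(NA_character_, length(ids))
  } else if (!is.null(names(groups))) {
    groups <- unname(groups[ids])
  }
  if (length(groups) != length(ids)) {
    rlang::abort("`groups` must match `ids` in length (or be named by id)")
  }
  out <- tibble::tibble(id = ids, group = as.character(groups))
  class(out) <- c("parent_set", class(out))
  out
}

parent_ids <- function(parents) {
  if (inherits(parents, "parent_set")) parents$id else as.character(parents)
}

#' Coerce a data frame to a validated half-diallel phenotype table
#'
#' Validates the five required columns, checks parent identifiers against
#' the parent set, and canonicalizes each cross so that the parent with the
#' lower canonical index is stored in `parent_a`. Selfs (`parent_a ==
#' parent_b`) are the parental genotypes of a Griffing Method 2 design.
#'
#' @param x A data frame with columns `parent_a`, `parent_b`, `block`,
#'   `trait`, `value` (one plot observation per row).
#' @param parents A [parent_set()] or character vector of parent ids.
#'
#' @return A tibble of class `diallel_pheno` with canonicalized pairs and a
#'   `parents` attribute holding the canonical id order.
#' @seealso [read_phenotypes()], [design_counts()]
#' @export
as_diallel_pheno <- function(x, parents) {
  ids <- parent_ids(parents)
  req <- c("parent_a", "parent_b", "block", "trait", "value")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "phenotype table lacks required column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "diallelkit_format_error")
  }
  x <- tibble::as_tibble(x)[req]
  x$parent_a <- as.character(x$parent_a)
  x$parent_b <- as.character(x$parent_b)
  bad <- setdiff(unique(c(x$parent_a, x$parent_b)), ids)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "unknown parent id(s): ", paste(bad, collapse = ", "),
      " (known: ", paste(ids, collapse = ", "), ")"
    ), class = "diallelkit_validation_error")
  }
  val <- suppressWarnings(as.numeric(x$value))
  if (anyNA(val) || any(!is.finite(val))) {
    rows <- which(is.na(val) | !is.finite(val))
    rlang::abort(paste0(
      "non-numeric or non-finite value in row(s): ",
      paste(utils::head(rows, 10), collapse = ", ")
    ), class = "diallelkit_validation_error")
  }
  x$value <- val
  x$block <- as.integer(x$block)
  if (anyNA(x$block) || any(x$block < 1)) {
    rlang::abort("`block` must be integer >= 1",
      class = "diallelkit_validation_error")
  }
  x$trait <- as.character(x$trait)
  ia <- match(x$parent_a, ids)
  ib <- match(x$parent_b, ids)
  swap <- ia > ib
  pa <- ifelse(swap, x$parent_b, x$parent_a)
  pb <- ifelse(swap, x$parent_a, x$parent_b)
  x$parent_a <- pa
  x$parent_b <- pb
  attr(x, "parents") <- ids
  class(x) <- c("diallel_pheno", class(x))
  x
}

#' Read half-diallel phenotypes from CSV
#'
#' Expects a UTF-8 CSV with header `parent_a,parent_b,block,trait,value`,
#' one plot observation per row, decimal point `.`. Crosses may appear in
#' either parent order; both orders map to the same canonical genotype.
#'
#' @inheritParams as_diallel_pheno
#' @param path Path to the CSV file.
#' @return A `diallel_pheno` tibble (see [as_diallel_pheno()]).
#' @export
read_phenotypes <- function(path, parents) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path),
      class = "diallelkit_format_error")
  }
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  as_diallel_pheno(x, parents)
}

diallel_parents <- function(table) {
  p <- attr(table, "parents")
  if (is.null(p)) {
    rlang::abort("not a diallel_pheno table; use as_diallel_pheno() first")
  }
  p
}

#' Design arithmetic and completeness of a half-diallel
#'
#' For `p` parents a half-diallel with selfs has `p(p-1)/2` hybrids and
#' `p(p+1)/2` genotypes; a complete design observes every genotype in every
#' block for every trait. Missing genotype-by-block cells are reported as a
#' warning and listed in the `missing_cells` attribute, not treated as
#' fatal — downstream Griffing analysis requires completeness and errors
#' there.
#'
#' @param table A `diallel_pheno` tibble.
#' @return One-row tibble with columns `p`, `b`, `n_hybrids`,
#'   `n_genotypes`, `complete`; attribute `missing_cells` is a tibble of
#'   absent (trait, parent_a, parent_b, block) combinations.
#' @examples
#' sim <- simulate_diallel(p = 4, b = 2, seed = 1)
#' design_counts(sim$phenotypes)
#' @export
design_counts <- function(table) {
  ids <- diallel_parents(table)
  if (nrow(table) == 0) rlang::abort("empty phenotype table")
  p <- length(ids)
  blocks <- sort(unique(table$block))
  b <- length(blocks)
  grid <- genotype_grid(ids)
  full <- tidyr::expand_grid(
    trait = unique(table$trait),
    grid,
    block = blocks
  )
  seen <- dplyr::distinct(table, .data$trait, .data$parent_a, .data$parent_b, .data$block)
  miss <- dplyr::anti_join(full, seen,
    by = c("trait", "parent_a", "parent_b", "block"))
  if (nrow(miss) > 0) {
    rlang::warn(paste0("incomplete design: ", nrow(miss),
      " missing genotype x block cell(s)"))
  }
  out <- tibble::tibble(
    p = p,
    b = b,
    n_hybrids = (p * (p - 1L)) %/% 2L,
    n_genotypes = (p * (p + 1L)) %/% 2L,
    complete = nrow(miss) == 0
  )
  attr(out, "missing_cells") <- miss
  out
}

# all unordered pairs (selfs included) in canonical order
genotype_grid <- function(ids) {
  p <- length(ids)
  idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  tibble::tibble(parent_a = ids[idx[, "row"]], parent_b = ids[idx[, "col"]])
}

#' Genotype means over blocks
#'
#' @param table A `diallel_pheno` tibble.
#' @param traits Traits to include (default all).
#' @return Tibble `parent_a`, `parent_b`, `trait`, `mean`, `n_blocks`,
#'   with `is_self` marking parental genotypes.
#' @export
genotype_means <- function(table, traits = NULL) {
  if (!is.null(traits)) table <- dplyr::filter(table, .data$trait %in% traits)
  table |>
    dplyr::group_by(.data$parent_a, .data$parent_b, .data$trait) |>
    dplyr::summarise(
      mean = mean(.data$value), n_blocks = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(is_self = .data$parent_a == .data$parent_b)
}

#' Compare parent and hybrid groups per trait
#'
#' Means, ranges and a two-sided two-sample t-test comparing the group of
#' parental genotype means with the group of hybrid genotype means, as used
#' to ask whether hybrids as a group outperform their parents. Welch's
#' unequal-variance test is the default; set `var_equal = TRUE` for the
#' pooled-variance variant. If both groups are constant the statistic is
#' undefined: the row is flagged `degenerate` with `statistic = 0`,
#' `p_value = 1`.
#'
#' @param table A `diallel_pheno` tibble.
#' @param traits Traits to include (default all).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Tibble with one row per trait: group means, ranges, `statistic`,
#'   `p_value`, `degenerate`.
#' @export
group_compare <- function(table, traits = NULL, var_equal = FALSE) {
  gm <- genotype_means(table, traits)
  gm |>
    dplyr::group_by(.data$trait) |>
    dplyr::group_modify(function(d, key) {
      pv <- d$mean[d$is_self]
      hv <- d$mean[!d$is_self]
      if (length(pv) < 2 || length(hv) < 2) {
        rlang::abort(paste0("need >= 2 parents and >= 2 hybrids with data for trait ",
          key$trait))
      }
      degenerate <- stats::sd(pv) == 0 && stats::sd(hv) == 0
      if (degenerate) {
        stat <- 0; pval <- 1
      } else {
        tt <- stats::t.test(pv, hv, var.equal = var_equal)
        stat <- unname(tt$statistic); pval <- tt$p.value
      }
      tibble::tibble(
        parent_mean = mean(pv), parent_min = min(pv), parent_max = max(pv),
        hybrid_mean = mean(hv), hybrid_min = min(hv), hybrid_max = max(hv),
        statistic = stat, p_value = pval, degenerate = degenerate
      )
    }) |>
    dplyr::ungroup()
}

#' @export
print.diallel_pheno <- function(x, ...) {
  ids <- attr(x, "parents")
  cat("<diallel_pheno> ", length(ids), " parents, ",
    length(unique(x$trait)), " trait(s), ",
    length(unique(x$block)), " block(s)\n", sep = "")
  NextMethod()
}
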