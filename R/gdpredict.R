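#' Join genetic distance with per-hybrid responses
#'
#' Builds one record per hybrid of the (sub)set of parents, carrying the
#' parents' genetic distance alongside the hybrid's genotype mean, its
#' mid-parent heterosis and its specific combining ability for every trait.
#' This is the table on which genetic distance is evaluated as a predictor
#' of hybrid performance.
#'
#' @param gd Symmetric genetic-distance matrix whose dimnames are parent
#'   ids (e.g. from [ibs_distance()]).
#' @param table A `diallel_pheno` tibble covering the same parents.
#' @param het Heterosis tibble from [heterosis()]; computed from `table`
#'   when `NULL`.
#' @param sca Long SCA tibble (`trait`, `parent_a`, `parent_b`, `sca`),
#'   e.g. `tidy(fit, "sca")`; computed from `table` when `NULL`.
#' @param subset Optional character vector of parent ids: only hybrids with
#'   both parents in the subset are kept (e.g. excluding a wild parent).
#' @return Long tibble: `parent_a`, `parent_b`, `gd`, `trait`, `value`,
#'   `het`, `sca` (hybrids only).
#' @export
assemble_hybrid_records <- function(gd, table, het = NULL, sca = NULL,
                                    subset = NULL) {
  ids <- diallel_parents(table)
  if (is.null(subset)) subset <- ids
  subset <- intersect(ids, subset)
  if (length(subset) < 3) {
    rlang::abort("parent subset must contain at least 3 parents")
  }
  absent <- setdiff(subset, rownames(gd))
  if (length(absent) > 0) {
    rlang::abort(paste0("parent(s) missing from the distance matrix: ",
      paste(absent, collapse = ", ")))
  }
  if (is.null(het)) het <- heterosis(table)
  if (is.null(sca)) {
    sca <- purrr::map(unique(table$trait), function(tr) {
      eff <- estimate_effects(cell_means(table, tr))
      dplyr::mutate(eff$sca, trait = tr, .before = 1)
    }) |> purrr::list_rbind()
  }
  gm <- genotype_means(table)
  hyb <- gm[!gm$is_self &
    gm$parent_a %in% subset & gm$parent_b %in% subset, ]
  rec <- hyb |>
    dplyr::transmute(
      parent_a = .data$parent_a, parent_b = .data$parent_b,
      gd = gd[cbind(.data$parent_a, .data$parent_b)],
      trait = .data$trait, value = .data$mean
    ) |>
    dplyr::left_join(
      dplyr::select(het, "parent_a", "parent_b", "trait", "het"),
      by = c("parent_a", "parent_b", "trait")
    ) |>
    dplyr::left_join(
      dplyr::select(sca, "parent_a", "parent_b", "trait", "sca"),
      by = c("parent_a", "parent_b", "trait")
    )
  if (anyNA(rec$het) || anyNA(rec$sca)) {
    miss <- rec[is.na(rec$het) | is.na(rec$sca), ]
    rlang::abort(paste0(
      "hybrid(s) missing from heterosis or SCA input: ",
      paste(utils::head(unique(paste0(miss$parent_a, "x", miss$parent_b)), 5),
        collapse = ", ")
    ))
  }
  rec
}

#' Correlate genetic distance with hybrid responses
#'
#' Pearson correlation (with two-sided p from [stats::cor.test()], `n - 2`
#' df) of parental genetic distance against each of the three per-hybrid
#' responses — trait value, mid-parent heterosis, SCA — per trait.
#' Significance stars are per-cell and unadjusted (`*`, `**`, `***` at
#' 0.05, 0.01, 0.001); set `adjust = "bonferroni"` to Bonferroni-adjust the
#' p-values across all cells of the report instead.
#'
#' @param records Output of [assemble_hybrid_records()].
#' @param adjust `"none"` (default) or a [stats::p.adjust()] method applied
#'   across all trait x response cells.
#' @return Tibble: `trait`, `response` (value / het / sca), `n`, `r`,
#'   `p_value`, `stars`, `degenerate`.
#' @export
gd_correlations <- function(records, adjust = "none") {
  if (length(unique(paste(records$parent_a, records$parent_b))) < 3) {
    rlang::abort("need at least 3 hybrids")
  }
  out <- records |>
    tidyr::pivot_longer(c("value", "het", "sca"),
      names_to = "response", values_to = "y") |>
    dplyr::group_by(.data$trait, .data$response) |>
    dplyr::group_modify(function(d, key) {
      ok <- is.finite(d$y) & is.finite(d$gd)
      degen <- sum(ok) < 3 || stats::sd(d$y[ok]) == 0 || stats::sd(d$gd[ok]) == 0
      if (degen) {
        tibble::tibble(n = sum(ok), r = NA_real_, p_value = NA_real_,
          degenerate = TRUE)
      } else {
        ct <- stats::cor.test(d$gd[ok], d$y[ok])
        tibble::tibble(n = sum(ok), r = unname(ct$estimate),
          p_value = ct$p.value, degenerate = FALSE)
      }
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(response = factor(.data$response,
      levels = c("value", "het", "sca"))) |>
    dplyr::arrange(.data$trait, .data$response)
  if (adjust != "none") {
    out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  }
  out$stars <- dplyr::case_when(
    is.na(out$p_value) ~ "",
    out$p_value < 0.001 ~ "***",
    out$p_value < 0.01 ~ "**",
    out$p_value < 0.05 ~ "*",
    TRUE ~ ""
  )
  out
}
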