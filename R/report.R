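write_manifest <- function(out_dir, step, params, files) {
  manifest <- list(
    step = step,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "diallelkit",
    version = as.character(utils::packageVersion("diallelkit")),
    params = params,
    files = files
  )
  jsonlite::write_json(manifest,
    file.path(out_dir, paste0(step, "_manifest.json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the combining-ability analysis and write its report files
#'
#' Fits [griffing_analysis()] on every trait and writes `anova.csv`,
#' `gca.csv`, `sca.csv`, `varcomp.csv` (variance components, ratios,
#' heritabilities), `heterosis.csv`, `sca_percent.csv`,
#' `group_compare.csv`, and a run-manifest JSON recording the parameters
#' used.
#'
#' @param table A `diallel_pheno` tibble (complete design).
#' @param out_dir Output directory (created if absent).
#' @return The `diallel_fit`, invisibly.
#' @export
write_diallel_report <- function(table, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- griffing_analysis(table)
  files <- c(
    anova = "anova.csv", gca = "gca.csv", sca = "sca.csv",
    varcomp = "varcomp.csv", heterosis = "heterosis.csv",
    sca_percent = "sca_percent.csv"
  )
  for (w in names(files)) {
    readr::write_csv(tidy(fit, w), file.path(out_dir, files[[w]]))
  }
  readr::write_csv(group_compare(table),
    file.path(out_dir, "group_compare.csv"))
  write_manifest(out_dir, "diallel",
    params = list(p = fit$p, b = fit$b, traits = names(fit$traits)),
    files = c(unname(files), "group_compare.csv"))
  invisible(fit)
}

#' Compute genetic distances and a bootstrapped UPGMA tree; write files
#'
#' Reads (or takes) an SNP matrix, applies [filter_snp_sites()], writes the
#' IBS genetic-distance matrix (`gd_matrix.csv`, square with id header row
#' and column), the bootstrapped UPGMA tree (`tree.nwk`, Hamming distance)
#' and a manifest logging the site-filtering counts.
#'
#' @param x A [snp_matrix()] or a VCF file path.
#' @param out_dir Output directory.
#' @param samples Optional sample subset (passed to [read_snp_vcf()]).
#' @param B Bootstrap replicates for [bootstrap_upgma()].
#' @param seed Integer seed for the bootstrap.
#' @return List with `gd` (matrix), `tree` (`phylo`), `filtered`
#'   (`snp_matrix`), invisibly.
#' @export
write_distance_report <- function(x, out_dir, samples = NULL, B = 1000,
                                  seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  m <- if (inherits(x, "snp_matrix")) x else read_snp_vcf(x, samples)
  mf <- filter_snp_sites(m)
  message("sites retained: ", ncol(mf$dosage),
    " (dropped ", attr(mf, "n_dropped_missing"), " with missing calls, ",
    attr(mf, "n_dropped_monomorphic"), " monomorphic)")
  gd <- ibs_distance(mf)
  tree <- bootstrap_upgma(mf, B = B, seed = seed)
  utils::write.csv(gd, file.path(out_dir, "gd_matrix.csv"))
  write_newick(tree, file.path(out_dir, "tree.nwk"))
  write_manifest(out_dir, "distance",
    params = list(
      B = B, seed = seed,
      n_samples = length(mf$samples),
      n_sites_input = ncol(m$dosage),
      n_sites_retained = ncol(mf$dosage),
      n_dropped_missing = attr(mf, "n_dropped_missing"),
      n_dropped_monomorphic = attr(mf, "n_dropped_monomorphic")
    ),
    files = c("gd_matrix.csv", "tree.nwk"))
  invisible(list(gd = gd, tree = tree, filtered = mf))
}

#' Correlate genetic distance with hybrid performance; write the report
#'
#' For the full parent set and each requested subset, assembles per-hybrid
#' records ([assemble_hybrid_records()]) and writes the correlations of GD
#' with hybrid trait value, heterosis and SCA ([gd_correlations()]) as a
#' long CSV (`gd_correlations.csv`) and a wide, table-style CSV per subset
#' (`gd_correlations_wide.csv`).
#'
#' @param gd Genetic-distance matrix over parents.
#' @param table A `diallel_pheno` tibble.
#' @param out_dir Output directory.
#' @param subsets Named list of parent-id vectors; the full set is always
#'   reported under `"all"`.
#' @return The long report tibble (with a `subset` column), invisibly.
#' @export
write_gd_report <- function(gd, table, out_dir, subsets = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- diallel_parents(table)
  subsets <- c(list(all = ids), subsets)
  long <- purrr::imap(subsets, function(sub, nm) {
    rec <- assemble_hybrid_records(gd, table, subset = sub)
    dplyr::mutate(gd_correlations(rec), subset = nm, .before = 1)
  }) |> purrr::list_rbind()
  readr::write_csv(long, file.path(out_dir, "gd_correlations.csv"))
  wide <- long |>
    dplyr::mutate(cell = sprintf("%.3f%s", .data$r, .data$stars)) |>
    tidyr::pivot_wider(id_cols = "trait",
      names_from = c("subset", "response"), values_from = "cell")
  readr::write_csv(wide, file.path(out_dir, "gd_correlations_wide.csv"))
  write_manifest(out_dir, "gd_predict",
    params = list(subsets = lapply(subsets, as.list)),
    files = c("gd_correlations.csv", "gd_correlations_wide.csv"))
  invisible(long)
}
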