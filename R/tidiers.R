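#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy components of a diallel fit
#'
#' @param x A `diallel_fit` from [griffing_analysis()].
#' @param what One of `"anova"`, `"gca"`, `"sca"`, `"varcomp"`,
#'   `"heterosis"`, `"sca_percent"`.
#' @param ... Unused.
#' @return A tibble with a `trait` column plus the component's columns.
#' @export
tidy.diallel_fit <- function(x, what = c("anova", "gca", "sca", "varcomp",
                                         "heterosis", "sca_percent"), ...) {
  what <- match.arg(what)
  if (what == "heterosis") return(x$heterosis)
  purrr::imap(x$traits, function(ft, tr) {
    out <- switch(what,
      anova = ft$anova,
      gca = ft$effects$gca,
      sca = ft$effects$sca,
      varcomp = dplyr::bind_cols(ft$varcomp, ft$herit),
      sca_percent = ft$sca_pct
    )
    dplyr::mutate(out, trait = tr, .before = 1)
  }) |>
    purrr::list_rbind()
}

#' One-row-per-trait summary of a diallel fit
#'
#' @param x A `diallel_fit`.
#' @param ... Unused.
#' @return Tibble with, per trait, the grand mean, GCA/SCA/error mean
#'   squares and F p-values, both GCA/SCA ratio conventions and the
#'   heritabilities.
#' @export
glance.diallel_fit <- function(x, ...) {
  purrr::imap(x$traits, function(ft, tr) {
    an <- ft$anova
    tibble::tibble(
      trait = tr,
      mu = ft$effects$mu,
      ms_gca = an$ms[an$source == "GCA"],
      ms_sca = an$ms[an$source == "SCA"],
      ms_error = an$ms[an$source == "Error"],
      p_gca = an$p_value[an$source == "GCA"],
      p_sca = an$p_value[an$source == "SCA"],
      ratio_component = ft$varcomp$ratio_component,
      ratio_baker = ft$varcomp$ratio_baker,
      h2 = ft$herit$h2,
      H2 = ft$herit$H2
    )
  }) |>
    purrr::list_rbind()
}

#' Plot a diallel fit
#'
#' `type = "gca"` draws per-parent GCA effects faceted by trait;
#' `type = "heterosis"` draws the distribution of mid-parent heterosis per
#' trait.
#'
#' @param object A `diallel_fit`.
#' @param type `"gca"` or `"heterosis"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diallel_fit <- function(object, type = c("gca", "heterosis"), ...) {
  type <- match.arg(type)
  if (type == "gca") {
    d <- tidy(object, "gca")
    d$parent <- factor(d$parent, levels = object$parents)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$parent, y = .data$gca)) +
      ggplot2::geom_col() +
      ggplot2::facet_wrap(ggplot2::vars(.data$trait), scales = "free_y") +
      ggplot2::labs(x = "parent", y = "GCA effect") +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  } else {
    d <- object$heterosis
    ggplot2::ggplot(d, ggplot2::aes(x = .data$trait, y = .data$het)) +
      ggplot2::geom_boxplot() +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::labs(x = NULL, y = "mid-parent heterosis (%)") +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  }
}
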