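#' Tidy a bitscore-decay fit
#'
#' @param x A `"decay_fit"`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`a`, `r`, `c`).
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "r", "c"),
    estimate = c(x$a, x$r, x$c),
    unit = c("bits", "1/(subst/site)", "relative")
  )
}

#' One-row summary of a bitscore-decay fit
#'
#' @param x A `"decay_fit"`.
#' @param ... Unused.
#' @return One-row tibble: `a`, `r`, `c`, `n_points`, `status`.
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(a = x$a, r = x$r, c = x$c, n_points = x$n_points,
                 status = x$status)
}

#' Plot a bitscore-decay fit
#'
#' Observed best-hit bitscores against evolutionary distance with the
#' fitted exponential decay curve; an optional horizontal line marks the
#' detectability threshold where homologs start to escape the search.
#'
#' @param object A `"decay_fit"` with status `"ok"`.
#' @param s_thr Optional detectability threshold (bits) to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, s_thr = NULL, ...) {
  stopifnot(object$status == "ok")
  pts <- object$points
  grid <- tibble::tibble(
    distance = seq(0, max(pts$distance) * 1.2, length.out = 200))
  grid$mu <- object$a * exp(-object$r * grid$distance)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$distance,
                                         y = .data$bitscore)) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$mu), colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "evolutionary distance (substitutions/site)",
                  y = "best-hit bitscore (bits)")
  if (!is.null(s_thr)) {
    p <- p + ggplot2::geom_hline(yintercept = s_thr, linetype = "dashed")
  }
  p
}

#' Plot founder-event counts per taxonomic level
#'
#' The classic founder-event profile: events per lineage level, with the
#' unfiltered counts dashed and the HDF-filtered high-confidence counts
#' solid when both sets are present.
#'
#' @param founder_counts Tibble from [run_pipeline()]'s `founder_counts`
#'   (columns `level`, `level_name`, `n_founder_events`, `set`).
#' @return A ggplot.
#' @export
plot_founder_events <- function(founder_counts) {
  ggplot2::ggplot(founder_counts,
                  ggplot2::aes(x = .data$level,
                               y = .data$n_founder_events,
                               linetype = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_linetype_manual(
      values = c(all = "dashed", high_confidence = "solid")) +
    ggplot2::scale_x_continuous(
      breaks = founder_counts$level,
      labels = founder_counts$level_name) +
    ggplot2::labs(x = NULL, y = "gene-family founder events",
                  linetype = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot the gene-age distribution
#'
#' Number of genes assigned (or flagged) at each taxonomic level.
#'
#' @param ages Gene-age tibble from [gene_ages()].
#' @return A ggplot.
#' @export
plot_gene_ages <- function(ages) {
  ages |>
    dplyr::filter(!is.na(.data$age_level)) |>
    dplyr::count(.data$age_level, .data$status) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$age_level, y = .data$n,
                                 fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "taxonomic level (young to old)",
                  y = "genes", fill = NULL)
}
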