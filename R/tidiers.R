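# broom-style accessors and plots for ranking results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a candidate ranking
#'
#' @param x a `cf_ranking`.
#' @param ... unused.
#' @return A plain tibble with one row per candidate network: `rank`,
#'   `score`, `partition`, `signature`, `symmetric_rank`.
#' @export
tidy.cf_ranking <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a candidate ranking
#'
#' @param x a `cf_ranking`.
#' @param ... unused.
#' @return A one-row tibble: number of taxa and candidates, the best score,
#'   the best partition, the score gap to the next non-symmetric candidate,
#'   and how many candidates fall within the reported top m.
#' @export
glance.cf_ranking <- function(x, ...) {
  sym2 <- x$symmetric_rank[1]
  next_rank <- setdiff(seq_len(nrow(x)), c(1L, sym2))[1]
  tibble::tibble(
    n_taxa = length(attr(x, "taxa")),
    n_candidates = nrow(x),
    best_partition = x$partition[1],
    best_score = x$score[1],
    gap_to_next = x$score[next_rank] - x$score[1],
    m = attr(x, "m"))
}

#' Plot a candidate ranking
#'
#' Invariant score against rank (log scale), with the reported top-m
#' candidates highlighted.  A sharp drop at the left edge is the visual
#' signature of an identifiable four-node cycle.
#'
#' @param object a `cf_ranking`.
#' @param highlight partitions (text form) to mark, e.g. the true network
#'   in a simulation; the top-m candidates are always colored.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cf_ranking <- function(object, highlight = NULL, ...) {
  d <- tibble::as_tibble(object)
  m <- attr(object, "m")
  d$status <- ifelse(d$rank <= m, "top m", "other")
  if (!is.null(highlight))
    d$status[d$partition %in% highlight] <- "highlighted"
  floor_score <- max(min(d$score[d$score > 0], na.rm = TRUE), 1e-18)
  d$score_plot <- pmax(d$score, floor_score)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$score_plot,
                                  colour = .data$status)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank", y = "invariant score (L2 norm)",
                  colour = NULL,
                  title = paste0("Candidate 4-cycle ranking (",
                                 length(attr(object, "taxa")), " taxa, ",
                                 nrow(d), " candidates)")) +
    ggplot2::theme_minimal()
}
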