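# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an accuracy report
#'
#' `tidy()` returns the difference events (one row per substitution or indel
#' event); `glance()` returns the one-row summary.
#'
#' @param x a `nanobar_accuracy` from [global_identity()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.nanobar_accuracy <- function(x, ...) x$diffs

#' @rdname tidy.nanobar_accuracy
#' @export
glance.nanobar_accuracy <- function(x, ...) {
  tibble(percent_identity = x$percent_identity,
         aligned_columns = x$aligned_columns, matches = x$matches,
         substitutions = x$substitutions, insertions = x$insertions,
         deletions = x$deletions,
         homopolymer_indels = x$homopolymer_indels)
}

#' Tidy a polishing result
#'
#' `tidy()` gives one row per polishing round; `glance()` the final summary.
#'
#' @param x a `nanobar_polish` from [polish_consensus()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.nanobar_polish <- function(x, ...) {
  tibble(round = seq_len(x$report$rounds),
         changes = x$report$changes_per_round)
}

#' @rdname tidy.nanobar_polish
#' @export
glance.nanobar_polish <- function(x, ...) {
  r <- x$report
  tibble(rounds = r$rounds, final_mapped = r$final_mapped,
         mean_depth = r$mean_depth, total_depth = r$total_depth,
         consensus_length = nchar(x$contig$seq),
         support = x$contig$support)
}

#' Plot a subsampling experiment
#'
#' Consensus identity against read depth: one point per replicate, a line
#' through the per-size means.
#'
#' @param object a `nanobar_subsample` tibble from [subsample_experiment()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.nanobar_subsample <- function(object, ...) {
  means <- object %>% group_by(.data$size) %>%
    summarise(percent_identity = mean(.data$percent_identity),
              .groups = "drop")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$size,
                                       y = .data$percent_identity)) +
    ggplot2::geom_line(data = means, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10(breaks = unique(object$size)) +
    ggplot2::labs(x = "reads subsampled", y = "consensus identity (%)",
                  title = "Consensus accuracy vs read depth") +
    ggplot2::theme_minimal()
}

#' Plot the differences of an accuracy report along the truth
#'
#' @param object a `nanobar_accuracy` (ideally after [classify_errors()]).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.nanobar_accuracy <- function(object, ...) {
  d <- object$diffs
  if (nrow(d) == 0) {
    d <- tibble(column = numeric(0), type = character(0),
                homopolymer = logical(0))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$column, y = .data$type)) +
    ggplot2::geom_point(ggplot2::aes(shape = isTRUE_vec(.data$homopolymer)),
                        size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                name = "homopolymer") +
    ggplot2::labs(x = "truth position (bp)", y = NULL,
                  title = sprintf("%.1f%% identity: %d difference event(s)",
                                  object$percent_identity, nrow(object$diffs))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
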