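# tidy()/glance()/autoplot() surface for the main result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.rec_events <- function(x, ...) {
  out <- x
  attr(out, "details") <- NULL
  class(out) <- setdiff(class(out), "rec_events")
  tibble::as_tibble(out)
}

#' @export
glance.rec_events <- function(x, ...) {
  tibble::tibble(
    n_events = nrow(x),
    n_recombinant_sequences = if (nrow(x)) {
      length(unique(unlist(strsplit(x$recombinants, ",\\s*"))))
    } else 0L,
    iterations = attr(x, "iterations") %||% NA_integer_,
    incomplete = isTRUE(attr(x, "incomplete"))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Breakpoint density with permutation envelopes
#'
#' @param object a [hotspot_test()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rec_hotspots <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$center)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$local_lo,
                                      ymax = .data$local_hi),
                         fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$perm_mean),
                       colour = "grey50", linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$count)) +
    ggplot2::geom_hline(yintercept = attr(object, "global_upper"),
                        colour = "firebrick", linetype = 3) +
    ggplot2::geom_point(data = df[df$hot, ], ggplot2::aes(y = .data$count),
                        colour = "firebrick") +
    ggplot2::labs(x = "alignment position", y = "breakpoints per window",
                  title = "Breakpoint density and permutation envelopes")
}

#' Breakpoint posterior mass with HPD interval
#'
#' @param object a [breakpoint_posterior()] result.
#' @param ... unused.
#' @export
autoplot.rec_bp_posterior <- function(object, ...) {
  df <- tidy(object)
  xvar <- if (all(is.na(df$coord))) "boundary" else "coord"
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data$mass,
                                   fill = .data$in_hpd)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70"),
                               guide = "none") +
    ggplot2::labs(x = "breakpoint position", y = "posterior mass",
                  title = "Single-switch breakpoint posterior (HPD shaded)")
}

#' Phylogenetic compatibility heatmap (RF lower / SH-like upper)
#'
#' @param object a [compatibility_matrix()] result.
#' @param ... unused.
#' @export
autoplot.rec_compat <- function(object, ...) {
  nw <- nrow(object$windows)
  df <- expand.grid(i = seq_len(nw), j = seq_len(nw))
  df$value <- object$matrix[cbind(df$i, df$j)]
  df$half <- ifelse(df$i > df$j, "RF distance",
                    ifelse(df$i < df$j, "SH-like support", "diagonal"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~half) +
    ggplot2::labs(x = "window", y = "window",
                  title = "Window-tree compatibility")
}

#' @importFrom ggplot2 .data
NULL
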