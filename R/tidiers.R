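#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a clustering result
#'
#' @param x An `amp_clustering`.
#' @param ... Unused.
#' @return One row per cluster: size, target count, and whether it is
#'   the target cluster.
#' @method tidy amp_clustering
#' @export
tidy.amp_clustering <- function(x, ...) {
  asg <- x$assignment
  out <- dplyr::count(asg, cluster = .data$cluster, name = "size")
  out <- tidyr::complete(out, cluster = seq_len(x$k),
                         fill = list(size = 0L))
  if ("is_target" %in% names(asg)) {
    tc <- dplyr::summarise(dplyr::group_by(asg, .data$cluster),
                           n_target = sum(.data$is_target))
    out <- dplyr::left_join(out, tc, by = "cluster")
    out$n_target[is.na(out$n_target)] <- 0L
    out$is_target_cluster <- out$cluster == x$target_cluster
  }
  out
}

#' @rdname tidy.amp_clustering
#' @method glance amp_clustering
#' @export
glance.amp_clustering <- function(x, ...) {
  base <- tibble(k = x$k, iterations = x$iterations,
                 tot_withinss = x$tot_withinss)
  if ("is_target" %in% names(x$assignment)) {
    dplyr::bind_cols(base, evaluate_clustering(x))
  } else {
    base
  }
}

#' Tidy a GA feature-selection result
#'
#' @param x An `amp_selection`.
#' @param ... Unused.
#' @return One row per candidate feature with its descriptor fields and
#'   whether it was selected.
#' @method tidy amp_selection
#' @export
tidy.amp_selection <- function(x, ...) {
  feats <- names(x$chromosome)
  parts <- strsplit(feats, ":", fixed = TRUE)
  tibble(
    feature = feats,
    category = vapply(parts, `[`, character(1), 1),
    region = vapply(parts, `[`, character(1), 2),
    name = vapply(parts, `[`, character(1), 3),
    selected = unname(x$chromosome)
  )
}

#' @rdname tidy.amp_selection
#' @method glance amp_selection
#' @export
glance.amp_selection <- function(x, ...) {
  dplyr::bind_cols(
    tibble(
      d_n = x$d_n %||% NA_real_, d_c = x$d_c %||% NA_real_, k = x$k,
      n_candidates = x$n_candidates, n_selected = length(x$features),
      fitness = x$fitness
    ),
    x$metrics
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot the GA fitness trace
#'
#' Best-of-generation and best-ever fitness across generations.
#'
#' @param object An `amp_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot amp_selection
#' @export
autoplot.amp_selection <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, c("best", "best_ever", "mean"),
                            names_to = "series", values_to = "fitness")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "fitness (1 - F + m/N)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cluster composition
#'
#' Stacked bar of target vs non-target membership per cluster.
#'
#' @param object An `amp_clustering` whose assignment carries
#'   `is_target`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot amp_clustering
#' @export
autoplot.amp_clustering <- function(object, ...) {
  asg <- object$assignment
  if (!"is_target" %in% names(asg)) abort("assignment carries no labels")
  asg$class <- ifelse(asg$is_target, "target", "non-target")
  ggplot2::ggplot(asg, ggplot2::aes(x = factor(.data$cluster),
                                    fill = .data$class)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "cluster", y = "peptides", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-region composition of a peptide set
#'
#' Mean amino-acid composition per region across a peptide tibble,
#' faceted by family if present; useful for eyeballing planted
#' enrichments.
#'
#' @param peptides A peptide tibble.
#' @param d_n,d_c Region-length parameters.
#' @return A ggplot object.
#' @export
plot_region_composition <- function(peptides, d_n = 10, d_c = 10) {
  feats <- encode_basic(peptides, d_n, d_c)
  long <- tidyr::pivot_longer(feats, dplyr::starts_with("composition:"),
                              names_to = "feature", values_to = "fraction")
  parts <- strsplit(long$feature, ":", fixed = TRUE)
  long$region <- factor(vapply(parts, `[`, character(1), 2),
                        levels = c(REGION_NAMES, "FULL"))
  long$residue <- vapply(parts, `[`, character(1), 3)
  grp <- c("region", "residue", intersect("family", names(long)))
  agg <- dplyr::summarise(dplyr::group_by(long, dplyr::across(dplyr::all_of(grp))),
                          fraction = mean(.data$fraction), .groups = "drop")
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$residue, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 6))
  if ("family" %in% grp) {
    p + ggplot2::facet_grid(ggplot2::vars(.data$family),
                            ggplot2::vars(.data$region))
  } else {
    p + ggplot2::facet_wrap(ggplot2::vars(.data$region))
  }
}
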