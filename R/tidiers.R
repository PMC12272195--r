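#' Tidy a fitted decomposition
#'
#' @param x A `dlocus_fit`.
#' @param matrix Which component to tidy: `"sources"` returns one row per
#'   trait and edge (nonzero entries only unless `all_edges = TRUE`);
#'   `"loadings"` returns one row per subject, window, and trait.
#' @param all_edges Keep zero trait entries too?
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dlocus_fit <- function(x, matrix = c("sources", "loadings"),
                            all_edges = FALSE, ...) {
  matrix <- match.arg(matrix)
  if (matrix == "sources") {
    V <- x$V
    labels <- x$node_labels %||% as.character(seq_len(V))
    uu <- unlist(lapply(seq_len(V - 1), function(u) rep(u, V - u)))
    vv <- unlist(lapply(seq_len(V - 1), function(u) (u + 1):V))
    out <- purrr::map(seq_len(nrow(x$S)), function(l) {
      s <- x$S[l, ]
      keep <- if (all_edges) seq_along(s) else which(abs(s) > 1e-12)
      tibble::tibble(
        trait = l, node_u = labels[uu[keep]], node_v = labels[vv[keep]],
        weight = s[keep]
      )
    })
    dplyr::bind_rows(out)
  } else {
    q <- ncol(x$A)
    tibble::tibble(
      subject = rep(rep(x$subject_ids, each = x$T), q),
      window = rep(rep(seq_len(x$T), x$N), q),
      trait = rep(seq_len(q), each = x$N * x$T),
      loading = as.vector(x$A)
    )
  }
}

#' One-row summary of a fitted decomposition
#'
#' @param x A `dlocus_fit`.
#' @param ... Unused.
#' @return Tibble with the model size, tuning parameters, sparsity of the
#'   trait matrix, final objective, and convergence status.
#' @export
glance.dlocus_fit <- function(x, ...) {
  tibble::tibble(
    q = nrow(x$S),
    N = x$N, T = x$T, V = x$V,
    phi = x$control$phi, lambda = x$control$lambda, rho = x$control$rho,
    mean_rank = mean(x$ranks),
    sparsity = mean(abs(x$S) <= 1e-6),
    objective = x$objective_trace[length(x$objective_trace)],
    n_iter = x$n_iter,
    converged = x$converged
  )
}

#' Plot a latent connectivity trait as an edge heatmap
#'
#' @param fit A `dlocus_fit`.
#' @param l Trait index.
#' @return A ggplot object (node-by-node tile map of the reconstructed
#'   trait connectivity matrix).
#' @export
plot_trait <- function(fit, l) {
  M <- unvectorize(fit$S[l, ], fit$V)
  df <- tidyr::expand_grid(u = seq_len(fit$V), v = seq_len(fit$V))
  df$weight <- as.vector(t(M))
  ggplot2::ggplot(df, ggplot2::aes(.data$v, .data$u, fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::labs(
      title = sprintf("Connectivity trait %d (rank %d)", l, fit$ranks[l]),
      x = "node", y = "node", fill = "weight"
    ) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot trait-loading time series
#'
#' @param fit A `dlocus_fit`.
#' @param traits Trait indices to display (default all).
#' @param subjects Subject ids to display (default first 3).
#' @return A ggplot object of loading series, faceted by trait.
#' @export
plot_loadings <- function(fit, traits = NULL, subjects = NULL) {
  traits <- traits %||% seq_len(ncol(fit$A))
  subjects <- subjects %||% head(fit$subject_ids, 3)
  df <- tidy(fit, matrix = "loadings")
  df <- dplyr::filter(
    df, .data$trait %in% traits, .data$subject %in% subjects
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$window, .data$loading,
    color = .data$subject
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~trait, scales = "free_y", labeller = "label_both") +
    ggplot2::labs(x = "window", y = "trait loading", color = "subject") +
    ggplot2::theme_minimal()
}

#' @rdname plot_trait
#' @param object A `dlocus_fit`.
#' @param ... Passed to [plot_trait()].
#' @export
autoplot.dlocus_fit <- function(object, l = 1, ...) {
  plot_trait(object, l)
}

#' Plot dFC state occurrence percentages
#'
#' @param object A `dlocus_states`.
#' @param ... Unused.
#' @return A ggplot bar chart of state occurrence.
#' @export
autoplot.dlocus_states <- function(object, ...) {
  ggplot2::ggplot(
    object$occurrence,
    ggplot2::aes(factor(.data$state), .data$occurrence_pct)
  ) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::labs(x = "dFC state", y = "occurrence (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
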