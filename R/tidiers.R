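#' Tidy the training history of an autoencoder
#'
#' @param x A [smiles_vae()].
#' @param ... Unused.
#' @return Tibble with columns `epoch`, `train_loss`, `val_loss` (empty if
#'   the model is untrained).
#' @exportS3Method generics::tidy
tidy.smiles_vae <- function(x, ...) {
  x$history %||% tibble(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
}

#' One-row summary of an autoencoder
#'
#' @param x A [smiles_vae()].
#' @param ... Unused.
#' @return Tibble with model size, configuration corners and final losses.
#' @exportS3Method generics::glance
glance.smiles_vae <- function(x, ...) {
  h <- tidy(x)
  tibble(
    trained = x$trained,
    n_parameters = sum(rapply(x$params, length, how = "unlist")),
    max_len = x$config$max_len,
    vocab_size = x$config$vocab_size,
    latent_dim = x$config$latent_dim,
    orientation = x$config$orientation,
    epochs = nrow(h),
    final_train_loss = if (nrow(h)) h$train_loss[nrow(h)] else NA_real_,
    final_val_loss = if (nrow(h)) h$val_loss[nrow(h)] else NA_real_
  )
}

#' Tidy a similarity matrix into long format
#'
#' @param x A `sim_matrix` from [all_vs_all()].
#' @param ... Unused.
#' @return Tibble with columns `row_id`, `col_id`, `similarity`.
#' @exportS3Method generics::tidy
tidy.sim_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble(
    row_id = rep(rownames(m), times = ncol(m)),
    col_id = rep(colnames(m), each = nrow(m)),
    similarity = as.numeric(m)
  )
}

#' Heatmap of a similarity matrix
#'
#' @param object A `sim_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sim_matrix <- function(object, ...) {
  df <- tidy(object)
  df$row_id <- factor(df$row_id, levels = rev(rownames(object)))
  df$col_id <- factor(df$col_id, levels = colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$col_id, .data$row_id,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5))
}

#' Training-loss curves
#'
#' @param object A trained [smiles_vae()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.smiles_vae <- function(object, ...) {
  h <- tidy(object)
  df <- tidyr::pivot_longer(h, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  df <- df[!is.na(df$loss), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss (BCE + KL per molecule)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of a chemical-space projection
#'
#' @param emb Projection tibble from [umap_project()] (columns `id`, `u1`,
#'   `u2`).
#' @param highlight Optional character vector of ids to label.
#' @return A ggplot object.
#' @export
plot_chemical_space <- function(emb, highlight = NULL) {
  stopifnot(all(c("id", "u1", "u2") %in% names(emb)))
  p <- ggplot2::ggplot(emb, ggplot2::aes(.data$u1, .data$u2)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    sel <- emb[emb$id %in% highlight, , drop = FALSE]
    p <- p +
      ggplot2::geom_point(data = sel, colour = "red", size = 2) +
      ggplot2::geom_text(data = sel, ggplot2::aes(label = .data$id),
                         vjust = -0.8, size = 3)
  }
  p
}

#' Bar chart of a best-match rank ordering
#'
#' @param ranked Tibble from [rank_order_best_match()].
#' @param top_n Show at most this many drugs (default all).
#' @return A ggplot object.
#' @export
plot_rank_order <- function(ranked, top_n = nrow(ranked)) {
  stopifnot(all(c("drug_id", "similarity") %in% names(ranked)))
  df <- head(ranked, top_n)
  df$drug_id <- factor(df$drug_id, levels = rev(df$drug_id))
  ggplot2::ggplot(df, ggplot2::aes(.data$similarity, .data$drug_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "best-match similarity", y = NULL) +
    ggplot2::theme_minimal()
}
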