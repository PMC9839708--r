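# Two-dimensional projection of embeddings for expert review. Review only:
# no pipeline stage consumes the coordinates.

#' Project embeddings to two dimensions
#'
#' Non-linear neighbour-preserving mapping via Sammon's stress minimization
#' (initialized from classical MDS), or plain PCA. Deterministic for a fixed
#' seed: the seed only governs the tiny jitter applied to duplicate points,
#' which Sammon mapping cannot host at zero distance.
#'
#' @param embeddings `M x D` numeric matrix (M >= 4).
#' @param seed integer seed.
#' @param method `"sammon"` or `"pca"`.
#' @return a `projection_2d`: list with `coords` (`M x 2`), `segment_ids`,
#'   `method`, `seed`.
#' @export
project_2d <- function(embeddings, seed = 42L, method = c("sammon", "pca")) {
  method <- match.arg(method)
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, ncol = 1L)
  M <- nrow(embeddings)
  if (M < 4L) ieeg_error("need at least 4 points to project", "ieegsift_too_few")
  coords <- withr::with_seed(seed, {
    if (method == "pca") {
      pc <- stats::prcomp(embeddings, rank. = 2L)
      sc <- pc$x
      if (ncol(sc) < 2L) sc <- cbind(sc, 0)
      sc[, 1:2, drop = FALSE]
    } else {
      d <- stats::dist(embeddings)
      if (any(d < 1e-12)) {
        embeddings <- embeddings +
          matrix(stats::rnorm(length(embeddings), sd = 1e-8), nrow = M)
        d <- stats::dist(embeddings)
      }
      init <- stats::cmdscale(d, k = 2L)
      if (ncol(init) < 2L) init <- cbind(init, stats::rnorm(M, sd = 1e-6))
      MASS::sammon(d, y = init, trace = FALSE)$points
    }
  })
  colnames(coords) <- c("dim1", "dim2")
  structure(list(coords = coords,
                 segment_ids = rownames(embeddings) %||% as.character(seq_len(M)),
                 method = method, seed = as.integer(seed)),
            class = "projection_2d")
}

#' Render a labeled scatter plot of a projection
#'
#' One color per class with a legend in class-code order; in binary
#' (pseudo-prospective) mode the legend reads "0 - physiological" and
#' "1 - IED".
#'
#' @param projection a [project_2d()] result.
#' @param labels class codes aligned with the projected points.
#' @param path output image path (extension selects the device, e.g. `.png`).
#' @param binary_mode use the binary physiological/IED legend.
#' @param palette optional vector of colors, one per class in code order.
#' @return the ggplot object, invisibly; the image is written to `path`.
#' @export
render_scatter <- function(projection, labels, path, binary_mode = FALSE,
                           palette = NULL) {
  if (length(labels) != nrow(projection$coords)) {
    ieeg_error("labels not aligned with projected coordinates", "ieegsift_shape_mismatch")
  }
  codes <- sort(unique(labels))
  legend_names <- if (binary_mode) {
    c("0" = "0 - physiological", "1" = "1 - IED")[as.character(codes)]
  } else {
    paste0(codes, " - ", CLASS_NAMES[as.character(codes)])
  }
  df <- data.frame(dim1 = projection$coords[, 1], dim2 = projection$coords[, 2],
                   class = factor(labels, levels = codes, labels = legend_names))
  if (is.null(palette)) {
    palette <- c("#4C72B0", "#DD8452", "#C44E52", "#55A868")[seq_along(codes)]
  }
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = dim1, y = dim2, color = class)) +
    ggplot2::geom_point(size = 1, alpha = 0.8) +
    ggplot2::scale_color_manual(values = palette, name = NULL, drop = FALSE) +
    ggplot2::labs(x = "projection 1", y = "projection 2") +
    ggplot2::theme_minimal()
  ok <- tryCatch({
    ggplot2::ggsave(path, gg, width = 6, height = 5, dpi = 120)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    ieeg_error(sprintf("could not write figure to '%s': %s",
                       path, conditionMessage(ok)), "ieegsift_io")
  }
  invisible(gg)
}
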