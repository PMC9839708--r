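# Per-class kernel density classification in the embedding space. Each class
# gets a product-of-univariate-Gaussians KDE (axis-aligned, per-dimension
# Silverman bandwidths) — the operational form of a Naive Bayes density
# classifier; the predicted class maximizes prior * class density.

#' Fit per-class kernel density estimates on labeled embeddings
#'
#' Per class and per dimension the bandwidth follows Silverman's rule
#' `h = 0.9 * min(sd, IQR/1.34) * N^(-1/5)` with the population standard
#' deviation and a type-2 quantile IQR, floored at `eps_bw` (degenerate
#' dimensions get the floor).
#'
#' @param labeled_embeddings named list mapping class code (as character) to
#'   an `N_c x D` matrix of embeddings; every class needs at least one row.
#' @param eps_bw bandwidth floor.
#' @param priors class prior probabilities (default uniform), in class-code
#'   order.
#' @param shared_bandwidth use one scalar bandwidth per class (the mean of the
#'   per-dimension rule) instead of per-dimension bandwidths.
#' @return a `kde_classifier`: per-class list of `points` and `bandwidths`,
#'   plus `priors` and `classes`.
#' @export
fit_kde <- function(labeled_embeddings, eps_bw = 1e-3, priors = NULL,
                    shared_bandwidth = FALSE) {
  classes <- sort(names(labeled_embeddings))
  models <- lapply(classes, function(cl) {
    pts <- labeled_embeddings[[cl]]
    if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1L)
    if (nrow(pts) < 1L) {
      ieeg_error(sprintf("class %s has no labeled embeddings", cl),
                 "ieegsift_empty_class")
    }
    N <- nrow(pts)
    sd_pop <- col_sd_pop(pts)
    iqr <- apply(pts, 2L, function(col) {
      q <- stats::quantile(col, c(0.25, 0.75), type = 2, names = FALSE)
      q[2] - q[1]
    })
    h <- 0.9 * pmin(sd_pop, iqr / 1.34) * N^(-1 / 5)
    h <- pmax(h, eps_bw)
    if (shared_bandwidth) h <- rep(mean(h), length(h))
    list(class_code = cl, points = pts, bandwidths = h)
  })
  names(models) <- classes
  if (is.null(priors)) priors <- rep(1 / length(classes), length(classes))
  if (any(priors < 0) || abs(sum(priors) - 1) > 1e-9) {
    ieeg_error("priors must be nonnegative and sum to 1", "ieegsift_bad_params")
  }
  structure(list(models = models, priors = priors, classes = classes),
            class = "kde_classifier")
}

#' Log density of one class KDE at query points
#'
#' `log (1/N) sum_i prod_d phi((x_d - p_id)/h_d)/h_d` with the standard
#' Gaussian `phi`, computed with the log-sum-exp identity so the result is
#' finite (possibly very negative) for any finite query.
#'
#' @param kde one element of a `kde_classifier`'s `models` list.
#' @param x a length-D vector or an `M x D` matrix of queries.
#' @return numeric vector of length M.
#' @export
kde_log_density <- function(kde, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  D <- ncol(kde$points)
  if (ncol(x) != D) {
    ieeg_error(sprintf("query dimension %d does not match KDE dimension %d",
                       ncol(x), D), "ieegsift_shape_mismatch")
  }
  N <- nrow(kde$points)
  h <- kde$bandwidths
  const <- -sum(log(h)) - D / 2 * log(2 * pi)
  lp <- matrix(0, nrow(x), N)
  for (i in seq_len(N)) {
    z <- sweep(x, 2L, kde$points[i, ], "-")
    z <- sweep(z, 2L, h, "/")
    lp[, i] <- const - 0.5 * rowSums(z * z)
  }
  row_logsumexp(lp) - log(N)
}

#' Classify embeddings by highest class density
#'
#' Posterior is proportional to `prior_c * exp(log_density_c(x))`, normalized
#' with the log-sum-exp identity. Ties break toward the lowest class code.
#'
#' @param clf a `kde_classifier` from [fit_kde()].
#' @param x a length-D vector or `M x D` matrix.
#' @return list with `class` (integer vector of predicted codes) and
#'   `posterior` (`M x n_classes` matrix, columns in class-code order).
#' @export
kde_classify <- function(clf, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  lp <- vapply(clf$classes,
               function(cl) kde_log_density(clf$models[[cl]], x),
               numeric(nrow(x)))
  lp <- matrix(lp, nrow = nrow(x))
  lp <- sweep(lp, 2L, log(clf$priors), "+")
  post <- exp(lp - row_logsumexp(lp))
  pred <- as.integer(clf$classes[max.col(post, ties.method = "first")])
  colnames(post) <- clf$classes
  list(class = pred, posterior = post)
}
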