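# Independent brute-force oracles used to validate the package's
# implementations on small instances. These deliberately avoid the code paths
# they check (no log-domain tricks, no rank formulas).

# KDE density by direct summation of Gaussian products
brute_kde_density <- function(points, bandwidths, x) {
  N <- nrow(points); D <- ncol(points)
  total <- 0
  for (i in seq_len(N)) {
    prod_d <- 1
    for (d in seq_len(D)) {
      prod_d <- prod_d * dnorm((x[d] - points[i, d]) / bandwidths[d]) / bandwidths[d]
    }
    total <- total + prod_d
  }
  total / N
}

# Bayes posterior with explicit densities and explicit normalization
brute_posterior <- function(class_points, class_bw, priors, x) {
  dens <- mapply(function(pts, bw) brute_kde_density(pts, bw, x),
                 class_points, class_bw)
  unnorm <- priors * dens
  unnorm / sum(unnorm)
}

# AUROC by counting all positive/negative pairs, ties get half credit
brute_auroc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  total / (length(pos) * length(neg))
}

# AUPRC by sweeping every distinct score as a threshold (step rule)
brute_auprc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  prev_recall <- 0
  area <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    precision <- tp / sum(sel)
    recall <- tp / P
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# mean silhouette score from a data matrix and integer labels
mean_silhouette <- function(x, labels) {
  d <- as.matrix(dist(x))
  n <- nrow(x)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl]), numeric(1)))
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil)
}

# trustworthiness of a 2-D projection (rank-based neighborhood preservation)
trustworthiness <- function(high, low, k = 10) {
  n <- nrow(high)
  dh <- as.matrix(dist(high)); dl <- as.matrix(dist(low))
  diag(dh) <- Inf; diag(dl) <- Inf
  total <- 0
  for (i in seq_len(n)) {
    rank_high <- rank(dh[i, ], ties.method = "first")
    nn_low <- order(dl[i, ])[1:k]
    for (j in nn_low) {
      r <- rank_high[j]
      if (r > k) total <- total + (r - k)
    }
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * total
}

# small labeled synthetic dataset shared by several tests
make_small_dataset <- function(per_class = 15, seed = 7,
                               params = generator_params()) {
  counts <- stats::setNames(rep(per_class, 4), as.character(0:3))
  generate_dataset(counts, params, seed = seed)
}

# deterministic per-class division of one dataset into train/val/test roles
split_dataset <- function(segments, n_train, n_val, n_test) {
  labs <- vapply(segments, `[[`, integer(1), "label")
  take <- function(role_offset, n_role) {
    unlist(lapply(sort(unique(labs)), function(cl) {
      which(labs == cl)[role_offset + seq_len(n_role)]
    }))
  }
  list(train = segments[take(0, n_train)],
       val = segments[take(n_train, n_val)],
       test = segments[take(n_train + n_val, n_test)])
}
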