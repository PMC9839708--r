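# Internal helpers: labeled error conditions, seed derivation, numerics.

ieeg_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "ieegsift_error"), call = NULL))
}

assert_finite <- function(x, what, class = "ieegsift_nonfinite") {
  if (!all(is.finite(x))) {
    ieeg_error(sprintf("%s contains non-finite values", what), class)
  }
  invisible(x)
}

#' Derive a child seed from a master seed and an index
#'
#' Child seeds are a pure function of `(master, index)`, so a dataset is
#' reproducible no matter in which order its segments are generated. The
#' result always lies in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(master, index) {
  m <- as.double(master) %% 2147483647
  i <- as.double(index) %% 2147483647
  # two rounds of a multiplicative congruential mix; operands stay < 2^53
  h <- (m * 48271 + i + 1) %% 2147483647
  h <- (h * 16807 + 33179) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

# log(sum(exp(x))) rows of a matrix, guarded against -Inf rows
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) mx <- 0
  mx + log(sum(exp(x - mx)))
}

# population (divide-by-n) standard deviation per column
col_sd_pop <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt(pmax(colMeans(m * m) - mu * mu, 0))
}
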