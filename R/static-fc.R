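# Static functional connectivity: whole-record Pearson correlation between
# all pairs of network signals, vectorized into named features.

#' Pairwise Pearson correlation matrix of a session
#'
#' @param ts a [network_ts].
#' @return symmetric N x N correlation matrix with unit diagonal, dimnames
#'   set to the network labels.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "network_ts"))
  sds <- apply(ts$values, 2, stats::sd)
  if (any(sds == 0))
    stop_rsndyn("constant signal for network(s): %s",
                paste(ts$network_labels[sds == 0], collapse = ", "))
  r <- stats::cor(ts$values)
  dimnames(r) <- list(ts$network_labels, ts$network_labels)
  r
}

# canonical pair order: row-major upper triangle (1,2), (1,3), ..., (N-1,N)
pair_index <- function(N) {
  idx <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Static-connectivity feature row
#'
#' Upper-triangle (i < j, row-major) vectorization of the correlation
#' matrix, named `"sFC-<A>-<B>"` with A before B in network-label order;
#' N(N-1)/2 features (91 for the study's 14-network panel).
#'
#' @param ts a [network_ts].
#' @return a named numeric vector.
#' @export
sfc_features <- function(ts) {
  r <- correlation_matrix(ts)
  idx <- pair_index(ncol(r))
  vals <- r[idx]
  names(vals) <- sprintf("sFC-%s-%s", ts$network_labels[idx[, 1]],
                         ts$network_labels[idx[, 2]])
  vals
}
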