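# Conditional pairwise Granger causality among all networks, estimated by
# ordinary-least-squares VAR fits. The causality from source network j to
# target network i, conditional on all remaining networks, is the log ratio
# of the target's residual variance in a reduced VAR that omits the
# source's lags (from the target equation) over the full VAR.
#
# Matrix convention (throughout): G[i, j] = causal influence of source j on
# target i, i.e. F_{j -> i | rest}. Row sums are therefore total inflow
# (DegIn), column sums total outflow (DegOut).

# demeaned lagged design: Y = rows p+1..T, Z columns (lag k, series j) at
# index (k-1)*N + j
lag_design <- function(X, p, presample = p) {
  T <- nrow(X); N <- ncol(X)
  rows <- (presample + 1):T
  Y <- X[rows, , drop = FALSE]
  if (p == 0) return(list(Y = Y, Z = matrix(0, length(rows), 0)))
  Z <- matrix(0, length(rows), N * p)
  for (k in seq_len(p))
    Z[, ((k - 1) * N + 1):(k * N)] <- X[rows - k, , drop = FALSE]
  list(Y = Y, Z = Z)
}

#' Select a common VAR model order by information criterion
#'
#' Fits the full multivariate VAR by least squares for orders 0..`max_order`
#' on a common effective sample (conditioning on `max_order` presample
#' points) and returns the order minimizing AIC or BIC.
#'
#' @param ts a [network_ts].
#' @param max_order largest order considered.
#' @param criterion "BIC" (default) or "AIC".
#' @return the selected integer order.
#' @export
select_var_order <- function(ts, max_order = 10, criterion = c("BIC", "AIC")) {
  stopifnot(inherits(ts, "network_ts"))
  criterion <- match.arg(criterion)
  X <- scale(ts$values, center = TRUE, scale = FALSE)
  T <- nrow(X); N <- ncol(X)
  if (T <= N * max_order + 10)
    stop_rsndyn("max_order %d infeasible for T = %d, N = %d (need T > N*max_order + 10); lower max_order",
                max_order, T, N)
  Teff <- T - max_order
  ic <- numeric(max_order + 1)
  for (m in 0:max_order) {
    d <- lag_design(X, m, presample = max_order)
    res <- if (m == 0) d$Y else {
      qz <- qr(d$Z)
      if (qz$rank < ncol(d$Z))
        stop_rsndyn("ill-conditioned regressor matrix at order %d; lower max_order", m)
      qr.resid(qz, d$Y)
    }
    Sigma <- crossprod(res) / Teff
    ld <- determinant(Sigma, logarithm = TRUE)
    pen <- if (criterion == "AIC") 2 else log(Teff)
    ic[m + 1] <- as.numeric(ld$modulus) + pen * m * N^2 / Teff
  }
  which.min(ic) - 1L
}

#' Conditional pairwise Granger-causality matrix
#'
#' For every ordered pair (target i, source j) fits the full VAR(`order`)
#' over all N series and a reduced model omitting the source's lags from
#' the target's equation only, and returns
#' `G[i, j] = log(RSS_reduced / RSS_full)` (clamped at 0; the diagonal is
#' zero). Series are demeaned per column before fitting.
#'
#' @param ts a [network_ts].
#' @param order VAR order (>= 1); if `NULL`, selected by [select_var_order]
#'   with BIC (minimum 1).
#' @param max_order passed to order selection when `order` is `NULL`.
#' @return N x N matrix with the convention above, dimnames = labels.
#' @export
conditional_gc <- function(ts, order = NULL, max_order = 10) {
  stopifnot(inherits(ts, "network_ts"))
  X <- scale(ts$values, center = TRUE, scale = FALSE)
  T <- nrow(X); N <- ncol(X)
  if (is.null(order)) {
    max_order <- min(max_order, floor((T - 11) / N))
    order <- max(1L, select_var_order(ts, max_order = max_order))
  }
  p <- as.integer(order)
  if (p < 1) stop_rsndyn("GC needs order >= 1")
  k <- N * p
  if (T - p <= k)
    stop_rsndyn("VAR(%d) with N = %d infeasible for T = %d", p, N, T)
  if (p > 3 && (T - p) < 3 * k)
    warning(sprintf("VAR order %d leaves few degrees of freedom (%d obs for %d regressors per equation)",
                    p, T - p, k), call. = FALSE)
  d <- lag_design(X, p)
  qz <- qr(d$Z)
  if (qz$rank < ncol(d$Z)) stop_rsndyn("singular full-model fit")
  rss_full <- colSums(qr.resid(qz, d$Y)^2)
  G <- matrix(0, N, N, dimnames = list(ts$network_labels, ts$network_labels))
  for (j in seq_len(N)) {
    drop_cols <- (seq_len(p) - 1) * N + j
    Zr <- d$Z[, -drop_cols, drop = FALSE]
    qr_r <- qr(Zr)
    if (qr_r$rank < ncol(Zr)) stop_rsndyn("singular reduced-model fit (source %s)",
                                          ts$network_labels[j])
    rss_red <- colSums(qr.resid(qr_r, d$Y)^2)
    targets <- setdiff(seq_len(N), j)
    G[targets, j] <- pmax(0, log(rss_red[targets] / rss_full[targets]))
  }
  G
}

#' Net-GC and causal-degree summaries of a GC matrix
#'
#' @param G an N x N GC matrix in the package convention (entry (i, j) =
#'   influence of source j on target i), zero diagonal.
#' @return list with `deg_in` (row sums: total inflow), `deg_out` (column
#'   sums: total outflow), `net_deg = deg_out - deg_in`, and `net_gc`, the
#'   lower-triangle vector `G[i, j] - G[j, i]` (i > j), i.e. the net
#'   causality from the earlier-labelled network towards the later one,
#'   named `"netgc_<A>-><B>"`.
#' @export
gc_summaries <- function(G) {
  G <- as.matrix(G)
  if (any(diag(G) != 0)) stop_rsndyn("GC matrix must have a zero diagonal")
  labels <- rownames(G) %||% sprintf("NET%02d", seq_len(nrow(G)))
  deg_in <- rowSums(G); deg_out <- colSums(G)
  names(deg_in) <- names(deg_out) <- labels
  idx <- pair_index(nrow(G)) # (a, b), a < b
  net_gc <- G[idx[, c(2, 1), drop = FALSE]] - G[idx]
  names(net_gc) <- sprintf("netgc_%s->%s", labels[idx[, 1]], labels[idx[, 2]])
  list(deg_in = deg_in, deg_out = deg_out, net_deg = deg_out - deg_in,
       net_gc = net_gc)
}

#' Granger-causality feature row
#'
#' Named features following the reporting grammar: `"<A>-><B>"` for the
#' causality from A towards B, `"<A><-<B>"` for the reverse direction,
#' `"netgc_<A>-><B>"` for their difference (A before B in label order, all
#' N(N-1)/2 pairs), and `"GC_DegIn_<X>"`, `"GC_DegOut_<X>"`,
#' `"GC_NetDeg_<X>"` for the causal degrees: 3*N(N-1)/2 + 3*N features
#' (315 for N = 14).
#'
#' @inheritParams conditional_gc
#' @return a named numeric vector.
#' @export
gc_features <- function(ts, order = NULL, max_order = 10) {
  G <- conditional_gc(ts, order = order, max_order = max_order)
  s <- gc_summaries(G)
  labels <- ts$network_labels
  idx <- pair_index(length(labels))
  a <- labels[idx[, 1]]; b <- labels[idx[, 2]]
  fwd <- G[idx[, c(2, 1), drop = FALSE]]          # A -> B: target B, source A
  bwd <- G[idx]                     # A <- B: target A, source B
  names(fwd) <- sprintf("%s->%s", a, b)
  names(bwd) <- sprintf("%s<-%s", a, b)
  c(fwd, bwd, s$net_gc,
    stats::setNames(s$deg_in, sprintf("GC_DegIn_%s", labels)),
    stats::setNames(s$deg_out, sprintf("GC_DegOut_%s", labels)),
    stats::setNames(s$net_deg, sprintf("GC_NetDeg_%s", labels)))
}
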