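# Evolutionary-game-on-networks (EGN) emulation: fit directed pairwise
# emulation weights a_ij from the replicator form
#   xdot_i = x_i (1 - x_i) * sum_{j != i} a_ij (2 x_j - 1)
# and summarize them as in-/out-/net- emulative powers. A positive a_ij
# means network i tends to copy (emulate) network j's activity; negative,
# to do the opposite.

#' Affinely map each channel onto the open unit interval
#'
#' Replicator states must live strictly inside (0, 1): each column is
#' mapped so its minimum hits `eps` and its maximum `1 - eps`.
#'
#' @param x numeric matrix or [network_ts].
#' @param eps margin in (0, 0.5); default 0.05.
#' @return object of the same kind with transformed values.
#' @export
normalize_unit_interval <- function(x, eps = 0.05) {
  if (eps <= 0 || eps >= 0.5)
    stop_rsndyn("eps must lie strictly inside (0, 0.5): the replicator form is degenerate on the boundary")
  is_ts <- inherits(x, "network_ts")
  m <- if (is_ts) x$values else as.matrix(x)
  rng <- apply(m, 2, range)
  flat <- rng[2, ] - rng[1, ] == 0
  if (any(flat)) {
    nm <- colnames(m) %||% as.character(which(flat))
    stop_rsndyn("constant column(s): %s", paste(nm[flat], collapse = ", "))
  }
  z <- sweep(sweep(m, 2, rng[1, ]), 2, rng[2, ] - rng[1, ], "/")
  z <- eps + (1 - 2 * eps) * z
  if (is_ts) { x$values <- z; x } else z
}

#' Fit the EGN emulation matrix to a session
#'
#' Signals are normalized to (0, 1), time derivatives are estimated by
#' central differences (endpoints dropped), and each network's row of A is
#' solved by ridge-regularized least squares of its derivative on the
#' replicator regressors `x_i (1 - x_i) (2 x_j - 1)`. The ridge penalty is
#' `lambda` times the mean diagonal of the Gram matrix, so it is relative
#' to regressor scale.
#'
#' Samples where a state sits exactly on the normalization boundary (a
#' clipped or extreme sample) are excluded from that state's regression:
#' the replicator form does not hold where the trajectory is clipped. If
#' too few samples remain the exclusion is skipped.
#'
#' @param ts a [network_ts].
#' @param lambda relative ridge penalty (default 1e-3).
#' @param eps normalization margin (default 0.05).
#' @return zero-diagonal N x N matrix A; entry (i, j) is the weight with
#'   which network i emulates network j.
#' @export
fit_egn <- function(ts, lambda = 1e-3, eps = 0.05) {
  stopifnot(inherits(ts, "network_ts"))
  T <- nrow(ts$values); N <- ncol(ts$values)
  if (T < N + 10) stop_rsndyn("EGN fit needs T >= N + 10")
  z <- normalize_unit_interval(ts$values, eps)
  mid <- 2:(T - 1)
  xdot <- (z[mid + 1, , drop = FALSE] - z[mid - 1, , drop = FALSE]) /
    (2 * ts$dt)
  zc <- z[mid, , drop = FALSE]
  A <- matrix(0, N, N,
              dimnames = list(ts$network_labels, ts$network_labels))
  strat <- 2 * zc - 1
  tol <- 1e-9
  for (i in seq_len(N)) {
    zi3 <- cbind(z[mid - 1, i], z[mid, i], z[mid + 1, i])
    at_boundary <- abs(zi3 - eps) < tol | abs(zi3 - (1 - eps)) < tol
    keep <- rowSums(at_boundary) == 0
    if (sum(keep) < max(2 * N, 10)) keep <- rep(TRUE, length(mid))
    gate <- zc[keep, i] * (1 - zc[keep, i])
    R <- strat[keep, -i, drop = FALSE] * gate
    G <- crossprod(R)
    scale_ref <- mean(diag(G))
    ridge <- if (scale_ref > 0) lambda * scale_ref else lambda
    a <- tryCatch(solve(G + diag(ridge, ncol(R)), crossprod(R, xdot[keep, i])),
                  error = function(e)
                    stop_rsndyn("rank-deficient EGN regressors for network %s",
                                ts$network_labels[i]))
    A[i, -i] <- a
  }
  A
}

#' Emulative powers of an EGN matrix
#'
#' Out-EP of network i is the total weight with which it emulates the
#' others (`sum_j a_ij`, row sum); In-EP of network j is the total weight
#' with which the others emulate it (`sum_i a_ij`, column sum);
#' Net-EP = Out-EP - In-EP (sums to zero over networks by construction).
#'
#' @param A zero-diagonal emulation matrix from [fit_egn].
#' @return list of named vectors `in_ep`, `out_ep`, `net_ep`.
#' @export
emulative_powers <- function(A) {
  A <- as.matrix(A)
  if (any(diag(A) != 0)) stop_rsndyn("EGN matrix must have a zero diagonal")
  labels <- rownames(A) %||% sprintf("NET%02d", seq_len(nrow(A)))
  out_ep <- stats::setNames(rowSums(A), labels)
  in_ep <- stats::setNames(colSums(A), labels)
  list(in_ep = in_ep, out_ep = out_ep, net_ep = out_ep - in_ep)
}

#' Emulative-power feature row
#'
#' Names `"In-EP_<X>"`, `"Out-EP_<X>"`, `"Net-EP_<X>"`; 3N features (42
#' for N = 14).
#'
#' @inheritParams fit_egn
#' @return a named numeric vector.
#' @export
ep_features <- function(ts, lambda = 1e-3, eps = 0.05) {
  ep <- emulative_powers(fit_egn(ts, lambda = lambda, eps = eps))
  labels <- ts$network_labels
  c(stats::setNames(ep$in_ep, sprintf("In-EP_%s", labels)),
    stats::setNames(ep$out_ep, sprintf("Out-EP_%s", labels)),
    stats::setNames(ep$net_ep, sprintf("Net-EP_%s", labels)))
}
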