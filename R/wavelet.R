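# Morlet wavelet coherence between network pairs: continuous wavelet
# transform, scale-dependent smoothing, AR(1)-surrogate significance,
# phase-quadrant classification, and the time-of-coherence features
# (percentage of the scan during which a pair is significantly coherent
# with a given phase relation inside a given period band).

PHASE_CLASSES <- c("IN_PHASE", "ANTI_PHASE", "LEADING", "LAGGING")
PHASE_PREFIX <- c(IN_PHASE = "ip", ANTI_PHASE = "ap",
                  LEADING = "lead", LAGGING = "lag")
COHERENCE_BANDS <- list(c(4, 8), c(8, 16), c(16, 32), c(32, 64), c(64, 128))

morlet_fourier_factor <- function(omega0 = 6)
  4 * pi / (omega0 + sqrt(2 + omega0^2))

#' Continuous Morlet wavelet transform
#'
#' FFT-based transform with the standard Morlet mother wavelet
#' (omega0 = 6) over log2-spaced scales spanning the requested period
#' range (default 4-128 s, 12 sub-octaves per octave). The cone of
#' influence is the e-folding time of the wavelet at each scale; periods
#' longer than half the record are dropped with a warning.
#'
#' @param x numeric series (T >= 64).
#' @param dt sampling interval, seconds.
#' @param dj scale resolution in octaves (default 1/12).
#' @param min_period,max_period period range to span, seconds.
#' @param omega0 Morlet nondimensional frequency.
#' @return list with `wave` (complex scales x time matrix), `periods`,
#'   `scales` (seconds), `times`, `coi` (per-time maximum reliable period,
#'   seconds), `coi_mask` (TRUE = inside the cone, reliable), `dt`, `dj`.
#' @export
morlet_cwt <- function(x, dt, dj = 1 / 12, min_period = 4, max_period = 128,
                       omega0 = 6) {
  n <- length(x)
  if (n < 64) stop_rsndyn("wavelet transform needs T >= 64, got %d", n)
  if (min_period < 2 * dt)
    stop_rsndyn("min_period %gs below the resolvable limit 2*dt = %gs",
                min_period, 2 * dt)
  if (max_period > n * dt / 2) {
    warning(sprintf("record of %gs cannot resolve periods up to %gs; truncating to %gs",
                    n * dt, max_period, n * dt / 2), call. = FALSE)
    max_period <- n * dt / 2
  }
  if (max_period <= min_period)
    stop_rsndyn("record too short for the requested period range")
  ff <- morlet_fourier_factor(omega0)
  s0 <- min_period / ff
  J <- ceiling(log2(max_period / min_period) / dj)
  scales <- s0 * 2^(dj * (0:J))
  periods <- ff * scales
  base2 <- 2^ceiling(log2(n))
  xp <- c(x - mean(x), rep(0, base2 - n))
  fx <- stats::fft(xp)
  omega <- 2 * pi * c(0:(base2 / 2), -((base2 / 2 - 1):1)) / (base2 * dt)
  pos <- omega > 0
  # daughter wavelets for all scales at once (frequency domain, cols = scales)
  psi_hat <- matrix(0, base2, length(scales))
  psi_hat[pos, ] <- pi^(-1 / 4) *
    exp(-0.5 * (outer(omega[pos], scales) - omega0)^2)
  psi_hat <- sweep(psi_hat, 2, sqrt(2 * pi * scales / dt), "*")
  wave <- t(stats::mvfft(psi_hat * fx, inverse = TRUE)[seq_len(n), ,
                                                       drop = FALSE] / base2)
  dist_edge <- pmin(seq_len(n) - 1, n - seq_len(n)) * dt
  coi <- ff / sqrt(2) * dist_edge
  coi_mask <- outer(periods, coi, "<")
  times <- (seq_len(n) - 1) * dt
  list(wave = wave, periods = periods, scales = scales, times = times,
       coi = coi, coi_mask = coi_mask, dt = dt, dj = dj, omega0 = omega0)
}

# scale-dependent Gaussian smoothing along time (circular, via FFT) followed
# by a boxcar over 0.6/dj neighbouring scales; real input, real output
smooth_scalogram <- function(field, scales, dt, dj) {
  n <- ncol(field)
  k <- 2 * pi * c(0:floor(n / 2),
                  if (n > 2) -(floor((n - 1) / 2):1)) / n
  filt <- exp(-0.5 * outer(k^2, (scales / dt)^2)) # n x S
  ft <- stats::mvfft(t(field))                    # fft along time, per scale
  out <- t(Re(stats::mvfft(filt * ft, inverse = TRUE)) / n)
  w <- max(1L, round(0.6 / dj))
  if (w > 1L && nrow(out) > 1L) {
    half <- w %/% 2
    cs <- apply(rbind(0, out), 2, cumsum)
    S <- nrow(out)
    lo <- pmax(seq_len(S) - half, 1L); hi <- pmin(seq_len(S) + half, S)
    out <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1L)
  }
  out
}

smooth_power <- function(cw) {
  Re(smooth_scalogram(Mod(cw$wave)^2 / cw$scales, cw$scales, cw$dt, cw$dj))
}

# coherence + phase from two precomputed transforms (optionally with their
# smoothed auto-power, to share work across the pairs of one session)
coherence_from_cwt <- function(cwx, cwy, Px = NULL, Py = NULL) {
  stopifnot(identical(cwx$scales, cwy$scales), ncol(cwx$wave) == ncol(cwy$wave))
  Px <- Px %||% smooth_power(cwx)
  Py <- Py %||% smooth_power(cwy)
  cross <- cwx$wave * Conj(cwy$wave) / cwx$scales
  Sxy <- smooth_scalogram(Re(cross), cwx$scales, cwx$dt, cwx$dj) +
    1i * smooth_scalogram(Im(cross), cwx$scales, cwx$dt, cwx$dj)
  denom <- Px * Py
  coh <- Mod(Sxy)^2 / pmax(denom, .Machine$double.eps)
  coh <- pmin(pmax(coh, 0), 1)
  structure(list(times = cwx$times, periods = cwx$periods,
                 scales = cwx$scales, coherence = coh, phase = Arg(Sxy),
                 coi = cwx$coi, coi_mask = cwx$coi_mask, sig_mask = NULL,
                 dt = cwx$dt, dj = cwx$dj, omega0 = cwx$omega0),
            class = "coh_scalogram")
}

#' Wavelet coherence between two signals
#'
#' Squared cross-wavelet coherence
#' `|S(s^-1 Wxy)|^2 / (S(s^-1 |Wx|^2) S(s^-1 |Wy|^2))` with scale-dependent
#' Gaussian time smoothing and boxcar scale smoothing (S). The phase angle
#' is the argument of the smoothed cross-spectrum; positive phase in
#' (0, pi) means signal `x` leads signal `y`.
#'
#' @param x,y equal-length numeric series.
#' @param dt sampling interval, seconds.
#' @param ... passed to [morlet_cwt].
#' @return a `coh_scalogram`: times, periods, coherence in [0, 1], phase in
#'   (-pi, pi], cone-of-influence mask (TRUE = reliable), and a slot for
#'   the significance mask (`NULL` until [significance_mask] is run).
#' @export
coherence_pair <- function(x, y, dt, ...) {
  if (length(x) != length(y)) stop_rsndyn("series lengths differ")
  coherence_from_cwt(morlet_cwt(x, dt, ...), morlet_cwt(y, dt, ...))
}

#' @export
print.coh_scalogram <- function(x, ...) {
  cat(sprintf("<coh_scalogram> %d scales (%.1f-%.1f s) x %d times; %s\n",
              length(x$periods), min(x$periods), max(x$periods),
              length(x$times),
              if (is.null(x$sig_mask)) "no significance mask"
              else "significance mask set"))
  invisible(x)
}

# per-scale null coherence quantile from AR(1) surrogate pairs
coherence_null_threshold <- function(ar1x, ar1y, T, dt, n_surrogates, alpha,
                                     seed, dj = 1 / 12, min_period = 4,
                                     max_period = 128, omega0 = 6) {
  set.seed(seed)
  ref <- suppressWarnings(morlet_cwt(stats::rnorm(T), dt, dj, min_period,
                                     max_period, omega0))
  S <- length(ref$scales)
  keep_t <- seq(1L, T, by = max(1L, floor(T / 256)))
  pool <- vector("list", n_surrogates)
  for (b in seq_len(n_surrogates)) {
    sx <- gen_ar1(T, ar1x, 1); sy <- gen_ar1(T, ar1y, 1)
    sc <- suppressWarnings(coherence_pair(sx, sy, dt, dj = dj,
                                          min_period = min_period,
                                          max_period = max_period,
                                          omega0 = omega0))
    v <- sc$coherence[, keep_t, drop = FALSE]
    v[!sc$coi_mask[, keep_t, drop = FALSE]] <- NA
    pool[[b]] <- v
  }
  pooled <- do.call(cbind, pool)
  thr <- apply(pooled, 1, stats::quantile, probs = 1 - alpha, na.rm = TRUE)
  thr[!is.finite(thr)] <- Inf
  thr
}

#' Pointwise surrogate significance mask for a coherence scalogram
#'
#' The per-scale threshold is the (1 - alpha) quantile of coherence over
#' AR(1) surrogate pairs matched to each input's lag-1 autocorrelation,
#' pooled over times inside the cone of influence. The mask is TRUE where
#' the observed coherence exceeds the threshold of its scale.
#'
#' @param x,y the two series the scalogram was computed from.
#' @param scalogram a `coh_scalogram` from [coherence_pair].
#' @param n_surrogates number of surrogate pairs (>= 50).
#' @param alpha pointwise level.
#' @param seed integer seed (the mask is deterministic under it).
#' @return the scalogram with `sig_mask` set (logical scales x times
#'   matrix; the matrix itself carries the per-scale thresholds in
#'   `attr(,"threshold")`).
#' @export
significance_mask <- function(x, y, scalogram, n_surrogates = 300,
                              alpha = 0.05, seed = 1) {
  stopifnot(inherits(scalogram, "coh_scalogram"))
  if (n_surrogates < 50) stop_rsndyn("need n_surrogates >= 50")
  thr <- coherence_null_threshold(lag1_autocor(x), lag1_autocor(y),
                                  length(x), scalogram$dt, n_surrogates,
                                  alpha, seed, dj = scalogram$dj,
                                  min_period = min(scalogram$periods),
                                  max_period = max(scalogram$periods),
                                  omega0 = scalogram$omega0)
  mask <- sweep(scalogram$coherence, 1, thr, ">")
  attr(mask, "threshold") <- thr
  scalogram$sig_mask <- mask
  scalogram
}

#' Classify a coherence phase angle into the four phase quadrants
#'
#' The quadrants partition (-pi, pi]: in-phase on [-pi/4, pi/4), signal 1
#' leading on [pi/4, 3pi/4), anti-phase on [3pi/4, pi] and [-pi, -3pi/4),
#' signal 1 lagging on [-3pi/4, -pi/4).
#'
#' @param theta phase angle(s) in radians, in (-pi, pi].
#' @return character vector over `{"IN_PHASE", "ANTI_PHASE", "LEADING",
#'   "LAGGING"}`.
#' @export
classify_phase <- function(theta) {
  if (any(theta <= -pi - 1e-12 | theta > pi + 1e-12))
    stop_rsndyn("phase angles must lie in (-pi, pi]")
  out <- character(length(theta))
  out[theta >= -pi / 4 & theta < pi / 4] <- "IN_PHASE"
  out[theta >= pi / 4 & theta < 3 * pi / 4] <- "LEADING"
  out[theta >= 3 * pi / 4 | theta < -3 * pi / 4] <- "ANTI_PHASE"
  out[theta >= -3 * pi / 4 & theta < -pi / 4] <- "LAGGING"
  out
}

band_scale_rows <- function(periods, bands = COHERENCE_BANDS) {
  lapply(seq_along(bands), function(k) {
    lo <- bands[[k]][1]; hi <- bands[[k]][2]
    if (k == length(bands)) which(periods >= lo & periods <= hi)
    else which(periods >= lo & periods < hi)
  })
}

#' Time-of-coherence per period band and phase class
#'
#' For each band a time point counts towards a phase class if any scale in
#' the band is significant at that time inside the cone of influence; when
#' scales disagree the class of the maximal-coherence significant cell
#' wins. Values are percentages of the scan duration, so per band the four
#' phase classes sum to the total significant-time percentage.
#' `per_cell = TRUE` switches to cell counting: the percentage of
#' significant (scale, time) cells among all in-cone cells of the band.
#'
#' @param scalogram a `coh_scalogram` with `sig_mask` set.
#' @param bands list of period intervals, seconds; the defaults are
#'   `[4,8) [8,16) [16,32) [32,64) [64,128]`.
#' @param per_cell count (scale, time) cells instead of time points.
#' @return numeric matrix bands x phases (rownames "s1".."s5", colnames the
#'   phase classes), in [0, 100].
#' @export
time_of_coherence <- function(scalogram, bands = COHERENCE_BANDS,
                              per_cell = FALSE) {
  stopifnot(inherits(scalogram, "coh_scalogram"))
  if (is.null(scalogram$sig_mask))
    stop_rsndyn("run significance_mask() before time_of_coherence()")
  T <- length(scalogram$times)
  rows_per_band <- band_scale_rows(scalogram$periods, bands)
  out <- matrix(0, length(bands), length(PHASE_CLASSES),
                dimnames = list(sprintf("s%d", seq_along(bands)),
                                PHASE_CLASSES))
  M <- scalogram$sig_mask & scalogram$coi_mask
  for (k in seq_along(bands)) {
    rows <- rows_per_band[[k]]
    if (!length(rows)) next
    sub <- M[rows, , drop = FALSE]
    if (per_cell) {
      n_cone <- sum(scalogram$coi_mask[rows, , drop = FALSE])
      if (n_cone == 0) next
      cls <- classify_phase(scalogram$phase[rows, , drop = FALSE][sub])
      cnt <- table(factor(cls, levels = PHASE_CLASSES))
      out[k, ] <- 100 * as.numeric(cnt) / n_cone
    } else {
      hit <- colSums(sub) > 0
      if (!any(hit)) next
      cohsub <- scalogram$coherence[rows, , drop = FALSE]
      cohsub[!sub] <- -Inf
      best <- max.col(t(cohsub[, hit, drop = FALSE]), ties.method = "first")
      theta <- scalogram$phase[rows, , drop = FALSE][cbind(best, which(hit))]
      cnt <- table(factor(classify_phase(theta), levels = PHASE_CLASSES))
      out[k, ] <- 100 * as.numeric(cnt) / T
    }
  }
  out
}

# shared surrogate-threshold cache: the null coherence distribution depends
# only on (T, dt, lag-1 autocorrelations), so thresholds are computed once
# per rounded autocorrelation pair and reused across pairs and sessions
new_threshold_cache <- function() new.env(parent = emptyenv())

cached_threshold <- function(cache, ar1x, ar1y, T, dt, n_surrogates, alpha,
                             seed, ...) {
  r <- sort(round(c(ar1x, ar1y), 1))
  key <- sprintf("r%.1f_%.1f_T%d_dt%g_ns%d_a%g", r[1], r[2], T, dt,
                 n_surrogates, alpha)
  if (is.null(cache)) {
    return(coherence_null_threshold(r[1], r[2], T, dt, n_surrogates, alpha,
                                    derive_seed(seed, key), ...))
  }
  if (is.null(cache[[key]]))
    cache[[key]] <- coherence_null_threshold(r[1], r[2], T, dt, n_surrogates,
                                             alpha, derive_seed(seed, key),
                                             ...)
  cache[[key]]
}

#' Wavelet-coherence feature row for one session
#'
#' Time-of-coherence for every unordered network pair, each of the 5 period
#' bands, and each of the 4 phase classes: `4 * 5 * N(N-1)/2` features
#' (1820 for N = 14), named `"<prefix>_<A>-<B>_s<k>"` with prefix `ip`,
#' `ap`, `lead`, `lag` and A before B in label order ("lead" = A leads B).
#'
#' Significance thresholds are AR(1)-surrogate quantiles shared through a
#' cache keyed by the channels' rounded lag-1 autocorrelations (the null
#' coherence distribution does not depend on the signals otherwise), which
#' keeps the cost of a full session panel tractable.
#'
#' @param ts a [network_ts].
#' @param n_surrogates surrogate pairs per threshold (default 300).
#' @param alpha pointwise significance level.
#' @param seed integer seed.
#' @param cache optional environment from [new_threshold_cache] to share
#'   thresholds across sessions.
#' @param per_cell see [time_of_coherence].
#' @return a named numeric vector.
#' @export
wcoh_features <- function(ts, n_surrogates = 300, alpha = 0.05, seed = 1,
                          cache = NULL, per_cell = FALSE) {
  stopifnot(inherits(ts, "network_ts"))
  N <- ncol(ts$values)
  cwts <- lapply(seq_len(N), function(i)
    morlet_cwt(ts$values[, i], ts$dt))
  Ps <- lapply(cwts, smooth_power)
  ar1 <- apply(ts$values, 2, lag1_autocor)
  idx <- pair_index(N)
  feats <- vector("list", nrow(idx))
  for (r in seq_len(nrow(idx))) {
    a <- idx[r, 1]; b <- idx[r, 2]
    sc <- coherence_from_cwt(cwts[[a]], cwts[[b]], Ps[[a]], Ps[[b]])
    thr <- cached_threshold(cache, ar1[a], ar1[b], nrow(ts$values), ts$dt,
                            n_surrogates, alpha, seed)
    mask <- sweep(sc$coherence, 1, thr, ">")
    sc$sig_mask <- mask
    toc <- time_of_coherence(sc, per_cell = per_cell)
    v <- as.vector(t(toc)) # phase-major within band? -> band varies slowest
    nm <- as.vector(t(outer(rownames(toc), PHASE_PREFIX[colnames(toc)],
                            function(s, p) sprintf("%s_%s-%s_%s", p,
                                                   ts$network_labels[a],
                                                   ts$network_labels[b], s))))
    feats[[r]] <- stats::setNames(v, nm)
  }
  unlist(feats)
}
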