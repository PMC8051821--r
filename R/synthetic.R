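# Seeded synthetic cohorts with planted ground truth: lagged VAR coupling
# (for Granger causality), band-limited phase-locked oscillation (for
# wavelet coherence), replicator-dynamics emulation (for the EGN fit), and
# group-level effects in designated network pairs.

#' Default network panel used by the benchmark generator
#' @export
BENCHMARK_LABELS <- c("LVISU", "MVISU", "DMN", "AUDI", "VAN", "LSM", "DAN",
                      "OVIS", "SSM", "CB", "FPL", "FPR", "SN", "CING")

# AR(1) series with innovation sd `sd`, stationary start
gen_ar1 <- function(T, coef = 0.3, sd = 1) {
  innov <- stats::rnorm(T, sd = sd)
  if (coef == 0) return(innov)
  x <- numeric(T)
  x[1] <- stats::rnorm(1, sd = sd / sqrt(1 - coef^2))
  for (t in 2:T) x[t] <- coef * x[t - 1] + innov[t]
  x
}

#' Simulation configuration for synthetic cohorts
#'
#' Collects cohort shape, noise structure, and planted effect descriptors.
#' Effects are lists with a `kind` in `{"var_coupling", "phase_lock",
#' "egn_pair", "mean_shift"}` plus kind-specific parameters; each effect
#' applies to the ACA group only unless `both_groups = TRUE`.
#'
#' @param n_group_a number of ACA subjects.
#' @param n_group_b number of control subjects.
#' @param N number of networks.
#' @param T time points per session.
#' @param dt sampling interval, seconds.
#' @param noise_sd innovation standard deviation of the background noise.
#' @param ar1_coef background AR(1) coefficient in [0, 1); default 0.3,
#'   emulating BOLD autocorrelation at a 2 s sampling interval.
#' @param labels network labels (defaults to the benchmark panel, truncated
#'   or extended to N).
#' @param effects list of planted effect descriptors.
#' @param seed master seed; per-subject/session streams are derived from it
#'   with [derive_seed].
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_group_a = 10, n_group_b = 14, N = 14, T = 208,
                       dt = 2, noise_sd = 1, ar1_coef = 0.3,
                       labels = NULL, effects = list(), seed = 1) {
  if (T < 64) stop_rsndyn("sim_config needs T >= 64")
  if (ar1_coef < 0 || ar1_coef >= 1) stop_rsndyn("ar1_coef must lie in [0, 1)")
  if (is.null(labels)) {
    labels <- if (N <= length(BENCHMARK_LABELS)) BENCHMARK_LABELS[seq_len(N)]
              else c(BENCHMARK_LABELS,
                     sprintf("NET%02d", seq_len(N - length(BENCHMARK_LABELS))))
  }
  if (length(labels) != N) stop_rsndyn("need %d labels, got %d", N, length(labels))
  for (e in effects) {
    nets <- unlist(e[c("from", "to", "pair")], use.names = FALSE)
    bad <- setdiff(as.character(nets), labels)
    if (length(bad))
      stop_rsndyn("planted effect references unknown network(s): %s",
                  paste(bad, collapse = ", "))
  }
  structure(list(n_group_a = n_group_a, n_group_b = n_group_b, N = N, T = T,
                 dt = dt, noise_sd = noise_sd, ar1_coef = ar1_coef,
                 labels = labels, effects = effects, seed = seed),
            class = "sim_config")
}

companion_spectral_radius <- function(Phi) {
  # Phi: N x N x p array of VAR coefficient matrices
  N <- dim(Phi)[1]; p <- dim(Phi)[3]
  comp <- matrix(0, N * p, N * p)
  for (k in seq_len(p)) comp[1:N, ((k - 1) * N + 1):(k * N)] <- Phi[, , k]
  if (p > 1) comp[(N + 1):(N * p), 1:(N * (p - 1))] <- diag(N * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

simulate_var <- function(Phi, T, noise_sd) {
  N <- dim(Phi)[1]; p <- dim(Phi)[3]
  burn <- 50L
  x <- matrix(stats::rnorm((T + burn) * N, sd = noise_sd), T + burn, N)
  for (t in (p + 1):(T + burn))
    for (k in seq_len(p))
      x[t, ] <- x[t, ] + x[t - k, ] %*% t(Phi[, , k])
  x[(burn + 1):(burn + T), , drop = FALSE]
}

#' Generate a cohort of VAR(p) realizations with group-dependent coupling
#'
#' Each session is an independent realization of a stable VAR(p) process
#' with Gaussian innovations. The baseline coefficient array is diagonal
#' AR(1) (`ar1_coef`); planted `var_coupling` effects add lagged
#' cross-coupling entries, by default only in the ACA group. Ground truth
#' for the Granger-causality stage.
#'
#' @param config a [sim_config]; `var_coupling` effects have fields `from`,
#'   `to` (labels), `lag`, `coef`, optional `both_groups`.
#' @return a [cohort] with two sessions (RS1, RS2) per subject.
#' @export
gen_var_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- max(c(1L, vapply(config$effects,
                        function(e) if (e$kind == "var_coupling") as.integer(e$lag) else 1L,
                        1L)))
  make_phi <- function(is_aca) {
    Phi <- array(0, dim = c(config$N, config$N, p))
    Phi[, , 1] <- diag(config$ar1_coef, config$N)
    for (e in config$effects) {
      if (e$kind != "var_coupling") next
      if (!is_aca && !isTRUE(e$both_groups)) next
      i <- match(e$to, config$labels); j <- match(e$from, config$labels)
      Phi[i, j, e$lag] <- Phi[i, j, e$lag] + e$coef
    }
    Phi
  }
  for (is_aca in c(TRUE, FALSE)) {
    r <- companion_spectral_radius(make_phi(is_aca))
    if (r >= 1)
      stop_rsndyn("unstable VAR coefficients (spectral radius %.3f >= 1)", r)
  }
  sessions <- list()
  for (g in c("ACA", "CONTROL")) {
    n <- if (g == "ACA") config$n_group_a else config$n_group_b
    Phi <- make_phi(g == "ACA")
    for (s in seq_len(n)) {
      sid <- sprintf("%s%02d", if (g == "ACA") "aca" else "ctl", s)
      for (ses in SESSION_LEVELS) {
        set.seed(derive_seed(config$seed, paste0(sid, ":", ses)))
        vals <- simulate_var(Phi, config$T, config$noise_sd)
        sessions[[length(sessions) + 1L]] <-
          network_ts(vals, config$dt, config$labels, sid, ses, g)
      }
    }
  }
  cohort(sessions)
}

#' Generate a two-channel phase-locked pair
#'
#' A common sinusoid of the given period is present in both channels over a
#' contiguous centred window covering `coherent_fraction` of the record
#' (channel 2 shifted by `phase_offset_rad`); independent AR(1) noise is
#' added throughout. Ground truth for the wavelet-coherence stage: the
#' planted fraction maps directly onto time-of-coherence.
#'
#' @param period_s oscillation period, seconds; must satisfy
#'   `2*dt < period_s < T*dt/2`.
#' @param coherent_fraction fraction of the record carrying the oscillation,
#'   in [0, 1].
#' @param phase_offset_rad phase of channel 2 relative to channel 1 (0 =
#'   in-phase, pi = anti-phase, positive = channel 1 leads).
#' @param T,dt record length (samples) and sampling interval (seconds).
#' @param noise_sd AR(1) innovation sd of the additive noise.
#' @param seed integer seed.
#' @param amplitude sinusoid amplitude.
#' @param ar1_coef AR(1) coefficient of the noise.
#' @param labels the two channel labels.
#' @return a [network_ts] with N = 2.
#' @export
gen_phase_locked_pair <- function(period_s, coherent_fraction,
                                  phase_offset_rad = 0, T = 208, dt = 2,
                                  noise_sd = 1, seed = 1, amplitude = 1,
                                  ar1_coef = 0.3,
                                  labels = c("NET1", "NET2")) {
  if (!(period_s > 2 * dt && period_s < T * dt / 2))
    stop_rsndyn("period %gs not resolvable: need 2*dt < period < T*dt/2", period_s)
  if (coherent_fraction < 0 || coherent_fraction > 1)
    stop_rsndyn("coherent_fraction must lie in [0, 1]")
  set.seed(seed)
  tt <- (seq_len(T) - 1) * dt
  win_len <- round(coherent_fraction * T)
  lo <- floor((T - win_len) / 2) + 1L
  window <- if (win_len > 0) seq(lo, lo + win_len - 1L) else integer(0)
  carrier <- rep(0, T)
  carrier[window] <- 1
  x1 <- amplitude * carrier * sin(2 * pi * tt / period_s) +
    gen_ar1(T, ar1_coef, noise_sd)
  x2 <- amplitude * carrier * sin(2 * pi * tt / period_s - phase_offset_rad) +
    gen_ar1(T, ar1_coef, noise_sd)
  ts <- network_ts(cbind(x1, x2), dt, labels)
  attr(ts, "coherent_window") <- window
  ts
}

#' Forward-simulate the network replicator (EGN) model
#'
#' Integrates the adopted replicator form
#' \deqn{\dot x_i = x_i (1 - x_i) \sum_{j \ne i} a_{ij} (2 x_j - 1)}
#' by explicit Euler stepping with step `dt`, adding a Gaussian perturbation
#' of sd `noise_sd` per step and clipping states to `[eps, 1 - eps]`
#' (replicator dynamics are degenerate on the boundary). Ground truth for
#' [fit_egn].
#'
#' @param A zero-diagonal N x N emulation-weight matrix (entry (i, j) =
#'   weight with which network i emulates network j).
#' @param x0 start state, strictly inside (0, 1)^N.
#' @param T,dt record length and step, seconds.
#' @param noise_sd per-step Gaussian perturbation sd.
#' @param seed integer seed.
#' @param eps clipping margin in (0, 0.5).
#' @param labels network labels.
#' @param ... passed to [network_ts] (subject_id, session_id, group).
#' @return a [network_ts] whose values live in `[eps, 1 - eps]`.
#' @export
gen_egn_ts <- function(A, x0, T = 208, dt = 2, noise_sd = 0.02, seed = 1,
                       eps = 0.05, labels = NULL, ...) {
  A <- as.matrix(A)
  N <- nrow(A)
  if (any(diag(A) != 0)) stop_rsndyn("EGN matrix must have a zero diagonal")
  if (length(x0) != N) stop_rsndyn("x0 must have length %d", N)
  if (any(x0 <= 0 | x0 >= 1))
    stop_rsndyn("x0 must be strictly inside (0,1): replicator dynamics are degenerate on the boundary")
  if (eps <= 0 || eps >= 0.5) stop_rsndyn("eps must lie in (0, 0.5)")
  labels <- labels %||% sprintf("NET%02d", seq_len(N))
  set.seed(seed)
  x <- simulate_replicator(A, x0, T, dt, noise_sd, eps)
  network_ts(x, dt, labels, ...)
}

# per-subject effect-size jitter, stable across sessions
subject_jitter <- function(master, sid) {
  set.seed(derive_seed(master, paste0("subject:", sid)))
  1 + 0.15 * stats::rnorm(1)
}

#' Generate the two-session benchmark cohort with planted group effects
#'
#' Emulates the study conditions: 10 ACA and 14 control subjects, two
#' resting-state sessions each, 14 labelled networks, T = 208 samples at
#' dt = 2 s. The ACA group differs from controls by three planted effects:
#' \itemize{
#'   \item \strong{Emulation sign (EGN):} the DMN/DAN pair follows
#'     two-node replicator dynamics with the DAN-emulates-DMN weight
#'     +0.4 in controls and -0.4 in ACA (patients' DMN is non-emulated).
#'   \item \strong{Phase locking (coherence):} a 20 s in-phase oscillation
#'     shared by DMN and MVISU covers 20\% of the record in controls and
#'     60\% in ACA.
#'   \item \strong{Lagged coupling (GC):} AUDI receives 0.5 x lag-1 DMN
#'     input in ACA only.
#' }
#' Per-subject effect magnitudes are jittered by ~15\% (stable across the
#' two sessions); everything else is AR(1) noise. With `effects = FALSE`
#' the groups are exchangeable (null calibration).
#'
#' @param seed master seed.
#' @param n_aca,n_control group sizes.
#' @param T,dt record length and sampling interval.
#' @param effects logical: plant the group effects (default TRUE).
#' @return list with elements `rs1` and `rs2`, each a [cohort].
#' @export
gen_benchmark_dataset <- function(seed = 1, n_aca = 10, n_control = 14,
                                  T = 208, dt = 2, effects = TRUE) {
  labels <- BENCHMARK_LABELS
  N <- length(labels)
  iDMN <- match("DMN", labels); iDAN <- match("DAN", labels)
  iMV <- match("MVISU", labels); iAU <- match("AUDI", labels)
  sessions <- list()
  subjects <- c(sprintf("aca%02d", seq_len(n_aca)),
                sprintf("ctl%02d", seq_len(n_control)))
  groups <- rep(c("ACA", "CONTROL"), c(n_aca, n_control))
  for (k in seq_along(subjects)) {
    sid <- subjects[k]; grp <- groups[k]
    jit <- if (effects) subject_jitter(seed, sid) else 1
    for (ses in SESSION_LEVELS) {
      set.seed(derive_seed(seed, paste0(sid, ":", ses)))
      x <- sapply(seq_len(N), function(i) gen_ar1(T, 0.3, 1))
      if (effects) {
        # EGN effect: DMN/DAN replicator pair, emulation sign by group
        a <- jit * if (grp == "ACA") -0.4 else 0.4
        A2 <- matrix(c(0, 0.2, a, 0), 2, 2, byrow = TRUE) # rows DMN, DAN
        z0 <- stats::runif(2, 0.35, 0.65)
        z <- simulate_replicator(A2, z0, T, dt, noise_sd = 0.05, eps = 0.05)
        x[, iDMN] <- as.vector(scale(z[, 1])) + 0.4 * gen_ar1(T, 0.3, 1)
        x[, iDAN] <- as.vector(scale(z[, 2])) + 0.4 * gen_ar1(T, 0.3, 1)
        # coherence effect: shared 20 s in-phase oscillation, DMN & MVISU
        frac <- if (grp == "ACA") 0.6 else 0.2
        wl <- round(frac * T); lo <- floor((T - wl) / 2) + 1L
        carrier <- rep(0, T); carrier[seq(lo, lo + wl - 1L)] <- 1
        osc <- carrier * sin(2 * pi * (seq_len(T) - 1) * dt / 20)
        x[, iDMN] <- x[, iDMN] + jit * osc
        x[, iMV] <- x[, iMV] + jit * osc
        # GC effect: lag-1 DMN -> AUDI coupling in ACA
        if (grp == "ACA")
          x[2:T, iAU] <- x[2:T, iAU] + jit * 0.5 * x[1:(T - 1), iDMN]
      }
      sessions[[length(sessions) + 1L]] <-
        network_ts(x, dt, labels, sid, ses, grp)
    }
  }
  full <- cohort(sessions)
  list(rs1 = cohort_session(full, "RS1"), rs2 = cohort_session(full, "RS2"))
}

# bare replicator integrator shared by gen_egn_ts and the benchmark
simulate_replicator <- function(A, x0, T, dt, noise_sd, eps) {
  N <- nrow(A)
  x <- matrix(0, T, N)
  x[1, ] <- pmin(pmax(x0, eps), 1 - eps)
  for (t in 2:T) {
    xi <- x[t - 1, ]
    drift <- xi * (1 - xi) * as.vector(A %*% (2 * xi - 1))
    x[t, ] <- pmin(pmax(xi + dt * drift + stats::rnorm(N, sd = noise_sd),
                        eps), 1 - eps)
  }
  x
}

#' Generate a null feature table (no group effect)
#'
#' Standard-normal features for a two-group cohort, used for permutation
#' type-I calibration. `shift` adds a group mean difference (in SD units)
#' to the first `n_shifted` features of the ACA group.
#'
#' @param n_a,n_b group sizes.
#' @param n_features number of features.
#' @param shift mean shift (SD units) planted in the ACA group.
#' @param n_shifted how many leading features carry the shift.
#' @param seed integer seed.
#' @return a feature table.
#' @export
gen_feature_table <- function(n_a = 10, n_b = 14, n_features = 100,
                              shift = 0, n_shifted = 0, seed = 1) {
  set.seed(seed)
  n <- n_a + n_b
  X <- matrix(stats::rnorm(n * n_features), n, n_features)
  if (n_shifted > 0) X[seq_len(n_a), seq_len(n_shifted)] <-
      X[seq_len(n_a), seq_len(n_shifted)] + shift
  colnames(X) <- sprintf("f%04d", seq_len(n_features))
  keys <- data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                     session_id = "RS1",
                     group = rep(c("ACA", "CONTROL"), c(n_a, n_b)),
                     stringsAsFactors = FALSE)
  feature_table(keys, X)
}
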