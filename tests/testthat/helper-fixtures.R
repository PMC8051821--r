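# Small fixtures shared across test files; everything is generated in code.

toy_ts <- function(T = 64, N = 3, seed = 1, dt = 2, labels = NULL, ...) {
  set.seed(seed)
  network_ts(matrix(rnorm(T * N), T, N), dt = dt,
             network_labels = labels %||% sprintf("NET%02d", seq_len(N)), ...)
}

`%||%` <- rsndyn:::`%||%`

toy_cohort <- function(n_a = 2, n_b = 2, T = 64, N = 3, seed = 1) {
  sessions <- list()
  k <- 0
  for (g in c("ACA", "CONTROL")) {
    for (s in seq_len(if (g == "ACA") n_a else n_b)) {
      sid <- sprintf("%s%02d", tolower(substr(g, 1, 3)), s)
      for (ses in c("RS1", "RS2")) {
        k <- k + 1
        sessions[[k]] <- toy_ts(T, N, seed = seed + k, subject_id = sid,
                                session_id = ses, group = g)
      }
    }
  }
  cohort(sessions)
}

# two-session feature tables with a planted group shift, same subjects
toy_session_tables <- function(n_a = 10, n_b = 14, n_features = 5,
                               shift = 2.5, n_shifted = 3, seed = 1) {
  t1 <- gen_feature_table(n_a, n_b, n_features, shift, n_shifted, seed)
  t2 <- gen_feature_table(n_a, n_b, n_features, shift, n_shifted, seed + 1)
  t2$session_id <- "RS2"
  list(rs1 = t1, rs2 = t2)
}
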