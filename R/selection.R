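# Permutation-test screening of features (two-sided absolute group-mean
# difference, add-one p-values) and the extra reduction rules applied to
# the coherence features.

# vectorized permutation test over the columns of X
perm_test_matrix <- function(X, is_a, n_perm, seed, chunk = 500L) {
  X <- as.matrix(X)
  n <- nrow(X); na <- sum(is_a); nb <- n - na
  if (na < 2 || nb < 2) stop_rsndyn("both groups need >= 2 observations")
  obs <- abs(colMeans(X[is_a, , drop = FALSE]) -
             colMeans(X[!is_a, , drop = FALSE]))
  set.seed(seed)
  exceed <- numeric(ncol(X))
  done <- 0L
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    P <- matrix(0, n, b)
    for (k in seq_len(b)) P[sample.int(n, na), k] <- 1
    ma <- crossprod(P, X) / na
    mb <- crossprod(1 - P, X) / nb
    stat <- abs(ma - mb)
    exceed <- exceed + colSums(stat >= rep(obs, each = b) - 1e-12)
    done <- done + b
  }
  p <- (1 + exceed) / (n_perm + 1)
  data.frame(feature = colnames(X) %||% sprintf("f%d", seq_len(ncol(X))),
             statistic = as.numeric(obs), p = as.numeric(p),
             n_permutations = n_perm, stringsAsFactors = FALSE)
}

#' Permutation p-value for a two-group mean difference
#'
#' Statistic: absolute difference of group means (two-sided by
#' construction). P-value uses the add-one formula
#' `(1 + #{permuted >= observed}) / (n_perm + 1)`, valid at finite
#' permutation counts; its minimum attainable value is `1/(n_perm + 1)`.
#'
#' @param values_a,values_b numeric observations of the two groups (each
#'   >= 2).
#' @param n_perm number of label permutations (default 5000).
#' @param seed integer seed.
#' @return list with `statistic` and `p`.
#' @export
permutation_pvalue <- function(values_a, values_b, n_perm = 5000, seed = 1) {
  X <- matrix(c(values_a, values_b), ncol = 1,
              dimnames = list(NULL, "feature"))
  is_a <- rep(c(TRUE, FALSE), c(length(values_a), length(values_b)))
  r <- perm_test_matrix(X, is_a, n_perm, seed)
  list(statistic = r$statistic, p = r$p)
}

#' Permutation screening of every feature in a table
#'
#' Tests each feature for an ACA-vs-control group difference and keeps
#' those with uncorrected `p < alpha`. An optional Benjamini-Hochberg
#' correction is available but off by default, mirroring the uncorrected
#' screening this pipeline reproduces.
#'
#' @param table a feature table (both groups present).
#' @param alpha significance level (default 0.05).
#' @param n_perm permutations (default 5000).
#' @param seed integer seed; the same label permutations are shared by all
#'   features.
#' @param adjust "none" (default) or "BH".
#' @return list with `selected` (character vector of surviving feature
#'   names) and `results` (data.frame: feature, statistic, p, selected).
#' @export
select_features <- function(table, alpha = 0.05, n_perm = 5000, seed = 1,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  table <- validate_feature_table(table)
  is_a <- table$group == "ACA"
  if (all(is_a) || !any(is_a))
    stop_rsndyn("both groups must be present for feature selection")
  feats <- feature_names(table)
  if (!length(feats))
    return(list(selected = character(0),
                results = data.frame(feature = character(0),
                                     statistic = numeric(0), p = numeric(0),
                                     selected = logical(0))))
  res <- perm_test_matrix(feature_matrix(table), is_a, n_perm, seed)
  p_use <- if (adjust == "BH") stats::p.adjust(res$p, "BH") else res$p
  res$selected <- p_use < alpha
  list(selected = res$feature[res$selected], results = res)
}

parse_wcoh_name <- function(x) {
  m <- regmatches(x, regexec("^(ip|ap|lead|lag)_([^_]+)_s([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop_rsndyn("not a coherence feature name: %s", x[bad][1])
  data.frame(feature = x,
             phase = vapply(m, `[`, "", 2L),
             pair = vapply(m, `[`, "", 3L),
             band = vapply(m, `[`, "", 4L), stringsAsFactors = FALSE)
}

#' Overfitting-guard reduction of significant coherence features
#'
#' Applies, in order: (i) drop features that also differ significantly
#' between the two sessions within controls (session-consistency guard);
#' then keep a feature only if (ii) its network pair is significant in at
#' least two period bands or two phase classes (robustness), or (iii) its
#' p-value shows stronger evidence (`p < strict_alpha`, default 0.01). A
#' feature survives iff it passes (i) and ((ii) or (iii)).
#'
#' @param results_rs1,results_rs2 `results` data.frames from
#'   [select_features] run on the coherence features of each session.
#' @param control_consistency `results` data.frame from comparing controls'
#'   RS1 vs RS2 coherence features (same namespace).
#' @param alpha base significance level used for all three rules' "is
#'   significant" checks (default 0.05).
#' @param strict_alpha level for rule (iii) (default 0.01).
#' @return list with `selected` (surviving names) and `trace` (per-feature
#'   rule outcomes).
#' @export
reduce_wcoh <- function(results_rs1, results_rs2, control_consistency,
                        alpha = 0.05, strict_alpha = 0.01) {
  f <- sort(results_rs1$feature)
  if (!identical(f, sort(results_rs2$feature)) ||
      !identical(f, sort(control_consistency$feature)))
    stop_rsndyn("the three result sets must share one feature namespace")
  p1 <- results_rs1$p[match(f, results_rs1$feature)]
  p2 <- results_rs2$p[match(f, results_rs2$feature)]
  pc <- control_consistency$p[match(f, control_consistency$feature)]
  sig <- p1 < alpha | p2 < alpha
  info <- parse_wcoh_name(f)
  rule1 <- !(pc < alpha)
  rule2 <- logical(length(f))
  for (pr in unique(info$pair[sig])) {
    in_pair <- sig & info$pair == pr
    robust <- length(unique(info$band[in_pair])) >= 2 ||
      length(unique(info$phase[in_pair])) >= 2
    rule2[in_pair] <- robust
  }
  rule3 <- pmin(p1, p2) < strict_alpha
  keep <- sig & rule1 & (rule2 | rule3)
  trace <- data.frame(feature = f, p_rs1 = p1, p_rs2 = p2, p_controls = pc,
                      significant = sig, passes_consistency = rule1,
                      passes_robustness = rule2, passes_strict = rule3,
                      selected = keep, stringsAsFactors = FALSE)
  list(selected = f[keep], trace = trace)
}
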