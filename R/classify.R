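# Small-sample classification benchmark: SVM / LDA / KNN / decision tree,
# evaluated under five validation schemes (two cross-session transfers and
# three leave-one-observation-out designs), with accuracy, sensitivity and
# specificity anchored to the ACA class as positive.

VALIDATION_SCHEMES <- c("TRAIN_RS1_VAL_RS2", "TRAIN_RS2_VAL_RS1",
                        "LOOCV_RS1", "LOOCV_RS2", "LOOCV_CONCAT")
ALGORITHMS <- c("SVM", "LDA", "KNN", "DT")

#' Classifier specification
#'
#' Defaults reflect out-of-the-box set-ups: SVM with Gaussian (radial)
#' kernel and median-heuristic bandwidth; LDA with pooled covariance and a
#' shrinkage fallback when features outnumber observations; KNN with
#' k = 1; CART decision tree with Gini impurity and no pruning. Features
#' are z-scored by training statistics for SVM/LDA/KNN; trees consume raw
#' values.
#'
#' @param algorithm "SVM", "LDA", "KNN" or "DT".
#' @param k neighbours for KNN.
#' @param cost SVM soft-margin cost.
#' @param gamma SVM kernel width; `NULL` = median heuristic.
#' @param shrinkage LDA covariance shrinkage used when the pooled
#'   covariance is not invertible.
#' @param standardize z-score features by training statistics; default TRUE
#'   except for DT.
#' @param seed integer seed (KNN distance ties are broken reproducibly).
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("SVM", "LDA", "KNN", "DT"), k = 1,
                            cost = 1, gamma = NULL, shrinkage = 0.1,
                            standardize = NULL, seed = 1) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "KNN" && (k < 1 || k != round(k)))
    stop_rsndyn("KNN needs a positive integer k")
  structure(list(algorithm = algorithm, k = as.integer(k), cost = cost,
                 gamma = gamma, shrinkage = shrinkage,
                 standardize = standardize %||% (algorithm != "DT"),
                 seed = seed),
            class = "classifier_spec")
}

default_specs <- function(seed = 1)
  stats::setNames(lapply(ALGORITHMS, classifier_spec, seed = seed), ALGORITHMS)

median_heuristic_gamma <- function(X) {
  n <- nrow(X)
  take <- if (n > 100) sample.int(n, 100) else seq_len(n)
  d2 <- as.vector(stats::dist(X[take, , drop = FALSE])^2)
  d2 <- d2[d2 > 0]
  if (!length(d2)) return(1 / max(1, ncol(X)))
  1 / (2 * stats::median(d2))
}

ridge_lda_fit <- function(X, y, shrinkage) {
  lev <- levels(y)
  m1 <- colMeans(X[y == lev[1], , drop = FALSE])
  m2 <- colMeans(X[y == lev[2], , drop = FALSE])
  n1 <- sum(y == lev[1]); n2 <- sum(y == lev[2])
  c1 <- sweep(X[y == lev[1], , drop = FALSE], 2, m1)
  c2 <- sweep(X[y == lev[2], , drop = FALSE], 2, m2)
  S <- (crossprod(c1) + crossprod(c2)) / (n1 + n2 - 2)
  tr <- mean(diag(S))
  if (tr <= 0) tr <- 1
  Sreg <- (1 - shrinkage) * S + shrinkage * tr * diag(ncol(X))
  w <- solve(Sreg, m1 - m2)
  list(w = w, threshold = sum(w * (m1 + m2)) / 2 - log(n1 / n2),
       levels = lev)
}

#' Train one classifier on a feature table
#'
#' @param table a feature table (or numeric matrix, in which case `y` must
#'   be given).
#' @param spec a [classifier_spec].
#' @param features feature subset to use (default: all feature columns).
#' @param y group labels when `table` is a bare matrix.
#' @return an `rsndyn_model`.
#' @export
train_classifier <- function(table, spec, features = NULL, y = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (is.data.frame(table)) {
    X <- feature_matrix(table, features)
    y <- table$group
  } else {
    X <- as.matrix(table)
    if (!is.null(features)) X <- X[, features, drop = FALSE]
  }
  if (any(!is.finite(X))) stop_rsndyn("training features contain missing values")
  y <- factor(y, levels = GROUP_LEVELS)
  if (nlevels(droplevels(y)) < 2)
    stop_rsndyn("training set contains a single class")
  if (min(table(y)) < 2) stop_rsndyn("each class needs >= 2 observations")
  feats <- colnames(X) %||% sprintf("f%d", seq_len(ncol(X)))
  center <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (spec$standardize) {
    center <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
  }
  Xs <- sweep(sweep(X, 2, center), 2, scl, "/")
  set.seed(spec$seed)
  fit <- switch(spec$algorithm,
    SVM = e1071::svm(x = Xs, y = y, kernel = "radial",
                     gamma = spec$gamma %||% median_heuristic_gamma(Xs),
                     cost = spec$cost, scale = FALSE),
    LDA = {
      if (ncol(Xs) < nrow(Xs) - 2) {
        tryCatch(suppressWarnings(MASS::lda(Xs, grouping = y)),
                 error = function(e) ridge_lda_fit(Xs, y, spec$shrinkage))
      } else ridge_lda_fit(Xs, y, spec$shrinkage)
    },
    KNN = list(train = Xs, cl = y),
    DT = {
      df <- as.data.frame(Xs)
      names(df) <- sprintf("V%d", seq_len(ncol(Xs)))
      df$.group <- y
      rpart::rpart(.group ~ ., data = df, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(minsplit = 10,
                                                  minbucket = 1, cp = 0,
                                                  xval = 0))
    })
  structure(list(spec = spec, algorithm = spec$algorithm, features = feats,
                 fit = fit, center = center, scale = scl),
            class = "rsndyn_model")
}

#' Predict group labels with a trained model
#'
#' @param object an `rsndyn_model`.
#' @param newdata feature table or numeric matrix carrying at least the
#'   training features (matched by name).
#' @param ... unused.
#' @return factor of predicted labels over `{ACA, CONTROL}`.
#' @export
predict.rsndyn_model <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) feature_matrix(newdata, object$features)
       else {
    X0 <- as.matrix(newdata)
    missing <- setdiff(object$features, colnames(X0) %||% character(0))
    if (length(missing) && ncol(X0) != length(object$features))
      stop_rsndyn("newdata lacks training features: %s",
                  paste(utils::head(missing, 5), collapse = ", "))
    if (!length(missing)) X0[, object$features, drop = FALSE] else X0
  }
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  set.seed(object$spec$seed)
  pred <- switch(object$algorithm,
    SVM = stats::predict(object$fit, Xs),
    LDA = if (inherits(object$fit, "lda"))
            stats::predict(object$fit, Xs)$class
          else {
            sc <- Xs %*% object$fit$w - object$fit$threshold
            factor(ifelse(sc > 0, object$fit$levels[1], object$fit$levels[2]),
                   levels = object$fit$levels)
          },
    KNN = class::knn(object$fit$train, Xs, object$fit$cl, k = object$spec$k),
    DT = {
      df <- as.data.frame(Xs)
      names(df) <- sprintf("V%d", seq_len(ncol(Xs)))
      stats::predict(object$fit, df, type = "class")
    })
  factor(as.character(pred), levels = GROUP_LEVELS)
}

#' Accuracy, sensitivity and specificity of predictions
#'
#' The positive class is ACA: sensitivity is the fraction of ACA subjects
#' correctly identified, specificity the fraction of controls correctly
#' identified.
#'
#' @param pred,truth factors/characters over `{ACA, CONTROL}`.
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
evaluate_predictions <- function(pred, truth) {
  pred <- as.character(pred); truth <- as.character(truth)
  if (length(pred) != length(truth)) stop_rsndyn("length mismatch")
  c(accuracy = mean(pred == truth),
    sensitivity = mean(pred[truth == "ACA"] == "ACA"),
    specificity = mean(pred[truth == "CONTROL"] == "CONTROL"))
}

#' Evaluate a trained model on a labelled feature table
#'
#' @param model an `rsndyn_model`.
#' @param table a feature table containing the training features.
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
evaluate_model <- function(model, table) {
  evaluate_predictions(predict(model, table), table$group)
}

loocv_metrics <- function(table, spec, features) {
  n <- nrow(table)
  preds <- character(n)
  for (i in seq_len(n)) {
    m <- train_classifier(table[-i, , drop = FALSE], spec, features)
    preds[i] <- as.character(predict(m, table[i, , drop = FALSE]))
  }
  evaluate_predictions(preds, table$group)
}

#' Leave-one-subject-out cross-validation
#'
#' Stricter variant of the concatenated-session LOOCV: all observations of
#' one subject are held out together, so a subject's other session can
#' never inform its own prediction. Not part of the five-scheme benchmark,
#' which leaves out one observation.
#'
#' @param table feature table (typically both sessions stacked).
#' @param spec a [classifier_spec].
#' @param features feature subset (default: all).
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
loso_metrics <- function(table, spec, features = NULL) {
  table <- validate_feature_table(table)
  features <- features %||% feature_names(table)
  preds <- character(nrow(table))
  for (s in unique(table$subject_id)) {
    hold <- table$subject_id == s
    m <- train_classifier(table[!hold, , drop = FALSE], spec, features)
    preds[hold] <- as.character(predict(m, table[hold, , drop = FALSE]))
  }
  evaluate_predictions(preds, table$group)
}

#' Run the five-scheme validation suite
#'
#' Computes, for every classifier spec, the two cross-session transfers
#' (train on one session, validate on the other) and three
#' leave-one-observation-out cross-validations (within RS1, within RS2,
#' and on the two sessions concatenated: 2n folds), then appends the
#' per-algorithm average over the five schemes.
#'
#' @param rs1,rs2 feature tables of the two sessions: same feature
#'   namespace and same subjects.
#' @param specs list of [classifier_spec]s (default: all four algorithms).
#' @param features feature subset (default: all shared features).
#' @return a `validation_report` data.frame with columns `algorithm`,
#'   `scheme` (the five schemes plus "Average"), `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
validation_suite <- function(rs1, rs2, specs = default_specs(),
                             features = NULL) {
  rs1 <- validate_feature_table(rs1); rs2 <- validate_feature_table(rs2)
  if (!setequal(rs1$subject_id, rs2$subject_id))
    stop_rsndyn("RS1 and RS2 tables must cover the same subjects")
  features <- features %||% feature_names(rs1)
  if (!all(features %in% feature_names(rs2)))
    stop_rsndyn("feature namespace mismatch between sessions")
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, function(s) s$algorithm, character(1))
  concat <- rbind(rs1[c(KEY_COLUMNS, features)], rs2[c(KEY_COLUMNS, features)])
  rows <- list()
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    m12 <- evaluate_model(train_classifier(rs1, spec, features), rs2)
    m21 <- evaluate_model(train_classifier(rs2, spec, features), rs1)
    l1 <- loocv_metrics(rs1, spec, features)
    l2 <- loocv_metrics(rs2, spec, features)
    lc <- loocv_metrics(concat, spec, features)
    block <- rbind(m12, m21, l1, l2, lc)
    block <- rbind(block, colMeans(block))
    rows[[nm]] <- data.frame(algorithm = nm,
                             scheme = c(VALIDATION_SCHEMES, "Average"),
                             block, row.names = NULL,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("validation_report", "data.frame")
  out
}

#' Pick the best set-up per algorithm by average accuracy
#'
#' @param reports a single `validation_report` or a named list of them (one
#'   per feature set-up). Ties on average accuracy break by higher average
#'   sensitivity, then lexicographic set-up name.
#' @return data.frame with one row per algorithm: `algorithm`, `setup`,
#'   `avg_accuracy`, `avg_sensitivity`, `avg_specificity`.
#' @export
select_best <- function(reports) {
  if (inherits(reports, "validation_report")) reports <- list(setup = reports)
  if (!length(reports)) stop_rsndyn("no reports given")
  if (is.null(names(reports)))
    names(reports) <- sprintf("setup%d", seq_along(reports))
  avg <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    a <- r[r$scheme == "Average", ]
    data.frame(setup = nm, algorithm = a$algorithm,
               avg_accuracy = a$accuracy, avg_sensitivity = a$sensitivity,
               avg_specificity = a$specificity, stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, lapply(split(avg, avg$algorithm), function(d) {
    d <- d[order(-d$avg_accuracy, -d$avg_sensitivity, d$setup), ]
    d[1, ]
  }))
  rownames(out) <- NULL
  out[c("algorithm", "setup", "avg_accuracy", "avg_sensitivity",
        "avg_specificity")]
}

#' Which features mention one of the given networks
#'
#' Feature names are tokenized on non-alphanumeric separators, so
#' `"In-EP_DMN"`, `"sFC-DMN-VAN"`, `"netgc_DMN->AUDI"` and
#' `"ip_MVISU-DMN_s2"` all involve "DMN".
#'
#' @param features character feature names.
#' @param networks character network labels.
#' @return logical vector.
#' @export
feature_involves <- function(features, networks) {
  vapply(strsplit(features, "[^A-Za-z0-9]+"),
         function(tok) any(tok %in% networks), TRUE)
}

#' Greedy feature-subset refinement
#'
#' Builds candidate subsets from two admission criteria — (i) predictors
#' actually used as split variables by a fitted decision tree, (ii)
#' features whose name involves a configured network set (default DMN,
#' DAN, SN) — then runs bounded greedy passes that remove or add one
#' admissible feature at a time, keeping a change iff it improves the best
#' average accuracy over the validation suite.
#'
#' @param rs1,rs2 feature tables of the two sessions.
#' @param selected character vector of candidate (screened) features.
#' @param networks network labels for criterion (ii).
#' @param specs classifier specs used for the objective (default all four).
#' @param max_iter greedy passes; 0 returns the criteria-filtered subsets
#'   unchanged.
#' @return list with `subsets` (named list of feature vectors: `dt_used`,
#'   `network`, and their refined versions), `reports` (validation reports
#'   of the refined subsets), and `trace` (audit log of every attempted
#'   change).
#' @export
refine_subsets <- function(rs1, rs2, selected, networks = c("DMN", "DAN", "SN"),
                           specs = default_specs(), max_iter = 2) {
  if (!length(selected)) stop_rsndyn("selected feature set is empty")
  concat <- rbind(rs1[c(KEY_COLUMNS, selected)], rs2[c(KEY_COLUMNS, selected)])
  dt_model <- train_classifier(concat, classifier_spec("DT"), selected)
  frame <- dt_model$fit$frame
  used_internal <- unique(as.character(frame$var[frame$var != "<leaf>"]))
  dt_used <- selected[match(used_internal, sprintf("V%d", seq_along(selected)))]
  dt_used <- dt_used[!is.na(dt_used)]
  net_feats <- selected[feature_involves(selected, networks)]
  admissible <- union(dt_used, net_feats)
  objective <- function(feats) {
    if (!length(feats)) return(-Inf)
    rep <- validation_suite(rs1, rs2, specs, feats)
    max(rep$accuracy[rep$scheme == "Average"])
  }
  trace <- list()
  refine_one <- function(feats, label) {
    if (!length(feats)) return(feats)
    best <- objective(feats)
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      improved <- FALSE
      for (f in feats) {
        cand <- setdiff(feats, f)
        if (!length(cand)) next
        val <- objective(cand)
        trace[[length(trace) + 1L]] <<-
          data.frame(subset = label, iteration = iter, action = "remove",
                     feature = f, before = best, after = val,
                     kept = val > best, stringsAsFactors = FALSE)
        if (val > best) { feats <- cand; best <- val; improved <- TRUE }
      }
      for (f in setdiff(admissible, feats)) {
        cand <- c(feats, f)
        val <- objective(cand)
        trace[[length(trace) + 1L]] <<-
          data.frame(subset = label, iteration = iter, action = "add",
                     feature = f, before = best, after = val,
                     kept = val > best, stringsAsFactors = FALSE)
        if (val > best) { feats <- cand; best <- val; improved <- TRUE }
      }
      if (!improved) break
    }
    feats
  }
  subsets <- list(dt_used = dt_used, network = net_feats)
  refined <- list()
  for (nm in names(subsets))
    refined[[paste0(nm, "_refined")]] <- refine_one(subsets[[nm]], nm)
  subsets <- c(subsets, refined)
  reports <- lapply(refined[vapply(refined, length, 1L) > 0],
                    function(f) validation_suite(rs1, rs2, specs, f))
  list(subsets = subsets, reports = reports,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(subset = character(0), iteration = integer(0),
                    action = character(0), feature = character(0),
                    before = numeric(0), after = numeric(0),
                    kept = logical(0)))
}
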