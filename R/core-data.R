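# Domain containers: per-session network time series, cohorts of sessions,
# and the observation x feature table exchanged between pipeline stages.

SESSION_LEVELS <- c("RS1", "RS2")
GROUP_LEVELS <- c("ACA", "CONTROL")
KEY_COLUMNS <- c("subject_id", "session_id", "group")

#' Construct a per-session network time-series object
#'
#' The substrate of every metric in the package: one resting-state session's
#' activity signals for N large-scale networks sampled at a fixed interval.
#' Rows are time points, columns are networks.
#'
#' @param values numeric T x N matrix of network signals (arbitrary units).
#' @param dt sampling interval in seconds.
#' @param network_labels character vector of N unique network names
#'   (e.g. "DMN", "DAN", "SN").
#' @param subject_id subject identifier.
#' @param session_id "RS1" or "RS2".
#' @param group "ACA" or "CONTROL".
#' @return an object of class `network_ts`.
#' @export
network_ts <- function(values, dt, network_labels,
                       subject_id = "sub01", session_id = "RS1",
                       group = "CONTROL") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 32L)
    stop_rsndyn("network_ts needs T >= 32 time points, got %d", nrow(values))
  if (ncol(values) < 2L)
    stop_rsndyn("network_ts needs N >= 2 networks, got %d", ncol(values))
  if (!all(is.finite(values)))
    stop_rsndyn("network_ts values must all be finite")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop_rsndyn("dt must be a single positive number of seconds")
  network_labels <- as.character(network_labels)
  if (length(network_labels) != ncol(values))
    stop_rsndyn("got %d network labels for %d columns",
                length(network_labels), ncol(values))
  if (anyDuplicated(network_labels))
    stop_rsndyn("network labels must be unique")
  session_id <- match.arg(session_id, SESSION_LEVELS)
  group <- match.arg(group, GROUP_LEVELS)
  colnames(values) <- network_labels
  structure(list(values = values, dt = dt, network_labels = network_labels,
                 subject_id = as.character(subject_id),
                 session_id = session_id, group = group),
            class = "network_ts")
}

#' @export
print.network_ts <- function(x, ...) {
  cat(sprintf("<network_ts> %s/%s (%s): %d x %d, dt = %gs\n",
              x$subject_id, x$session_id, x$group,
              nrow(x$values), ncol(x$values), x$dt))
  invisible(x)
}

#' @export
dim.network_ts <- function(x) dim(x$values)

#' Assemble sessions into a cohort
#'
#' All sessions must share the network panel (same N, labels, order) and
#' sampling interval; (subject, session) keys must be unique and a subject's
#' group label must agree across its sessions.
#'
#' @param sessions list of [network_ts] objects.
#' @return an object of class `cohort`.
#' @export
cohort <- function(sessions) {
  if (!length(sessions)) stop_rsndyn("cohort needs at least one session")
  if (!all(vapply(sessions, inherits, TRUE, "network_ts")))
    stop_rsndyn("all cohort members must be network_ts objects")
  ref <- sessions[[1L]]
  for (s in sessions) {
    if (!identical(s$network_labels, ref$network_labels))
      stop_rsndyn("network labels differ between sessions (%s/%s)",
                  s$subject_id, s$session_id)
    if (!isTRUE(all.equal(s$dt, ref$dt)))
      stop_rsndyn("sampling interval differs between sessions")
  }
  keys <- vapply(sessions, function(s) paste(s$subject_id, s$session_id),
                 character(1))
  if (anyDuplicated(keys))
    stop_rsndyn("duplicate (subject, session) pair: %s",
                keys[duplicated(keys)][1L])
  grp <- vapply(sessions, function(s) s$group, character(1))
  sub <- vapply(sessions, function(s) s$subject_id, character(1))
  if (any(tapply(grp, sub, function(g) length(unique(g))) > 1L))
    stop_rsndyn("a subject's group label must agree across its sessions")
  structure(list(sessions = sessions,
                 network_labels = ref$network_labels, dt = ref$dt),
            class = "cohort")
}

#' @export
length.cohort <- function(x) length(x$sessions)

#' @export
print.cohort <- function(x, ...) {
  grp <- vapply(x$sessions, function(s) s$group, character(1))
  cat(sprintf("<cohort> %d sessions, %d networks, dt = %gs (%d ACA / %d CONTROL)\n",
              length(x$sessions), length(x$network_labels), x$dt,
              sum(grp == "ACA"), sum(grp == "CONTROL")))
  invisible(x)
}

#' Keep only the sessions of one resting-state run
#'
#' @param x a [cohort].
#' @param session_id "RS1" or "RS2".
#' @return a [cohort] restricted to that session.
#' @export
cohort_session <- function(x, session_id) {
  session_id <- match.arg(session_id, SESSION_LEVELS)
  keep <- vapply(x$sessions, function(s) s$session_id == session_id, TRUE)
  if (!any(keep)) stop_rsndyn("cohort has no %s sessions", session_id)
  cohort(x$sessions[keep])
}

#' Load a cohort from a CSV manifest
#'
#' The manifest has columns `subject_id`, `session_id`, `group`, `file`;
#' each referenced file is a delimited text matrix, one row per time point,
#' one column per network, with a header row of network labels. Relative
#' file paths are resolved against the manifest's directory. Column order
#' is preserved: column k of every loaded matrix maps to label k.
#'
#' @param manifest_path path to the manifest CSV.
#' @param dt sampling interval in seconds (the text format carries no
#'   timing metadata); default 2.
#' @return a [cohort].
#' @export
load_cohort <- function(manifest_path, dt = 2) {
  if (!file.exists(manifest_path))
    stop_rsndyn("manifest not found: %s", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "session_id", "group", "file")
  if (!all(need %in% names(man)))
    stop_rsndyn("manifest must have columns: %s", paste(need, collapse = ", "))
  base <- dirname(normalizePath(manifest_path))
  sessions <- vector("list", nrow(man))
  labels_ref <- NULL
  for (i in seq_len(nrow(man))) {
    f <- man$file[i]
    if (!grepl("^(/|[A-Za-z]:)", f)) f <- file.path(base, f)
    if (!file.exists(f)) stop_rsndyn("time-series file not found: %s", f)
    m <- utils::read.csv(f, check.names = FALSE)
    vals <- as.matrix(m)
    if (!is.numeric(vals))
      stop_rsndyn("non-numeric values in %s", f)
    labels <- colnames(m)
    if (is.null(labels_ref)) labels_ref <- labels
    if (!identical(labels, labels_ref))
      stop_rsndyn("network labels in %s do not match the cohort's (%s/%s)",
                  f, man$subject_id[i], man$session_id[i])
    sessions[[i]] <- network_ts(vals, dt = dt, network_labels = labels,
                                subject_id = man$subject_id[i],
                                session_id = man$session_id[i],
                                group = man$group[i])
  }
  cohort(sessions)
}

#' Write a cohort to a directory as manifest + per-session CSV matrices
#'
#' @param x a [cohort].
#' @param dir output directory (created if absent).
#' @param manifest manifest file name within `dir`.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(x, dir, manifest = "manifest.csv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(x$sessions, function(s) {
    fn <- sprintf("%s_%s.csv", s$subject_id, s$session_id)
    df <- as.data.frame(s$values)
    utils::write.csv(df, file.path(dir, fn), row.names = FALSE)
    data.frame(subject_id = s$subject_id, session_id = s$session_id,
               group = s$group, file = fn, stringsAsFactors = FALSE)
  })
  man_path <- file.path(dir, manifest)
  utils::write.csv(do.call(rbind, rows), man_path, row.names = FALSE)
  invisible(man_path)
}

#' Build a feature table from observation keys and named feature rows
#'
#' A feature table is a plain data.frame whose first three columns are the
#' observation keys (`subject_id`, `session_id`, `group`) followed by one
#' numeric column per named feature. It is the interchange object between
#' metric extraction, permutation screening, and classification.
#'
#' @param keys data.frame with the three key columns.
#' @param values numeric matrix, rows matching `keys`, with unique column
#'   names (zero columns allowed).
#' @return a feature-table data.frame.
#' @export
feature_table <- function(keys, values) {
  keys <- as.data.frame(keys, stringsAsFactors = FALSE)
  if (!all(KEY_COLUMNS %in% names(keys)))
    stop_rsndyn("keys must have columns: %s", paste(KEY_COLUMNS, collapse = ", "))
  values <- as.matrix(values)
  if (length(values) && !is.numeric(values))
    stop_rsndyn("feature values must be numeric")
  if (nrow(keys) != nrow(values) && ncol(values) > 0)
    stop_rsndyn("keys (%d rows) and values (%d rows) disagree",
                nrow(keys), nrow(values))
  validate_feature_table(cbind(keys[KEY_COLUMNS],
                               as.data.frame(values, optional = TRUE)))
}

validate_feature_table <- function(df) {
  feat <- setdiff(names(df), KEY_COLUMNS)
  if (anyDuplicated(names(df)))
    stop_rsndyn("duplicate feature names: %s",
                paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  if (length(feat)) {
    vals <- as.matrix(df[feat])
    if (!is.numeric(vals)) stop_rsndyn("feature columns must be numeric")
    if (any(!is.finite(vals)))
      stop_rsndyn("feature table contains missing/non-finite values")
  }
  if (!all(df$group %in% GROUP_LEVELS))
    stop_rsndyn("group labels must be in {%s}", paste(GROUP_LEVELS, collapse = ", "))
  df
}

#' Feature columns of a feature table
#' @param df a feature table.
#' @return character vector of feature names (keys excluded).
#' @export
feature_names <- function(df) setdiff(names(df), KEY_COLUMNS)

#' Numeric feature matrix of a feature table
#' @param df a feature table.
#' @param features optional subset of feature names.
#' @return numeric matrix (observations x features).
#' @export
feature_matrix <- function(df, features = NULL) {
  features <- features %||% feature_names(df)
  missing <- setdiff(features, names(df))
  if (length(missing))
    stop_rsndyn("features absent from table: %s",
                paste(utils::head(missing, 5), collapse = ", "))
  as.matrix(df[features])
}

#' Write / read a feature table as CSV
#'
#' Lossless up to float text precision (15 significant digits). Writing
#' refuses tables with missing values; reading refuses duplicate feature
#' names.
#'
#' @param df a feature table.
#' @param path CSV path.
#' @return `read_feature_table` returns the table; `write_feature_table`
#'   returns `path` invisibly.
#' @export
write_feature_table <- function(df, path) {
  df <- validate_feature_table(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_rsndyn("feature table not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_feature_table(df)
}
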