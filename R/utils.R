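#' @keywords internal
"_PACKAGE"

#' Derive a reproducible child seed from a master seed and a string key
#'
#' One master seed spawns independent per-subject/per-session/per-stage
#' random streams through a stable polynomial string hash, so adding
#' subjects or stages never perturbs the streams of existing ones.
#'
#' @param master integer master seed.
#' @param key character key naming the stream (e.g. "sub03:RS2").
#' @return an integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key),
            length(key) == 1L)
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483647
  as.integer((h + abs(round(master))) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rsndyn <- function(...) stop(sprintf(...), call. = FALSE)

# lag-1 sample autocorrelation, used for AR(1) surrogate matching
lag1_autocor <- function(x) {
  x <- x - mean(x)
  denom <- sum(x^2)
  if (denom == 0) return(0)
  sum(x[-1] * x[-length(x)]) / denom
}
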