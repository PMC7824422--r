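`%||%` <- function(a, b) if (is.null(a)) b else a

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Convert a power ratio to decibels
#' @param ratio positive power ratio
#' @return 10*log10(ratio)
#' @keywords internal
db <- function(ratio) 10 * log10(ratio)

#' Derive a stage seed from a root seed
#'
#' All randomness in the package flows from one root seed; stage- and
#' subject-level seeds are derived deterministically with a small string
#' hash so that stages can be re-run independently yet reproducibly.
#' Result is always in [1, 2^31 - 2] (a valid R integer seed).
#'
#' @param root integer root seed
#' @param label character tag, e.g. "synth/subject3"
#' @return integer seed
#' @export
derive_seed <- function(root, label) {
  stopifnot(is.numeric(root), length(root) == 1, is.character(label))
  # FNV-1a over the label bytes, folded with the root via LCG-style mixing;
  # all arithmetic kept in doubles below 2^53 so it is exact.
  h <- 2166136261
  for (b in utf8ToInt(label)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2147483629
  }
  s <- (h + (root %% 2147483629) * 48271) %% 2147483629
  as.integer(s + 1)
}

stop_data <- function(...) {
  stop(structure(class = c("erspconn_data_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("erspconn_config_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}
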