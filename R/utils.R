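# Internal helpers shared across modules.

# Deterministic 31-bit seed derived from a set of identity strings (FNV-1a on
# the UTF-8 bytes, folded into [0, 2^31)). Used to give every simulated trace
# and every shared sample factor its own reproducible RNG stream.
hash_seed <- function(...) {
  s <- paste(vapply(list(...), as.character, character(1)), collapse = "\x1f")
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261 %% 2^31
  for (b in bytes) {
    h <- bitwXor(as.integer(h), b)
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

stop_iphplc <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

assert_finite_scalar <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_iphplc("`%s` must be a single finite number", what)
  }
  invisible(x)
}

# Arms recognised throughout the package. The negative-control channel carries
# the reserved antibody label so nonspecific binding is a channel, not a
# special case, in manifests and peak tables.
ARM_LEVELS <- c("treated", "control", "negative_control")

#' Reserved antibody label for the negative-control channel
#'
#' Traces of the irrelevant-antibody channel (used to estimate nonspecific
#' binding, whose peak area is subtracted from every raw peak area) carry this
#' label in their `antibody` field.
#'
#' @export
NEG_CONTROL <- "NEG_CONTROL"

#' Default housekeeping antibody set
#'
#' The three expression-stable internal-control proteins used as the
#' proportional baseline: alpha-tubulin, beta-actin and GAPDH.
#'
#' @return Character vector of length 3.
#' @export
housekeeping_antibodies <- function() {
  c("\u03b1-tubulin", "\u03b2-actin", "GAPDH")
}
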