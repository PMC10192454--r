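# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
squash_ws <- function(x) {
  gsub("\\s+", " ", trimws(x))
}

# Stable 31-bit string hash (polynomial rolling hash). Used to key independent
# RNG substreams by (seed, label, replicate) so that adding crosses to a design
# never perturbs the draws of existing ones.
str_hash <- function(x) {
  stopifnot(length(x) == 1L)
  h <- 0
  for (c in utf8ToInt(enc2utf8(as.character(x)))) {
    h <- (h * 31 + c) %% 2147483629
  }
  as.integer(h)
}

# Derive a substream seed from a base seed and any number of key parts.
# Kept below 2^31 - 1.
substream_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "\r")
  str_hash(key)
}

stop_kola <- function(..., class) {
  stop(structure(
    class = c(class, "kola_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}
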