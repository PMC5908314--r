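#' Round half away from zero
#'
#' Base R's `round()` rounds half to even ("banker's rounding"), which would
#' print 2.25 -> 2.2. Clinical tables conventionally round half up, so 11/44
#' prints as 25.0%. Used for every reported percentage.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.25, 1)   # 0.3, where round(0.25, 1) gives 0.2
#' round_half_up(100 * 11 / 44, 1)
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic sub-stream seed derived from a master seed and a stage label.
# Keeps every generator stage independently reproducible under one master seed.
sub_seed <- function(master_seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1000003L
  as.integer((as.numeric(master_seed) * 7919 + h) %% 2147483647)
}

# Small stable content hash (polynomial rolling hash over the serialized text
# rendering) used to fingerprint training inputs in serialized models and run
# manifests. Not cryptographic; only change detection is needed.
content_hash <- function(x) {
  txt <- paste(utils::capture.output(utils::str(x, digits.d = 15, vec.len = 1e6)),
               collapse = "\n")
  h1 <- 0; h2 <- 0
  for (ch in utf8ToInt(txt)) {
    h1 <- (h1 * 31 + ch) %% 2147483647
    h2 <- (h2 * 131 + ch) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
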