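# deterministic 31-bit polynomial hash of a string (stable across sessions)
stable_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# per-subject RNG substream seed: mixing the cohort seed with a stable hash
# of the subject id, so adding a subject does not perturb the others
substream_seed <- function(seed, id) {
  as.integer((as.numeric(seed) * 48271 + stable_hash(id)) %% 2147483647)
}

with_substream <- function(seed, id, code) {
  withr::with_seed(substream_seed(seed, id), code)
}

file_md5 <- function(paths) {
  unname(tools::md5sum(paths))
}

# hash of a config object via its canonical JSON serialization
config_hash <- function(cfg) {
  json <- jsonlite::toJSON(unclass_deep(cfg), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(json, tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else if (is.matrix(x)) {
    apply(x, 1, as.numeric, simplify = FALSE)
  } else {
    x
  }
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Percentage with half-up rounding to one decimal
#'
#' The rounding convention used in clinical characteristics tables:
#' `100 * count / total` rounded half-up to one decimal place.
#'
#' @param count Numerator count.
#' @param total Denominator count.
#' @param digits Decimal places (default 1).
#' @return Numeric percentage.
#' @export
#' @examples
#' pct(29, 62)  # 46.8
pct <- function(count, total, digits = 1) {
  round_half_up(100 * count / total, digits)
}
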