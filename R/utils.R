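#' @keywords internal
logit <- function(p) log(p / (1 - p))

#' @keywords internal
invlogit <- function(x) stats::plogis(x)

# ICD-9-CM codes are matched on dot-stripped strings ("410.71" -> "41071").
strip_dots <- function(x) gsub(".", "", x, fixed = TRUE)

# Collapse principal + secondary diagnoses of one admission into a single
# ";"-delimited string so that prefix matching can be done with one regex
# pass per prefix over all admissions.
dx_string <- function(principal, secondary) {
  s <- ifelse(is.na(secondary) | secondary == "", "", paste0(";", secondary))
  paste0(strip_dots(principal), strip_dots(s))
}

# TRUE where any ";"-delimited code in `codes` starts with any of `prefixes`.
match_any_prefix <- function(codes, prefixes) {
  hit <- rep(FALSE, length(codes))
  for (p in strip_dots(prefixes)) {
    pat <- paste0("(^|;)", p)
    hit <- hit | grepl(pat, codes)
  }
  hit
}

# TRUE where any ";"-delimited code has its leading 3 digits inside
# [lo, hi] (ICD-9-CM chapter ranges such as cancer 140-208).
match_code_range <- function(codes, lo, hi) {
  vapply(strsplit(codes, ";", fixed = TRUE), function(cs) {
    cs <- cs[nzchar(cs)]
    if (!length(cs)) return(FALSE)
    top <- suppressWarnings(as.integer(substr(cs, 1L, 3L)))
    any(!is.na(top) & top >= lo & top <= hi)
  }, logical(1))
}

# Derive a bounded substream seed from a master seed; keeps each record
# type's draws stable when unrelated stages are added or reordered.
substream_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
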