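#' Round half away from zero
#'
#' Percentages in the summary tables are rounded half-up (the convention of
#' the published tables), not with R's round-half-even rule.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A connection that transparently handles .gz paths.
open_text <- function(file) {
  if (is.character(file) && grepl("\\.gz$", file)) gzfile(file) else file
}

# Stable, platform-independent key used for grouping rows.
group_key <- function(...) {
  do.call(paste, c(list(...), sep = "\r"))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
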