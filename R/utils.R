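# shared small helpers

BASES <- c("A", "C", "G", "T")

#' Round half away from zero at a fixed number of decimals
#'
#' Printed metric tables conventionally round half-up (0.8265 -> 0.827),
#' unlike R's banker's rounding. Used when reconciling integer confusion
#' matrices with printed three-decimal metrics.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("pileupcnn_data_error", "error")))
}

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("pileupcnn_usage_error", "error")))
}

is_scalar_int <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x == as.integer(x)
}

# content hash of an R object (used to tie model checkpoints to the
# encoding configuration they were trained with)
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}
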