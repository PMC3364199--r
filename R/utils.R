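#' Inverse logit
#'
#' Numerically stable inverse of the logit link.
#'
#' @param x numeric vector on the log-odds scale.
#' @return probabilities in (0, 1).
#' @export
ilogit <- function(x) {
  out <- ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
  out
}

#' Logit link
#'
#' @param p probabilities in (0, 1).
#' @return log-odds.
#' @export
logit <- function(p) {
  stopifnot(all(p > 0 & p < 1))
  log(p / (1 - p))
}

# Internal: check a numeric vector is binary 0/1
is_binary01 <- function(x) all(x %in% c(0, 1))

# Internal: stop with a formatted message
fail <- function(...) stop(sprintf(...), call. = FALSE)
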