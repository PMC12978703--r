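# shared input checks and seed derivation

.check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

#' Derive a stream seed from a master seed
#'
#' Every stochastic stage draws its own seed from the run's master seed by a
#' fixed splitting rule, so a whole analysis is reproducible from one
#' integer. The rule is a multiplicative hash reduced modulo 2^31 - 1 and is
#' never time-based.
#'
#' @param master Master seed (non-negative integer).
#' @param stream Stream label (character) naming the consumer stage.
#' @param index Optional index within the stream (e.g. trajectory number).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stream, index = 0L) {
  .check_scalar(master, "master")
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  m <- 2147483647
  s <- (as.double(master) %% m)
  s <- (s * 48271 + h * 7919 + as.double(index) * 104729 + 12345) %% m
  # avoid the degenerate 0 seed
  as.integer(s %% (m - 2) + 1)
}

.as_matrix <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 1L) else as.matrix(x)
}
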