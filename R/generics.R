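# Broom-style generics for the package's fitted/result objects.

#' Turn a result object into a tidy tibble
#' @param x A result object (e.g. `sigma_sweep`, `nlf_estimate`).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of a result object
#' @inheritParams tidy
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")
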