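# Internal validators and small numeric helpers shared across modules.

stop_invalid <- function(msg) stop(msg, call. = FALSE)

assert_image <- function(img, name = "image", allow_negative = TRUE) {
  if (!is.matrix(img) || !is.numeric(img))
    stop_invalid(sprintf("%s must be a numeric matrix", name))
  if (anyNA(img) || any(!is.finite(img)))
    stop_invalid(sprintf("%s contains non-finite values", name))
  if (!allow_negative && any(img < 0))
    stop_invalid(sprintf("%s must be nonnegative", name))
  invisible(img)
}

assert_same_shape <- function(x, y) {
  if (!identical(dim(x), dim(y)))
    stop_invalid("images must have identical dimensions")
  invisible(NULL)
}

assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid(sprintf("%s must be a positive finite scalar", name))
  invisible(x)
}

# Round-half-up at two decimals, with a tiny guard against binary representation
# of midpoints (1.085 stores just below the midpoint and must report as 1.09).
round2_half_up <- function(x) floor(x * 100 + 0.5 + 1e-6) / 100

# Clip to a closed range; NULL range is a no-op.
clip_range <- function(img, range) {
  if (is.null(range)) return(img)
  pmin(pmax(img, range[1]), range[2])
}
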