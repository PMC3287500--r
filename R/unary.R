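#' Unary (1UN) number representation
#'
#' The mesh components operate on non-negative integers in the 1UN unary
#' format: a value `x` stored in `w` bits is a prefix of `x + 1` one-bits
#' followed by zeros (`b_i = 1` for all `i <= x`).  The all-zero pattern is
#' reserved as the underflow marker for operations that would produce a
#' negative result.  Encodable values are therefore `0 .. w - 1`.
#'
#' A 1UN value is represented as a plain integer vector of 0/1 of length `w`;
#' these helpers enforce the prefix invariant.
#'
#' @param x non-negative integer value to encode.
#' @param w bit width of the representation.
#' @return `un_encode` returns an integer 0/1 vector of length `w`.
#' @examples
#' un_encode(3, 8)            # 1 1 1 1 0 0 0 0
#' un_decode(un_encode(3, 8)) # 3
#' @export
un_encode <- function(x, w) {
  stopifnot(length(x) == 1L, length(w) == 1L, w >= 1L)
  x <- as.integer(x); w <- as.integer(w)
  if (is.na(x) || x < 0L)
    stop("un_encode: x must be a non-negative integer")
  if (x > w - 1L)
    stop(sprintf("un_encode: capacity error, value %d does not fit in width %d (max %d)",
                 x, w, w - 1L))
  c(rep(1L, x + 1L), rep(0L, w - x - 1L))
}

#' @rdname un_encode
#' @param u an integer 0/1 vector holding a 1UN pattern.
#' @return `un_decode` returns the encoded integer, or `NA` for the all-zero
#'   underflow marker.
#' @export
un_decode <- function(u) {
  if (!un_is_valid(u))
    stop("un_decode: representation error, bits are not a 1UN prefix pattern")
  if (all(u == 0L)) return(NA_integer_)
  sum(u) - 1L
}

#' @rdname un_encode
#' @return `un_is_underflow` returns `TRUE` for the reserved all-zero pattern.
#' @export
un_is_underflow <- function(u) all(u == 0L)

#' @rdname un_encode
#' @return `un_is_valid` checks the prefix invariant (monotone non-increasing
#'   bits, or all zero).
#' @export
un_is_valid <- function(u) {
  if (length(u) < 1L || anyNA(u) || !all(u %in% c(0L, 1L))) return(FALSE)
  all(diff(u) <= 0L)
}

#' @rdname un_encode
#' @return `un_underflow` returns the all-zero underflow pattern of width `w`.
#' @export
un_underflow <- function(w) rep(0L, as.integer(w))

#' Drop the zero-representing bit of a 1UN value
#'
#' Left-shifts a 1UN pattern by one bit (drops `b_0`, appends a 0).  Because a
#' 1UN encoding of `x` carries `x + 1` ones, the shifted pattern carries
#' exactly `x` ones: this is how the adder/subtractor's second operand is fed
#' into the West border so that its rows correspond one-to-one to unit
#' increments.
#'
#' @param u an integer 0/1 vector holding a 1UN pattern.
#' @return the shifted pattern, same width.
#' @export
un_shift_left <- function(u) {
  stopifnot(length(u) >= 1L)
  c(u[-1L], 0L)
}
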