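# Slider ratings live on [0, 100]; the beta likelihood needs the open unit
# interval. The affine map below compresses [0, 100] onto
# [0.0005, 0.9995] so no observation sits on a boundary.
UNIT_SCALE <- 0.999
UNIT_OFFSET <- 0.0005

#' Map raw slider ratings to the open unit interval
#'
#' Applies the affine transformation `y = (x / 100) * 0.999 + 0.0005`,
#' which carries the 0--100 slider scale onto `[0.0005, 0.9995]` so that
#' transformed ratings never touch 0 or 1 and can be modelled with a beta
#' likelihood.
#'
#' @param x Numeric vector of raw ratings in `[0, 100]`.
#' @return Numeric vector of unit-interval ratings in `[0.0005, 0.9995]`.
#' @seealso [unit_to_rating()] for the inverse map.
#' @examples
#' rating_to_unit(c(0, 50, 100))
#' @export
rating_to_unit <- function(x) {
  if (!is.numeric(x)) {
    stop("ratings must be numeric", call. = FALSE)
  }
  bad <- which(!is.na(x) & (x < 0 | x > 100))
  if (length(bad)) {
    stop(sprintf("rating out of [0, 100]: %s", paste(x[bad], collapse = ", ")),
         call. = FALSE)
  }
  (x / 100) * UNIT_SCALE + UNIT_OFFSET
}

#' Map unit-interval ratings back to the raw slider scale
#'
#' Inverse of [rating_to_unit()]: `x = (y - 0.0005) / 0.999 * 100`.
#'
#' @param y Numeric vector of unit-interval ratings in `[0.0005, 0.9995]`.
#' @return Numeric vector of raw ratings in `[0, 100]`.
#' @examples
#' unit_to_rating(rating_to_unit(37.2))
#' @export
unit_to_rating <- function(y) {
  if (!is.numeric(y)) {
    stop("unit ratings must be numeric", call. = FALSE)
  }
  tol <- 1e-12
  bad <- which(!is.na(y) & (y < UNIT_OFFSET - tol | y > 1 - UNIT_OFFSET + tol))
  if (length(bad)) {
    stop(sprintf("unit rating out of [%g, %g]: %s", UNIT_OFFSET,
                 1 - UNIT_OFFSET, paste(y[bad], collapse = ", ")),
         call. = FALSE)
  }
  (y - UNIT_OFFSET) / UNIT_SCALE * 100
}
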