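# Gyromagnetic frequency ratios relative to 1H. Used to convert the
# spectrometer 1H field (MHz) into per-nucleus Larmor frequencies so that
# ppm displacements can be expressed in Hz.
GYRO_RATIO <- c(H1 = 1, N15 = 0.10136767, C13 = 0.25144953)

KNOWN_NUCLEI <- names(GYRO_RATIO)

#' Larmor frequency of a nucleus at a given spectrometer field
#'
#' @param nucleus character vector of nucleus identifiers
#'   (\code{"H1"}, \code{"N15"}, \code{"C13"}).
#' @param field_h1 spectrometer 1H Larmor frequency in MHz (e.g. 600, 950).
#' @return numeric vector of Larmor frequencies in MHz.
#' @examples
#' larmor_frequency("N15", 600)  # 60.82 MHz
#' @export
larmor_frequency <- function(nucleus, field_h1) {
  stopifnot(is.numeric(field_h1), field_h1 > 0)
  bad <- setdiff(nucleus, KNOWN_NUCLEI)
  if (length(bad) > 0) {
    stop("unknown nucleus identifier(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(KNOWN_NUCLEI, collapse = ", "), ")")
  }
  unname(GYRO_RATIO[nucleus] * field_h1)
}

# round-half-up at d decimals; base round() goes half-to-even which does
# not match how titration tables and percentages are conventionally quoted
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
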