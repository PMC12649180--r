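#' Closed vocabularies used throughout the package
#'
#' Habitat types, seasons, and flight-height bands recognised by the survey
#' readers and the simulator. Height bands partition altitude as
#' [0,5), [5,30), [30,50), [50,100), [100,Inf) metres.
#'
#' @name vocabularies
#' @keywords internal
NULL

HABITATS <- c("urban", "farmland", "forest", "wetland")
SEASONS <- c("spring", "summer", "autumn", "winter")
HEIGHT_BANDS <- c("B0_5", "B5_30", "B30_50", "B50_100", "B100plus")
ZONES <- c("inside", "outside")

#' Round half away from zero
#'
#' Decimal rounding with halves rounded up (away from zero), the convention
#' used for report percentages. Base \code{round()} rounds halves to even,
#' which would turn e.g. 0.125 into 0.12 rather than 0.13.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage share of a count
#'
#' \code{100 * count / total}, rounded half-up to \code{digits} decimals.
#' Used for all report-style percentage columns (risk-tier shares, taxon
#' shares, and the like).
#'
#' @param count numeric count(s).
#' @param total denominator.
#' @param digits decimal places (default 2).
#' @return numeric percentage(s).
#' @examples
#' percent_share(109, 148) # 73.65
#' @export
percent_share <- function(count, total, digits = 2) {
  stopifnot(total > 0)
  round_half_up(100 * count / total, digits)
}

# stop() with a consistent prefix, no call in the message
abort <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
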