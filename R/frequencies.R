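# Canonical frequency design shared by all modules: three fundamental flicker
# frequencies (7, 13, 17 Hz), their first/second harmonics and subharmonics,
# and the fixed ordering of the nine frequencies of interest.

FOI <- c(7, 14, 21, 6.5, 13, 26, 8.5, 17, 34)
FOI_FAMILY <- c(7, 7, 7, 13, 13, 13, 17, 17, 17)
FAMILY_COMMAND <- c("7" = 1L, "13" = 2L, "17" = 3L)
PAIR_COMMAND <- c("7+13" = 4L, "7+17" = 5L, "13+17" = 6L)

#' Frequencies of interest for SSVEP detection
#'
#' The nine target frequencies monitored by the detector, in their fixed
#' canonical order: each fundamental (7, 13, 17 Hz) together with its first and
#' second harmonics, and the subharmonics used by the mixed
#' fundamental-harmonic stimuli (6.5 and 8.5 Hz).
#'
#' @return Numeric vector of length 9: `c(7, 14, 21, 6.5, 13, 26, 8.5, 17, 34)`.
#' @seealso [foi_families()], [flicker_table()]
#' @export
frequencies_of_interest <- function() FOI

#' Frequency families
#'
#' Groups the frequencies of interest by their fundamental. A detected peak at
#' a harmonic counts towards its fundamental's family when commands are
#' decoded.
#'
#' @return Named list: `"7" = c(7, 14, 21)`, `"13" = c(6.5, 13, 26)`,
#'   `"17" = c(8.5, 17, 34)`.
#' @export
foi_families <- function() {
  list("7" = FOI[1:3], "13" = FOI[4:6], "17" = FOI[7:9])
}

#' Fundamental family of a frequency of interest
#'
#' @param f Numeric vector of frequencies; each must be one of the nine
#'   frequencies of interest.
#' @return Numeric vector of fundamentals (7, 13 or 17), `NA` for frequencies
#'   outside the set.
#' @export
family_of <- function(f) FOI_FAMILY[match(f, FOI)]
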