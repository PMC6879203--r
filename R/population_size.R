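# Conversion of genetic effective-size estimates into census head counts.
# Mitochondrial data estimate the female effective size (Nef); translating it
# into a census range requires (i) a female-to-total doubling factor and
# (ii) a range of plausible Ne/Nc ratios from the comparative literature.

#' Record a female effective population size estimate
#'
#' @param nef Point estimate of the female effective size (individuals).
#' @param lo,hi Credibility interval bounds.
#' @param generation_interval Generation interval in years used upstream in
#'   the dating of the estimate (documentation only; it does not enter the
#'   census conversion). Default 12.
#' @return An object of class `auk_nef`.
#' @export
#' @examples
#' effective_size_estimate(9558, 4548, 19665)
effective_size_estimate <- function(nef, lo, hi, generation_interval = 12) {
  stopifnot(nef > 0, lo > 0, hi > 0, lo <= nef, nef <= hi,
            generation_interval > 0)
  structure(list(nef = nef, lo = lo, hi = hi,
                 generation_interval = generation_interval),
            class = "auk_nef")
}

#' @export
print.auk_nef <- function(x, ...) {
  cat(sprintf("Female effective size: %s (95%% CI %s-%s), generation interval %g y\n",
              format(x$nef, big.mark = ","), format(x$lo, big.mark = ","),
              format(x$hi, big.mark = ","), x$generation_interval))
  invisible(x)
}

#' Total effective size from the female effective size
#'
#' Mitochondrial DNA tracks the female lineage only; under an even adult sex
#' ratio the total effective size is twice the female one. The doubling
#' factor is exposed as a documented assumption.
#'
#' @param nef Female effective size (positive; vectorised).
#' @param doubling_factor Multiplier from female to total effective size.
#'   Default 2.
#' @return `doubling_factor * nef`.
#' @export
#' @examples
#' total_effective_from_female(9558)  # 19116
total_effective_from_female <- function(nef, doubling_factor = 2) {
  if (any(nef <= 0) || doubling_factor <= 0)
    stop("effective sizes and the doubling factor must be positive")
  doubling_factor * nef
}

#' Ne/Nc ratio range
#'
#' @param lo,hi Bounds of the plausible effective-to-census ratio, each in
#'   `(0, 1]` with `lo <= hi`.
#' @return An object of class `auk_ratios`.
#' @export
ne_nc_ratios <- function(lo, hi) {
  if (!(lo > 0 && lo <= hi && hi <= 1))
    stop("Ne/Nc ratios must satisfy 0 < lo <= hi <= 1")
  structure(list(lo = lo, hi = hi), class = "auk_ratios")
}

#' Census size range from an effective size range
#'
#' Widest-interval convention: the lower census bound divides the lower
#' effective bound by the *largest* ratio, and the upper census bound the
#' upper effective bound by the *smallest* ratio. Results are rounded to the
#' nearest individual.
#'
#' @param ne_lo,ne_hi Effective population size bounds.
#' @param ratios An [ne_nc_ratios()] object.
#' @return Named numeric vector `c(nc_lo, nc_hi)`.
#' @export
#' @examples
#' census_from_effective(100, 100, ne_nc_ratios(0.1, 0.5))  # 200, 1000
census_from_effective <- function(ne_lo, ne_hi, ratios) {
  stopifnot(inherits(ratios, "auk_ratios"))
  if (!(ne_lo > 0 && ne_lo <= ne_hi))
    stop("effective-size bounds must be positive with lo <= hi")
  c(nc_lo = round(ne_lo / ratios$hi), nc_hi = round(ne_hi / ratios$lo))
}
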