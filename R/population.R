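#' Initial population at the stable age distribution
#'
#' Allocates `n0` individuals across sex and age classes `1..max_age`
#' proportionally to the model's stable age distribution, split evenly
#' between the sexes (or by `sex_ratio`), using largest-remainder rounding so
#' the integer counts sum exactly to `n0`. Deterministic.
#'
#' @param n0 Total starting population size (individuals), at least 2.
#' @param model An `auk_leslie` from [build_leslie()].
#' @param sex_ratio Female share of each age class. Default 0.5.
#' @return A `population_state`: integer matrix with rows `F`, `M` and one
#'   column per age class, with attribute `year = 0`.
#' @export
#' @examples
#' pre <- conservative_preset()
#' st <- initial_population(2e6, pre$model)
#' sum(st)                                   # exactly 2e6
#' count_mature(st, pre$breeding$first_breeding)
initial_population <- function(n0, model, sex_ratio = 0.5) {
  stopifnot(inherits(model, "auk_leslie"))
  if (!is.numeric(n0) || length(n0) != 1 || n0 < 2)
    stop("the starting population must hold at least 2 individuals")
  if (anyNA(model$stable_age))
    stop("the model has no stable age distribution (lambda = 0)")
  w <- rbind(F = sex_ratio * model$stable_age,
             M = (1 - sex_ratio) * model$stable_age)
  target <- w * n0
  counts <- floor(target)
  shortfall <- round(n0 - sum(counts))
  if (shortfall > 0) {
    frac <- target - counts
    top <- order(frac, decreasing = TRUE)[seq_len(shortfall)]
    counts[top] <- counts[top] + 1
  }
  population_state(counts, year = 0L)
}

#' Construct a population state
#'
#' @param counts Non-negative integer matrix, rows `F` and `M`, one column
#'   per age class `1..max_age`.
#' @param year Census year.
#' @return A `population_state`.
#' @export
population_state <- function(counts, year = 0L) {
  stopifnot(is.matrix(counts), nrow(counts) == 2)
  if (any(counts < 0)) stop("population counts must be non-negative")
  rownames(counts) <- c("F", "M")
  colnames(counts) <- as.character(seq_len(ncol(counts)))
  structure(counts, year = as.integer(year), class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population state, year %d: %s individuals (%s F / %s M) over %d age classes\n",
              attr(x, "year"),
              format(sum(x), big.mark = ","),
              format(sum(x[1, ]), big.mark = ","),
              format(sum(x[2, ]), big.mark = ","), ncol(x)))
  invisible(x)
}

#' Count mature individuals
#'
#' Sum of both sexes over all age classes at or above the age at first
#' breeding.
#'
#' @param state A `population_state`.
#' @param first_breeding Age at first breeding (years).
#' @return Number of mature individuals.
#' @export
count_mature <- function(state, first_breeding) {
  stopifnot(inherits(state, "population_state"),
            first_breeding >= 1, first_breeding <= ncol(state))
  sum(state[, first_breeding:ncol(state)])
}

#' Maximum annual egg production
#'
#' The number of eggs that would be produced if all mature individuals were
#' breeding: one egg per monogamous pair, with pairs limited to
#' `floor(mature / 2)` under an even sex ratio.
#'
#' @param mature Number of mature individuals (vectorised).
#' @return `floor(mature / 2)` eggs.
#' @export
#' @examples
#' max_annual_eggs(1027532)  # 513766
#' max_annual_eggs(3082594)  # 1541297
max_annual_eggs <- function(mature) {
  stopifnot(is.numeric(mature), all(mature >= 0))
  floor(mature / 2)
}
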