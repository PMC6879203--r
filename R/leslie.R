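#' Dominant eigenpair of a projection matrix
#'
#' Extracts the asymptotic annual growth rate (dominant eigenvalue) and the
#' stable age distribution (matching right eigenvector, normalised to sum to
#' one) of a non-negative projection matrix. By Perron-Frobenius the dominant
#' eigenvalue of such a matrix is real and its eigenvector non-negative.
#'
#' @param m A square non-negative matrix.
#' @return A list with `lambda` (dominant eigenvalue), `stable_age`
#'   (normalised eigenvector; `NA` when `lambda` is numerically zero) and
#'   `residual` (the max-norm eigen residual `|M v - lambda v|`).
#' @export
#' @examples
#' dominant_eigen(matrix(c(0, 1, 0.5, 0), 2, 2))$lambda  # sqrt(0.5)
dominant_eigen <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (any(m < 0)) stop("projection matrix entries must be non-negative")
  e <- eigen(m)
  i <- which.max(Re(e$values))
  lambda <- Re(e$values[i])
  if (abs(Im(e$values[i])) > 1e-8 * max(1, abs(lambda)))
    stop("eigen extraction did not converge to a real dominant eigenvalue")
  if (lambda <= 1e-12) {
    return(list(lambda = 0, stable_age = rep(NA_real_, nrow(m)),
                residual = 0))
  }
  v <- abs(Re(e$vectors[, i]))
  v <- v / sum(v)
  residual <- max(abs(m %*% v - lambda * v))
  list(lambda = lambda, stable_age = as.numeric(v), residual = residual)
}

#' Build the female-only Leslie projection model
#'
#' Constructs the deterministic annual projection matrix over female age
#' classes `1..max_age` that corresponds to the stochastic annual cycle used
#' by the simulator (breed, natural mortality, ageing). Newborns are not a
#' census class: an egg laid by a female of breeding age survives first-year
#' mortality `q0` before entering class 1, so fertility entries are
#' `f * (1 - q0)` for all ages at or above `first_breeding`, with per-female
#' fecundity `f = clutch * sex_ratio * p_breed * p_success`. Survival
#' `1 - q[x]` sits on the sub-diagonal; individuals at the maximum age breed
#' and then die (no survival out of the last class).
#'
#' @param life_table An [life_table()].
#' @param breeding A [breeding_params()].
#' @param fecundity_scale Extra multiplicative factor on fecundity, used by
#'   the calibration layer to represent a fixed egg harvest as a constant
#'   proportional drag on reproduction. Default 1.
#' @return An object of class `auk_leslie`: list with `matrix`, `lambda`,
#'   `stable_age` (over classes `1..max_age`), `mature_fraction` (share of
#'   the stable age distribution at or above the breeding age),
#'   `first_breeding` and `max_age`.
#' @export
#' @examples
#' pre <- conservative_preset()
#' mod <- build_leslie(pre$life_table, pre$breeding)
#' mod$lambda          # asymptotic annual growth rate
#' sum(mod$stable_age) # 1
build_leslie <- function(life_table, breeding, fecundity_scale = 1) {
  stopifnot(inherits(life_table, "auk_life_table"),
            inherits(breeding, "auk_breeding"),
            fecundity_scale >= 0)
  A <- life_table$max_age
  b <- breeding$first_breeding
  if (b > A) stop("age at first breeding exceeds the maximum age")
  q <- life_table$q
  if (b > 1 && any(q[2:b] >= 1))  # ages 1..b-1
    stop("no reproductive path: a juvenile age class has survival 0")
  f <- breeding$clutch * breeding$sex_ratio * breeding$p_breed *
    breeding$p_success * fecundity_scale
  s0 <- 1 - q[1]
  m <- matrix(0, A, A)
  m[1, b:A] <- f * s0
  for (x in 1:(A - 1)) m[x + 1, x] <- 1 - q[x + 1]
  eig <- dominant_eigen(m)
  if (eig$lambda > 0 && eig$residual >= 1e-10)
    stop("eigen extraction failed to meet the residual tolerance: ",
         format(eig$residual))
  mature_fraction <- if (eig$lambda > 0) sum(eig$stable_age[b:A]) else NA_real_
  structure(list(matrix = m, lambda = eig$lambda,
                 stable_age = eig$stable_age,
                 mature_fraction = mature_fraction,
                 first_breeding = b, max_age = A,
                 fecundity_scale = fecundity_scale),
            class = "auk_leslie")
}

#' Asymptotic growth rate and stable age distribution of a Leslie model
#'
#' Accessor for the dominant eigenpair of a built model: the asymptotic
#' annual growth rate `lambda` and the stable age distribution the
#' population converges to under fixed vital rates.
#'
#' @param model An `auk_leslie` from [build_leslie()].
#' @return A list with `lambda` and `stable_age`.
#' @export
asymptotic_growth_and_stable_age <- function(model) {
  stopifnot(inherits(model, "auk_leslie"))
  list(lambda = model$lambda, stable_age = model$stable_age)
}

#' Project an age vector forward with a Leslie matrix
#'
#' Deterministic projection `n_{t+1} = M n_t`, repeated `years` times.
#'
#' @param model An `auk_leslie` (or a plain projection matrix).
#' @param n Initial age-class vector.
#' @param years Number of annual transitions.
#' @return Matrix with `years + 1` columns holding the trajectory.
#' @export
project_leslie <- function(model, n, years) {
  m <- if (inherits(model, "auk_leslie")) model$matrix else model
  stopifnot(is.matrix(m), length(n) == nrow(m), years >= 0)
  out <- matrix(0, nrow(m), years + 1)
  out[, 1] <- n
  for (t in seq_len(years)) out[, t + 1] <- m %*% out[, t]
  out
}

#' @export
print.auk_leslie <- function(x, ...) {
  cat(sprintf(
    "Leslie model over ages 1..%d (first breeding %d): lambda = %.5f, mature fraction = %.4f\n",
    x$max_age, x$first_breeding, x$lambda, x$mature_fraction))
  invisible(x)
}
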