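#' @useDynLib enthcg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif sd lm coef optimize nlminb dnorm var setNames
#' @importFrom utils head tail
NULL

## Boltzmann constant, kcal/(mol K). Energies are kcal/mol, lengths nm,
## times ps, temperatures K throughout; EPR observables use Angstrom/Gauss.
kB <- 0.0019872041

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

## Evaluate `code` under a fixed RNG seed without touching global RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## Derive a stream of child seeds from one parent seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

vnorm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("Cannot normalize a zero vector.")
  v / n
}

## Rotation matrices about principal axes (angle in radians)
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

## Random rotation matrix (uniform over SO(3)), uses current RNG stream
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(paste0("`", name, "` must be a single number."))
  }
  if (positive && x <= 0) abort(paste0("`", name, "` must be positive."))
  invisible(x)
}
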