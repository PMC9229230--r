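`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so generators are
#' reproducible without clobbering the session RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_invalid <- function(...) stop(..., call. = FALSE)

#' Cross product of two 3-vectors
#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis (Rodrigues' formula)
#'
#' @param axis length-3 axis vector (need not be unit).
#' @param angle rotation angle in radians.
#' @return a 3x3 rotation matrix.
#' @keywords internal
rotation_matrix <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < .Machine$double.eps) return(diag(3))
  u <- axis / n
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Rectangle extent constructor
#'
#' @param xmin,ymin,xmax,ymax corners in map meters.
#' @return a named numeric vector `c(xmin, ymin, xmax, ymax)`.
#' @export
extent_rect <- function(xmin, ymin, xmax, ymax) {
  if (!(xmax > xmin && ymax > ymin)) {
    stop_invalid("degenerate extent: require xmax > xmin and ymax > ymin")
  }
  c(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax)
}
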