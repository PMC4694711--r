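# Least-squares rigid-body superposition (Kabsch algorithm).

#' Optimal rigid superposition of two point sets
#'
#' Kabsch algorithm: returns the rotation matrix and translation that
#' superpose \code{P} onto \code{Q} with minimum RMSD (proper rotation only;
#' reflections are excluded by the determinant correction).
#'
#' @param P,Q n x 3 coordinate matrices in row correspondence.
#' @param weights optional non-negative per-point weights.
#' @return list with \code{R} (3 x 3 rotation), \code{cP}, \code{cQ}
#'   (centroids) and \code{transform(X)}, a function applying the fit to any
#'   m x 3 matrix.
#' @export
kabsch <- function(P, Q, weights = NULL) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3, ncol(Q) == 3, nrow(P) == nrow(Q), nrow(P) >= 3)
  if (is.null(weights)) weights <- rep(1, nrow(P))
  w <- weights / sum(weights)
  cP <- colSums(P * w); cQ <- colSums(Q * w)
  P0 <- sweep(P, 2, cP); Q0 <- sweep(Q, 2, cQ)
  H <- t(P0 * w) %*% Q0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(
    R = R, cP = cP, cQ = cQ,
    transform = function(X) {
      sweep(sweep(as.matrix(X), 2, cP) %*% t(R), 2, cQ, `+`)
    }
  )
}

#' Superpose coordinates onto a reference
#' @inheritParams kabsch
#' @return \code{P} after the optimal rigid fit onto \code{Q}.
#' @export
superpose <- function(P, Q, weights = NULL) kabsch(P, Q, weights)$transform(P)

#' RMSD after optimal superposition
#' @inheritParams kabsch
#' @return root-mean-square deviation (Å) after the Kabsch fit.
#' @export
kabsch_rmsd <- function(P, Q) {
  Pf <- superpose(P, Q)
  sqrt(mean(rowSums((Pf - as.matrix(Q))^2)))
}

#' Apply a rigid transform to a structure model
#' @param model a \code{structure_model}.
#' @param R 3 x 3 rotation matrix.
#' @param t length-3 translation vector (Å).
#' @return the transformed \code{structure_model}.
#' @export
transform_model <- function(model, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(R), 2, t, `+`)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

#' Random rotation matrix (uniform over SO(3))
#' @param rng optional function returning n uniform deviates; defaults to
#'   \code{stats::runif} (driven by the session RNG / set.seed).
#' @keywords internal
random_rotation <- function() {
  # Arvo's method via quaternions
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}
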