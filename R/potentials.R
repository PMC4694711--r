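# Restraint scoring potentials and their evaluation on structures.

#' Shallow sigmoidal restraint potential
#'
#' \deqn{f(x) = \frac{1}{1 + e^{-m (x - x_0)}} - 0.5}
#'
#' Strictly increasing, range (-0.5, 0.5), zero at \code{x0}. Distances well
#' below \code{x0} contribute a bonus approaching -0.5; distances well above
#' plateau near +0.5 with vanishing derivative, so violated restraints exert
#' essentially no force on the model.
#'
#' @param x distance (Å); vectorised.
#' @param x0 midpoint (Å), default 8.
#' @param m steepness (1/Å), must be > 0, default 1.
#' @return score(s), unitless.
#' @export
#' @examples
#' sigmoid_score(8)          # 0
#' sigmoid_score(10)         # 1/(1+exp(-2)) - 0.5 ~ 0.38079
sigmoid_score <- function(x, x0 = 8.0, m = 1.0) {
  if (!is.numeric(m) || any(m <= 0)) stop("sigmoid steepness m must be > 0")
  1 / (1 + exp(-m * (x - x0))) - 0.5
}

#' Flat-bottom bounded restraint potential
#'
#' Zero on \code{[lb, ub]}, quadratic \eqn{((x-lb)/sd)^2} below \code{lb},
#' quadratic \eqn{((x-ub)/sd)^2} on \code{(ub, ub + 0.5 sd]}, then linear with
#' slope \code{1/sd}:
#' \deqn{f(x) = \frac{1}{sd}\,(x - (ub + 0.5\,sd)) + (0.5)^2 \quad
#'   \mathrm{for}\ x > ub + 0.5\,sd}
#' The linear tail joins the quadratic branch continuously at
#' \code{ub + 0.5 sd}.
#'
#' @param x distance (Å); vectorised.
#' @param lb,ub lower and upper bound (Å), \code{lb < ub}.
#' @param sd softness scale (Å), must be > 0; default 1.
#' @return non-negative score(s), unitless.
#' @export
bounded_score <- function(x, lb, ub, sd = 1.0) {
  if (!is.numeric(sd) || any(sd <= 0)) stop("bounded potential needs sd > 0")
  if (any(lb >= ub)) stop("bounded potential needs lb < ub")
  knee <- ub + 0.5 * sd
  ifelse(x < lb, ((x - lb) / sd)^2,
    ifelse(x <= ub, 0,
      ifelse(x <= knee, ((x - ub) / sd)^2,
        (x - knee) / sd + (0.5 * sd / sd)^2
      )
    )
  )
}

.potential_eval <- function(x, kind, x0, m, lb, ub, sd) {
  if (kind == "sigmoid") sigmoid_score(x, x0, m) else bounded_score(x, lb, ub, sd)
}

#' Atom-pair distances of restraints on a model
#'
#' @param model a \code{structure_model}.
#' @param restraints a \code{restraint_set}.
#' @return numeric vector of Euclidean distances (Å), one per restraint row.
#' @export
restraint_distances <- function(model, restraints) {
  stopifnot(inherits(restraints, "restraint_set"))
  a1 <- atom_coords(model, restraints$res1, restraints$atom1)
  a2 <- atom_coords(model, restraints$res2, restraints$atom2)
  unname(sqrt(rowSums((a1 - a2)^2)))
}

#' Score restraints on a structure model
#'
#' Evaluates each restraint's potential at the model's atom-pair distance.
#' Restraints in an ambiguity group are scored collectively: the group score
#' is the minimum over its members (the best-satisfied candidate carries the
#' group), and that minimum is reported for every member row.
#'
#' @param model a \code{structure_model}.
#' @param restraints a \code{restraint_set}.
#' @return data.frame with columns \code{distance}, \code{score} (per-row
#'   potential value), \code{group_score} (min over the ambiguity group;
#'   equals \code{score} for unambiguous restraints) and \code{satisfied}
#'   (distance <= 8 Å).
#' @export
restraint_score <- function(model, restraints) {
  d <- restraint_distances(model, restraints)
  score <- numeric(nrow(restraints))
  for (k in seq_len(nrow(restraints))) {
    r <- restraints[k, ]
    score[k] <- .potential_eval(d[k], r$kind, r$x0, r$m, r$lb, r$ub, r$sd)
  }
  group_score <- score
  for (g in unique(restraints$group[!is.na(restraints$group)])) {
    idx <- which(!is.na(restraints$group) & restraints$group == g)
    group_score[idx] <- min(score[idx])
  }
  data.frame(distance = d, score = score, group_score = group_score,
             satisfied = d <= 8.0)
}

#' Is a restraint satisfied on a model?
#'
#' A distance restraint counts as satisfied when the inter-atom distance is
#' at most \code{cutoff} (8 Å by convention, matching the contact definition).
#'
#' @inheritParams restraint_score
#' @param cutoff satisfaction cutoff (Å), default 8.
#' @return logical vector, one per restraint row.
#' @export
is_satisfied <- function(model, restraints, cutoff = 8.0) {
  restraint_distances(model, restraints) <= cutoff
}
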