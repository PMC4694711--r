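# Side-chain chi dihedrals, rotamer-well assignment, and rotamer recovery.

#' Dihedral angle of four points
#'
#' Standard atan2 formulation; returned in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors (Å).
#' @return dihedral angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi  # IUPAC sign
  if (ang <= -180) ang <- ang + 360
  ang
}

# chi-angle atom quadruples per residue type (heavy atoms, standard names)
.chi_atoms <- list(
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  VAL = list(c("N", "CA", "CB", "CG1"))
)

.chi_angle <- function(model, resno, quad) {
  at <- model$atoms
  key <- paste(at$resno, at$elety)
  idx <- match(paste(resno, quad), key)
  if (anyNA(idx)) return(NA_real_)
  xyz <- as.matrix(at[idx, c("x", "y", "z")])
  dihedral_angle(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
}

#' chi1 dihedral of a residue
#'
#' N-CA-CB-gamma dihedral in degrees; \code{NA} (with a warning) when the
#' residue is alanine/glycine or lacks the required atoms.
#'
#' @param model a \code{structure_model}.
#' @param resno residue index.
#' @return chi1 in degrees, or \code{NA}.
#' @export
chi1_angle <- function(model, resno) {
  res3 <- toupper(model$atoms$resid[match(resno, model$atoms$resno)])
  if (is.na(res3) || !res3 %in% names(.chi_atoms)) {
    warning(sprintf("chi1 undefined for residue %s %s", resno, res3))
    return(NA_real_)
  }
  ang <- .chi_angle(model, resno, .chi_atoms[[res3]][[1]])
  if (is.na(ang)) warning(sprintf("missing chi1 atoms for residue %d", resno))
  ang
}

# canonical chi wells: gauche+ (+60), trans (180), gauche- (-60)
.well_centers <- c("g+" = 60, "t" = 180, "g-" = -60)

.circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Assign a chi angle to its canonical rotamer well
#'
#' Nearest of the three staggered wells at +60, 180 and -60 degrees under
#' circular distance.
#'
#' @param chi angle(s) in degrees.
#' @return character vector: \code{"g+"}, \code{"t"} or \code{"g-"}
#'   (\code{NA} propagated).
#' @export
chi_well <- function(chi) {
  vapply(chi, function(a) {
    if (is.na(a)) return(NA_character_)
    names(.well_centers)[which.min(abs(.circ_diff(a, .well_centers)))]
  }, character(1))
}

#' chi1 rotamer well of a residue
#' @inheritParams chi1_angle
#' @return \code{"g+"}, \code{"t"}, \code{"g-"} or \code{NA}.
#' @export
chi1_well <- function(model, resno) chi_well(chi1_angle(model, resno))

#' Circular mean of angles in degrees
#' @param deg angles in degrees (NAs dropped).
#' @return mean direction in degrees in (-180, 180].
#' @export
circular_mean <- function(deg) {
  deg <- deg[!is.na(deg)]
  rad <- deg * pi / 180
  atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
}

#' Circular standard deviation of angles in degrees
#'
#' \eqn{\sqrt{-2 \ln \bar R}} where \eqn{\bar R} is the mean resultant
#' length; correctly treats wraparound, so {179, -179, 178} has an SD under a
#' degree.
#'
#' @param deg angles in degrees (NAs dropped).
#' @return circular SD in degrees.
#' @export
circular_sd <- function(deg) {
  deg <- deg[!is.na(deg)]
  rad <- deg * pi / 180
  R <- sqrt(mean(sin(rad))^2 + mean(cos(rad))^2)
  R <- min(max(R, 1e-12), 1)
  sqrt(-2 * log(R)) * 180 / pi
}

#' Buried side-chain chi1 rotamer recovery
#'
#' Reproduces the side-chain accuracy analysis over an ensemble of low-energy
#' models: side chains buried in the reference (side-chain SASA strictly
#' below \code{sasa_cut}; alanine and glycine excluded) are tested for
#' convergence across the models (circular SD of chi1 strictly below
#' \code{chi1_sd_cut}); for the converged-and-buried subset, the rotamer well
#' of the ensemble's circular-mean chi1 is compared to the reference well.
#' The all-chi fraction additionally requires every defined side-chain chi
#' angle to fall in the reference well; both its published denominators are
#' reported (converged-and-buried, and buried).
#'
#' @param models list of low-energy \code{structure_model}s (>= 2).
#' @param reference the native \code{structure_model}.
#' @param sasa_cut burial threshold on reference side-chain SASA (Å^2).
#' @param chi1_sd_cut convergence threshold on the chi1 circular SD (degrees).
#' @param probe,n_points forwarded to [sasa()].
#' @return list with counts \code{n_buried}, \code{n_converged_buried},
#'   \code{n_chi1_recovered}, fractions \code{frac_chi1}, \code{frac_all_chi},
#'   \code{frac_all_chi_buried}, and the per-residue detail table
#'   \code{residues}.
#' @export
rotamer_recovery <- function(models, reference, sasa_cut = 40,
                             chi1_sd_cut = 10, probe = 1.4, n_points = 960) {
  if (inherits(models, "structure_model")) models <- list(models)
  if (length(models) < 2) stop("rotamer recovery needs >= 2 models")
  ref_sasa <- sasa(reference, probe = probe, n_points = n_points)
  res <- sort(unique(reference$atoms$resno))
  res3 <- toupper(reference$atoms$resid[match(res, reference$atoms$resno)])

  eligible <- res3 %in% names(.chi_atoms)  # excludes ALA/GLY/non-standard
  ref_chi1 <- rep(NA_real_, length(res))
  ref_chi1[eligible] <- vapply(which(eligible), function(k) {
    .chi_angle(reference, res[k], .chi_atoms[[res3[k]]][[1]])
  }, numeric(1))
  eligible <- eligible & !is.na(ref_chi1)

  buried <- eligible & ref_sasa[as.character(res)] < sasa_cut
  n_buried <- sum(buried)

  detail <- data.frame(resno = res, resid = res3,
                       sasa = as.numeric(ref_sasa[as.character(res)]),
                       buried = buried, chi1_ref = ref_chi1,
                       chi1_sd = NA_real_, converged = FALSE,
                       chi1_model = NA_real_, recovered = NA,
                       all_chi = NA)

  for (k in which(buried)) {
    chis <- vapply(models, function(m) {
      .chi_angle(m, res[k], .chi_atoms[[res3[k]]][[1]])
    }, numeric(1))
    if (anyNA(chis)) next
    detail$chi1_sd[k] <- circular_sd(chis)
    if (detail$chi1_sd[k] < chi1_sd_cut) {
      detail$converged[k] <- TRUE
      detail$chi1_model[k] <- circular_mean(chis)
      detail$recovered[k] <-
        chi_well(detail$chi1_model[k]) == chi_well(ref_chi1[k])
      # all defined chi angles must land in the reference well
      quads <- .chi_atoms[[res3[k]]]
      ok <- TRUE
      for (q in quads) {
        rc <- .chi_angle(reference, res[k], q)
        if (is.na(rc)) next
        mc <- circular_mean(vapply(models, .chi_angle, numeric(1),
                                   resno = res[k], quad = q))
        if (is.na(mc) || chi_well(mc) != chi_well(rc)) { ok <- FALSE; break }
      }
      detail$all_chi[k] <- ok
    }
  }

  n_conv <- sum(detail$converged)
  n_rec <- sum(detail$recovered, na.rm = TRUE)
  n_all <- sum(detail$all_chi, na.rm = TRUE)
  stopifnot(n_rec <= n_conv, n_conv <= n_buried)
  list(
    n_buried = n_buried,
    n_converged_buried = n_conv,
    n_chi1_recovered = n_rec,
    frac_chi1 = if (n_conv) n_rec / n_conv else NA_real_,
    frac_all_chi = if (n_conv) n_all / n_conv else NA_real_,
    frac_all_chi_buried = if (n_buried) n_all / n_buried else NA_real_,
    residues = detail
  )
}
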