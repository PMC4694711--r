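# Model evaluation: contact PPV, RMSD / RMSD over secondary-structure
# elements, and restraint-satisfaction confusion statistics.

#' Positive predictive value of a contact set
#'
#' A predicted contact counts as a true positive when the C-beta/C-beta
#' distance (C-alpha for glycine) in the reference structure is at most
#' \code{cutoff}. Contacts whose residues are absent from the reference are
#' excluded from the denominator and reported via attributes.
#'
#' @param contacts a \code{contact_set}.
#' @param reference a \code{structure_model}.
#' @param cutoff contact distance cutoff (Å), default 8.
#' @return PPV in [0, 1], with attributes \code{n_true}, \code{n_evaluable},
#'   \code{n_excluded}.
#' @export
compute_ppv <- function(contacts, reference, cutoff = 8.0) {
  stopifnot(inherits(contacts, "contact_set"))
  rec <- contacts$records
  res <- unique(reference$atoms$resno)
  ok <- rec$i %in% res & rec$j %in% res
  n_excluded <- sum(!ok)
  rec <- rec[ok, , drop = FALSE]
  if (!nrow(rec)) stop("PPV undefined: no contact maps onto the reference")
  seq3 <- reference$atoms$resid[match(sort(res), reference$atoms$resno)]
  aa <- aa321(seq3)
  names(aa) <- sort(res)
  a1 <- contact_atom(aa[as.character(rec$i)])
  a2 <- contact_atom(aa[as.character(rec$j)])
  d <- sqrt(rowSums((atom_coords(reference, rec$i, a1) -
                       atom_coords(reference, rec$j, a2))^2))
  tp <- sum(d <= cutoff)
  structure(tp / nrow(rec), n_true = tp, n_evaluable = nrow(rec),
            n_excluded = n_excluded)
}

#' C-alpha RMSD after optimal superposition
#'
#' Kabsch-superposition RMSD over the C-alpha atoms of all residues present
#' in the reference (optionally restricted by \code{selection}); no outlier
#' trimming, so every model is judged on the same residues.
#'
#' @param model,reference \code{structure_model}s sharing residue numbering.
#' @param selection optional residue indices (or logical mask over the shared
#'   residue set) to restrict the superposition and RMSD.
#' @return RMSD in Å.
#' @export
rmsd <- function(model, reference, selection = NULL) {
  shared <- intersect(unique(reference$atoms$resno),
                      unique(model$atoms$resno))
  shared <- sort(shared)
  if (!is.null(selection)) {
    if (is.logical(selection)) selection <- shared[selection]
    shared <- intersect(shared, selection)
  }
  if (length(shared) < 3) stop("RMSD needs >= 3 shared C-alpha atoms")
  kabsch_rmsd(ca_matrix(model, shared), ca_matrix(reference, shared))
}

#' RMSD over secondary-structure elements
#'
#' C-alpha RMSD restricted to residues assigned helix (H) or strand (E) in an
#' externally supplied per-residue secondary-structure string for the
#' reference.
#'
#' @inheritParams rmsd
#' @param sse per-residue assignment (character vector over the reference
#'   residues; H and E count as structured).
#' @return RMSD in Å over the structured residues.
#' @export
rmsd_sse <- function(model, reference, sse) {
  res <- sort(unique(reference$atoms$resno))
  if (length(sse) != length(res)) {
    stop(sprintf("sse has %d labels but the reference has %d residues",
                 length(sse), length(res)))
  }
  sel <- res[toupper(sse) %in% c("H", "E")]
  if (!length(sel)) stop("no helix/strand residues in the assignment")
  rmsd(model, reference, selection = sel)
}

#' Restraint-satisfaction confusion statistics
#'
#' Partitions the restraints by whether the reference structure satisfies
#' them (atom-pair distance <= \code{cutoff}) and measures, averaged over the
#' models, the fraction of natively satisfied restraints that the models also
#' satisfy and the fraction of natively violated ("incorrect") restraints
#' that the models correctly violate.
#'
#' @param models list of \code{structure_model} (e.g. 10 lowest-energy).
#' @param reference the native \code{structure_model}.
#' @param restraints a \code{restraint_set}.
#' @param cutoff satisfaction cutoff (Å), default 8.
#' @return list with \code{frac_satisfied} (mean fraction of all restraints
#'   satisfied in the models), \code{frac_native_satisfied_also_satisfied},
#'   \code{frac_native_violated_also_violated}, and the group sizes
#'   \code{n_native_satisfied}, \code{n_native_violated}.
#' @export
restraint_confusion <- function(models, reference, restraints, cutoff = 8.0) {
  if (inherits(models, "structure_model")) models <- list(models)
  nat <- is_satisfied(reference, restraints, cutoff)
  sat <- vapply(models, is_satisfied, logical(nrow(restraints)),
                restraints = restraints, cutoff = cutoff)
  sat <- matrix(sat, nrow = nrow(restraints))
  frac_sat <- mean(colMeans(sat))
  frac_ss <- if (any(nat)) mean(colMeans(sat[nat, , drop = FALSE])) else NA_real_
  frac_vv <- if (any(!nat)) mean(colMeans(!sat[!nat, , drop = FALSE])) else NA_real_
  list(
    frac_satisfied = frac_sat,
    frac_native_satisfied_also_satisfied = frac_ss,
    frac_native_violated_also_violated = frac_vv,
    n_native_satisfied = sum(nat),
    n_native_violated = sum(!nat)
  )
}

#' Full evaluation report for a model set
#'
#' Convenience wrapper assembling the evaluation battery into one list:
#' contact PPV on the reference, RMSD / RMSD over secondary-structure
#' elements / TM-score of each model (plus their means), restraint
#' satisfaction statistics, and chi1 rotamer recovery of buried side chains.
#'
#' @param models list of low-energy \code{structure_model}s.
#' @param reference native \code{structure_model}.
#' @param contacts optional \code{contact_set} for PPV.
#' @param restraints optional \code{restraint_set} for satisfaction stats.
#' @param sse optional per-residue secondary-structure assignment.
#' @param sasa_cut,chi1_sd_cut rotamer-recovery thresholds (Å^2, degrees).
#' @param ... forwarded to [rotamer_recovery()] (e.g. \code{n_points}).
#' @return list of class \code{eval_report}.
#' @export
evaluate_models <- function(models, reference, contacts = NULL,
                            restraints = NULL, sse = NULL,
                            sasa_cut = 40, chi1_sd_cut = 10, ...) {
  if (inherits(models, "structure_model")) models <- list(models)
  per_model <- data.frame(
    model_id = vapply(models, function(m) m$id, ""),
    rmsd = vapply(models, rmsd, 0, reference = reference),
    tm_score = vapply(models, tm_score, 0, reference = reference)
  )
  if (!is.null(sse)) {
    per_model$rmsd_sse <- vapply(models, rmsd_sse, 0, reference = reference,
                                 sse = sse)
  }
  rep <- list(
    per_model = per_model,
    rmsd = mean(per_model$rmsd),
    tm_score = mean(per_model$tm_score),
    rmsd_sse = if (!is.null(sse)) mean(per_model$rmsd_sse) else NA_real_
  )
  if (!is.null(contacts)) rep$ppv <- as.numeric(compute_ppv(contacts, reference))
  if (!is.null(restraints)) {
    rep$satisfaction <- restraint_confusion(models, reference, restraints)
  }
  rep$rotamer <- rotamer_recovery(models, reference, sasa_cut = sasa_cut,
                                  chi1_sd_cut = chi1_sd_cut, ...)
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report over %d models:\n", nrow(x$per_model)))
  cat(sprintf("  mean RMSD     %.2f Å\n", x$rmsd))
  if (!is.na(x$rmsd_sse)) cat(sprintf("  mean RMSD_SSE %.2f Å\n", x$rmsd_sse))
  cat(sprintf("  mean TM-score %.3f\n", x$tm_score))
  if (!is.null(x$ppv)) cat(sprintf("  contact PPV   %.3f\n", x$ppv))
  if (!is.null(x$satisfaction)) {
    s <- x$satisfaction
    cat(sprintf("  restraints: %.0f%% of native-satisfied kept, %.0f%% of native-violated rejected\n",
                100 * s$frac_native_satisfied_also_satisfied,
                100 * s$frac_native_violated_also_violated))
  }
  r <- x$rotamer
  cat(sprintf("  rotamers: %d buried, %d converged, chi1 recovery %.2f\n",
              r$n_buried, r$n_converged_buried, r$frac_chi1))
  invisible(x)
}
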