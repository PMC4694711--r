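# Ensemble analysis: energy ranking, backbone convergence, success
# classification, and derivation of refinement-round restraints.

#' Select the n lowest-energy models
#'
#' @param models list of \code{structure_model}, each carrying an energy.
#' @param n how many to keep; if larger than the pool, the whole pool is
#'   returned with a warning.
#' @return models sorted by ascending energy (ties broken by model id),
#'   truncated to \code{n}.
#' @export
rank_models <- function(models, n = 10) {
  energies <- vapply(models, function(m) m$energy, numeric(1))
  if (anyNA(energies)) {
    stop("model(s) without energy: ",
         paste(vapply(models[is.na(energies)], function(m) m$id, ""), collapse = ", "))
  }
  ids <- vapply(models, function(m) m$id, character(1))
  ord <- order(energies, ids)
  if (n > length(models)) {
    warning(sprintf("requested %d models but pool has %d; returning all", n, length(models)))
    n <- length(models)
  }
  models[ord][seq_len(n)]
}

.shared_residues <- function(models) {
  sets <- lapply(models, function(m) unique(m$atoms$resno))
  shared <- Reduce(intersect, sets)
  if (!length(shared)) stop("models share no residues")
  sort(shared)
}

#' Per-residue backbone convergence of an ensemble
#'
#' Models are iteratively superposed (Kabsch, all shared C-alpha) onto the
#' evolving ensemble mean until the mean structure shifts by less than
#' \code{tol}. The coordinate variability of residue r is the RMSF of its
#' C-alpha about the ensemble mean position:
#' \deqn{v_r = \sqrt{\tfrac{1}{N}\sum_m \lVert x_{mr} - \bar x_r \rVert^2}}
#' A residue is converged when \eqn{v_r} is strictly below \code{threshold}
#' (2 Å by default).
#'
#' @param models list of >= 2 \code{structure_model} (typically the 30
#'   lowest-energy models of a folding run).
#' @param threshold convergence threshold on the variability (Å).
#' @param tol superposition fixed-point tolerance on the mean shift (Å).
#' @return an \code{ensemble_stats} object with \code{per_residue_variability}
#'   (named by residue), \code{converged_mask}, \code{fraction_converged},
#'   \code{n_models}, \code{residues} and \code{mean_ca} (the converged mean
#'   C-alpha coordinates).
#' @export
per_residue_convergence <- function(models, threshold = 2.0, tol = 1e-3) {
  if (length(models) < 2) stop("convergence analysis needs >= 2 models")
  res <- .shared_residues(models)
  mats <- lapply(models, ca_matrix, resno = res)
  mean_ca <- mats[[1]]
  repeat {
    mats <- lapply(mats, superpose, Q = mean_ca)
    new_mean <- Reduce(`+`, mats) / length(mats)
    shift <- sqrt(max(rowSums((new_mean - mean_ca)^2)))
    mean_ca <- new_mean
    if (shift < tol) break
  }
  dev2 <- vapply(mats, function(m) rowSums((m - mean_ca)^2),
                 numeric(length(res)))
  variability <- sqrt(rowMeans(matrix(dev2, nrow = length(res))))
  names(variability) <- res
  mask <- variability < threshold
  structure(
    list(
      n_models = length(models),
      residues = res,
      per_residue_variability = variability,
      converged_mask = mask,
      fraction_converged = mean(mask),
      threshold = threshold,
      mean_ca = mean_ca
    ),
    class = "ensemble_stats"
  )
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("ensemble_stats: %d models, %d residues", x$n_models,
              length(x$residues)))
  if (!is.null(x$fraction_converged)) {
    cat(sprintf(", %.1f%% converged (< %g Å)",
                100 * x$fraction_converged, x$threshold))
  }
  if (!is.null(x$pair_mean)) {
    cat(sprintf(", %d residue pairs", nrow(x$pairs)))
  }
  cat("\n")
  invisible(x)
}

#' Classify a prediction as successful or unsuccessful
#'
#' A prediction is regarded as unsuccessful when fewer than half of the
#' residues of the low-energy ensemble converged — the sampler found no
#' consistent low-energy state.
#'
#' @param stats output of [per_residue_convergence()].
#' @param min_fraction success requires \code{fraction_converged >=} this
#'   value (default 0.5; "less than half" reads as a strict inequality).
#' @return \code{"successful"} or \code{"unsuccessful"}.
#' @export
classify_success <- function(stats, min_fraction = 0.5) {
  if (stats$fraction_converged < min_fraction) "unsuccessful" else "successful"
}

#' Does the ensemble warrant a refinement round?
#'
#' @param stats output of [per_residue_convergence()].
#' @param threshold refinement triggers when the converged fraction is
#'   strictly below this value (default 0.9).
#' @return logical.
#' @export
needs_refinement <- function(stats, threshold = 0.9) {
  stats$fraction_converged < threshold
}

#' Inter-residue distance statistics across an ensemble
#'
#' For every residue pair (i < j) over the shared residue set, the mean and
#' population standard deviation of the chosen inter-atom distance across the
#' models.
#'
#' @param models list of >= 2 \code{structure_model}.
#' @param atom \code{"CA"} or \code{"CB"} (\code{"CB"} falls back to CA for
#'   glycine).
#' @return an \code{ensemble_stats} object with \code{pairs} (data.frame
#'   \code{i}, \code{j}, \code{mean}, \code{sd}) plus \code{n_models} and
#'   \code{residues}.
#' @export
pair_distance_stats <- function(models, atom = c("CA", "CB")) {
  atom <- match.arg(atom)
  if (length(models) < 2) stop("pair statistics need >= 2 models")
  res <- .shared_residues(models)
  coords <- lapply(models, function(m) {
    ats <- rep(atom, length(res))
    if (atom == "CB") {
      res3 <- m$atoms$resid[match(res, m$atoms$resno)]
      ats[toupper(res3) == "GLY"] <- "CA"
    }
    atom_coords(m, res, ats)
  })
  dvec <- vapply(coords, function(xy) as.vector(stats::dist(xy)),
                 numeric(length(res) * (length(res) - 1) / 2))
  dvec <- matrix(dvec, ncol = length(models))
  mu <- rowMeans(dvec)
  sdv <- sqrt(rowMeans(dvec^2) - mu^2)  # population SD
  sdv[sdv < 0 | is.na(sdv)] <- 0
  idx <- which(lower.tri(matrix(0, length(res), length(res))), arr.ind = TRUE)
  pairs <- data.frame(i = res[idx[, 2]], j = res[idx[, 1]],
                      mean = mu, sd = sdv)
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(
    list(n_models = length(models), residues = res, atom = atom, pairs = pairs),
    class = "ensemble_stats"
  )
}

#' Bounded restraints for converged residue pairs
#'
#' Re-establishes the converged core of a first folding round: every C-alpha
#' pair that is short-range (ensemble mean distance d <= \code{d_max}) and
#' converged (population SD strictly below \code{sd_max}) becomes a strict
#' bounded restraint with \code{lb = d - 1}, \code{ub = d + 1}, \code{sd = 1}.
#'
#' @param stats C-alpha pair statistics from [pair_distance_stats()].
#' @param d_max maximum mean distance (Å), default 8.
#' @param sd_max pair SD must be strictly below this (Å), default 1.
#' @return a \code{restraint_set} of bounded CA-CA restraints.
#' @export
derive_converged_restraints <- function(stats, d_max = 8.0, sd_max = 1.0) {
  p <- stats$pairs
  keep <- p$mean <= d_max & p$sd < sd_max
  p <- p[keep, , drop = FALSE]
  if (!nrow(p)) return(empty_restraint_set())
  new_restraint_set(data.frame(
    res1 = p$i, atom1 = "CA", res2 = p$j, atom2 = "CA",
    kind = "bounded", x0 = NA_real_, m = NA_real_,
    lb = p$mean - 1, ub = p$mean + 1, sd = 1.0, group = NA_integer_,
    stringsAsFactors = FALSE
  ))
}

#' Rescue low-rank contacts for the refinement round
#'
#' With first-round models in hand, lower-confidence contact predictions can
#' be admitted wherever they (a) touch an unconverged region — their own
#' ensemble distance SD exceeds \code{sd_min} — and (b) do not totally
#' disagree with the models (ensemble mean distance <= \code{d_max}).
#' Qualifying contacts not already used in the first round become wide
#' bounded restraints with bounds 1.5 / 8 Å.
#'
#' @param all_contacts full contact table ([parse_contacts()] output).
#' @param used the first-round \code{contact_set} (these pairs are excluded).
#' @param stats pair statistics from [pair_distance_stats()].
#' @param sd_min pair SD must exceed this (Å) to count as unconverged.
#' @param d_max maximum ensemble mean distance (Å).
#' @param sequence optional one-letter sequence; when given, restraint atoms
#'   are CB with CA for glycine, else CB throughout.
#' @param lb,ub wide bounds (Å), defaults 1.5 and 8.
#' @return a \code{restraint_set} of wide bounded restraints.
#' @export
derive_refinement_contacts <- function(all_contacts, used, stats,
                                       sd_min = 1.0, d_max = 8.0,
                                       sequence = NULL,
                                       lb = 1.5, ub = 8.0) {
  stopifnot(inherits(used, "contact_set"))
  used_key <- paste(used$records$i, used$records$j)
  cand <- all_contacts[!(paste(all_contacts$i, all_contacts$j) %in% used_key), ,
                       drop = FALSE]
  pk <- paste(stats$pairs$i, stats$pairs$j)
  hit <- match(paste(cand$i, cand$j), pk)
  ok <- !is.na(hit) &
    stats$pairs$sd[hit] > sd_min &
    stats$pairs$mean[hit] <= d_max
  cand <- cand[ok, , drop = FALSE]
  if (!nrow(cand)) return(empty_restraint_set())
  if (is.null(sequence)) {
    a1 <- rep("CB", nrow(cand)); a2 <- a1
  } else {
    aa <- .as_aa_vector(sequence)
    a1 <- contact_atom(aa[cand$i]); a2 <- contact_atom(aa[cand$j])
  }
  new_restraint_set(data.frame(
    res1 = cand$i, atom1 = a1, res2 = cand$j, atom2 = a2,
    kind = "bounded", x0 = NA_real_, m = NA_real_,
    lb = lb, ub = ub, sd = 1.0, group = NA_integer_,
    stringsAsFactors = FALSE
  ))
}

#' Combine restraints into random ambiguous groups
#'
#' Dilutes the impact of individual false positives: restraints are randomly
#' partitioned into ambiguity groups of \code{group_size} (the last group may
#' be smaller), scored downstream by their best-satisfied member. Several
#' independent groupings can be drawn, one per folding trajectory.
#'
#' @param restraints a \code{restraint_set}.
#' @param group_size members per group (>= 2).
#' @param seed integer seed; groupings are fully reproducible.
#' @param n_sets number of independent groupings.
#' @return list of \code{n_sets} restraint_sets, each a permutation-free copy
#'   of \code{restraints} with the \code{group} column filled.
#' @export
make_ambiguous <- function(restraints, group_size = 2, seed, n_sets = 1) {
  stopifnot(inherits(restraints, "restraint_set"))
  if (group_size < 2) stop("group_size must be >= 2")
  n <- nrow(restraints)
  if (n < group_size) {
    stop(sprintf("need at least %d restraints to form a group, have %d",
                 group_size, n))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(seq_len(n_sets), function(s) {
    perm <- sample.int(n)
    grp <- integer(n)
    grp[perm] <- (seq_len(n) - 1L) %/% group_size + 1L
    out <- restraints
    out$group <- grp
    out
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
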