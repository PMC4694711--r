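# Synthetic fixtures: toy folds with pseudo side chains, perturbed ensembles
# with planted convergence structure, and contact maps with controlled PPV.
# Every generator is a pure function of its spec and seed.

#' Specification for synthetic fixtures
#'
#' @param n_residues chain length.
#' @param fold \code{"helix"}, \code{"two_helix_bundle"} or
#'   \code{"sheet_pair"}.
#' @param noise_sd_converged per-atom Gaussian noise (Å) outside the diverged
#'   region.
#' @param noise_sd_diverged noise (Å) inside \code{diverged_region}.
#' @param diverged_region residue indices that receive the large noise.
#' @param contact_ppv fraction of true contacts in generated maps.
#' @param n_contacts contacts per generated map.
#' @param seed integer; fixes all randomness.
#' @return a \code{fixture_spec} list.
#' @export
fixture_spec <- function(n_residues = 60, fold = "two_helix_bundle",
                         noise_sd_converged = 0.5, noise_sd_diverged = 5.0,
                         diverged_region = integer(0), contact_ppv = 0.6,
                         n_contacts = 50, seed = 1L) {
  fold <- match.arg(fold, c("helix", "two_helix_bundle", "sheet_pair"))
  stopifnot(n_residues >= 10, contact_ppv >= 0, contact_ppv <= 1,
            all(diverged_region >= 1), all(diverged_region <= n_residues))
  structure(list(
    n_residues = as.integer(n_residues), fold = fold,
    noise_sd_converged = noise_sd_converged,
    noise_sd_diverged = noise_sd_diverged,
    diverged_region = as.integer(diverged_region),
    contact_ppv = contact_ppv, n_contacts = as.integer(n_contacts),
    seed = as.integer(seed)
  ), class = "fixture_spec")
}

.unit <- function(v) v / sqrt(sum(v^2))

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.ortho <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(.cross3(v, a))
}

# place atom D given A-B-C, bond |CD|, angle B-C-D and dihedral A-B-C-D (deg)
.place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- .unit(c - b)
  n <- .cross3(b - a, bc)
  if (sqrt(sum(n^2)) < 1e-8) n <- .ortho(bc) else n <- .unit(n)
  m <- .cross3(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
         bond * sin(ang) * sin(dih))  # sign matches dihedral_angle()
  c + bc * d[1] + m * d[2] + n * d[3]
}

# ideal CA traces -------------------------------------------------------------

.trace_helix <- function(n, origin = c(0, 0, 0), axis_z = TRUE, phase = 0,
                         reverse = FALSE) {
  rise <- 1.5
  turn <- 100 * pi / 180
  radius <- sqrt(3.8^2 - rise^2) / (2 * sin(turn / 2))  # exact 3.8 Å spacing
  k <- seq_len(n) - 1
  z <- k * rise
  if (reverse) z <- -z
  cbind(radius * cos(phase + k * turn),
        radius * sin(phase + k * turn),
        z) + matrix(origin, n, 3, byrow = TRUE)
}

.trace_strand <- function(n, origin = c(0, 0, 0), direction = 1) {
  dx <- sqrt(3.8^2 - 1.9^2)
  k <- seq_len(n) - 1
  cbind(origin[1] + direction * k * dx,
        origin[2] + 0.95 * (-1)^k,
        rep(origin[3], n))
}

# connect two anchor points with m CA positions spaced ~3.8 Å: a circular
# arc in the (chord, normal) plane whose arc length is 3.8 * (m + 1),
# sampled at equal arc steps so consecutive chords are uniform
.trace_loop <- function(from, to, m, step = 3.8) {
  if (m == 0) return(NULL)
  u <- .unit(to - from)
  p <- .ortho(u)
  chord <- sqrt(sum((to - from)^2))
  s <- step * (m + 1)
  if (chord >= s * 0.999) {  # anchors too far apart: straight interpolation
    return(outer(seq_len(m) / (m + 1), to - from) +
             matrix(from, m, 3, byrow = TRUE))
  }
  # subtended angle phi from arc length s and chord c: c/s = sin(phi/2)/(phi/2)
  phi <- stats::uniroot(function(x) sin(x / 2) / (x / 2) - chord / s,
                        c(1e-6, 2 * pi - 1e-4))$root
  R <- s / phi
  centre <- from + u * (chord / 2) - p * (R * cos(phi / 2))
  a0 <- atan2(sum((from - centre) * p), sum((from - centre) * u))
  a1 <- atan2(sum((to - centre) * p), sum((to - centre) * u))
  # sweep exactly phi from a0, in whichever direction ends at a1 (mod 2pi)
  dir <- if (abs((a0 + phi - a1) %% (2 * pi)) < 1e-6 ||
             abs((a0 + phi - a1) %% (2 * pi) - 2 * pi) < 1e-6) 1 else -1
  ang <- a0 + dir * phi * seq_len(m) / (m + 1)
  t(vapply(ang, function(a) centre + R * (cos(a) * u + sin(a) * p),
           numeric(3)))
}

# amino acids with a gamma heavy atom (chi1 defined), plus their gamma name
.gamma_atom <- vapply(.chi_atoms, function(q) q[[1]][4], character(1))

.default_sequence <- function(n) {
  pool <- names(.chi_atoms)
  aa <- pool[(seq_len(n) - 1L) %% length(pool) + 1L]
  aa[seq(5, n, by = 7)] <- "GLY"   # exercise the glycine CA rule
  aa[seq(3, n, by = 11)] <- "ALA"  # exercised as rotamer-excluded
  aa
}

#' Generate an idealised toy structure
#'
#' Builds a CA trace for the requested fold (3.8 Å spacing; helical geometry
#' for helix folds), adds pseudo backbone N and C atoms, a C-beta at
#' tetrahedral geometry and — for residues with a side chain — a single gamma
#' heavy atom placed at a planted chi1 rotamer well. The planted wells are
#' recorded as ground truth in \code{attr(model, "chi1_truth")}.
#'
#' @param spec a [fixture_spec()].
#' @param sequence optional three-letter residue names (default: a fixed
#'   rotation through the chi-bearing amino acids with periodic GLY/ALA).
#' @return a \code{structure_model}; attributes \code{chi1_truth} (named
#'   vector of planted chi1 angles, degrees) and \code{sequence}.
#' @export
make_structure <- function(spec, sequence = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_residues
  if (is.null(sequence)) sequence <- .default_sequence(n)
  stopifnot(length(sequence) == n)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  ca <- switch(spec$fold,
    helix = .trace_helix(n),
    two_helix_bundle = {
      n1 <- (n - 4L) %/% 2L
      n2 <- n - 4L - n1
      h1 <- .trace_helix(n1)
      h2 <- .trace_helix(n2, origin = c(8.5, 0, (n1 - 1) * 1.5),
                         phase = pi, reverse = TRUE)
      loop <- .trace_loop(h1[n1, ], h2[1, ], 4L)
      rbind(h1, loop, h2)
    },
    sheet_pair = {
      n1 <- (n - 3L) %/% 2L
      n2 <- n - 3L - n1
      s1 <- .trace_strand(n1)
      s2 <- .trace_strand(n2, origin = c(s1[n1, 1], 0, 4.9), direction = -1)
      loop <- .trace_loop(s1[n1, ], s2[1, ], 3L)
      rbind(s1, loop, s2)
    }
  )

  chi_truth <- rep(NA_real_, n)
  rows <- list()
  for (k in seq_len(n)) {
    u_prev <- if (k > 1) .unit(ca[k - 1, ] - ca[k, ]) else .unit(ca[k, ] - ca[k + 1, ])
    u_next <- if (k < n) .unit(ca[k + 1, ] - ca[k, ]) else .unit(ca[k, ] - ca[k - 1, ])
    p <- .cross3(u_prev, u_next)
    p <- if (sqrt(sum(p^2)) < 1e-6) .ortho(u_prev) else .unit(p)
    Npos <- ca[k, ] + 1.46 * .unit(u_prev + 0.35 * p)
    Cpos <- ca[k, ] + 1.52 * .unit(u_next - 0.35 * p)
    n1 <- .unit(Npos - ca[k, ]); n2 <- .unit(Cpos - ca[k, ])
    bis <- -(n1 + n2)
    bis <- if (sqrt(sum(bis^2)) < 1e-6) p else .unit(bis)
    perp <- .unit(.cross3(n1, n2))
    at <- data.frame(
      resno = k, resid = sequence[k],
      elety = c("N", "CA", "C"),
      x = c(Npos[1], ca[k, 1], Cpos[1]),
      y = c(Npos[2], ca[k, 2], Cpos[2]),
      z = c(Npos[3], ca[k, 3], Cpos[3]),
      stringsAsFactors = FALSE
    )
    if (sequence[k] != "GLY") {
      cb <- ca[k, ] + 1.53 * .unit(bis * cos(0.9556) + perp * sin(0.9556))
      at <- rbind(at, data.frame(resno = k, resid = sequence[k], elety = "CB",
                                 x = cb[1], y = cb[2], z = cb[3]))
      if (sequence[k] %in% names(.gamma_atom)) {
        chi <- unname(.well_centers[sample.int(3, 1)])
        g <- .place_atom(Npos, ca[k, ], cb, 1.52, 114, chi)
        at <- rbind(at, data.frame(resno = k, resid = sequence[k],
                                   elety = .gamma_atom[[sequence[k]]],
                                   x = g[1], y = g[2], z = g[3]))
        chi_truth[k] <- chi
      }
    }
    rows[[k]] <- at
  }
  model <- structure_model(do.call(rbind, rows),
                           id = sprintf("ref_%s_%d", spec$fold, n))
  names(chi_truth) <- seq_len(n)
  attr(model, "chi1_truth") <- chi_truth
  attr(model, "sequence") <- sequence
  model
}

#' Generate a perturbed model ensemble with planted convergence structure
#'
#' Each model is the reference plus isotropic per-atom Gaussian noise —
#' \code{noise_sd_converged} outside and \code{noise_sd_diverged} inside
#' \code{spec$diverged_region} — scaled by a per-model factor, followed by a
#' random rigid transform. Synthetic energies increase linearly with the
#' model's noise factor (plus small jitter), so energy ranking prefers
#' low-noise models.
#'
#' @param reference a \code{structure_model} (typically [make_structure()]).
#' @param spec a [fixture_spec()].
#' @param n_models ensemble size.
#' @return list with \code{models} (list of \code{structure_model} carrying
#'   energies), \code{scores} (data.frame \code{model_id}, \code{energy}),
#'   \code{converged_truth} (logical per residue: TRUE outside the diverged
#'   region) and \code{noise_scale} (per-model factor).
#' @export
make_ensemble <- function(reference, spec, n_models = 30) {
  stopifnot(inherits(spec, "fixture_spec"), n_models >= 2)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 1L)

  n <- n_residues(reference)
  sd_res <- rep(spec$noise_sd_converged, n)
  sd_res[spec$diverged_region] <- spec$noise_sd_diverged
  scale <- sample(seq(0.6, 1.4, length.out = n_models))

  models <- vector("list", n_models)
  energy <- numeric(n_models)
  for (m in seq_len(n_models)) {
    at <- reference$atoms
    sd_atom <- sd_res[at$resno] * scale[m]
    at$x <- at$x + stats::rnorm(nrow(at), 0, sd_atom)
    at$y <- at$y + stats::rnorm(nrow(at), 0, sd_atom)
    at$z <- at$z + stats::rnorm(nrow(at), 0, sd_atom)
    energy[m] <- -100 + 40 * scale[m] + stats::rnorm(1, 0, 0.5)
    id <- sprintf("model_%03d", m)
    mod <- structure_model(at, id = id, energy = energy[m])
    models[[m]] <- transform_model(mod, R = random_rotation(),
                                   t = stats::runif(3, -20, 20))
  }
  list(
    models = models,
    scores = data.frame(model_id = vapply(models, function(x) x$id, ""),
                        energy = energy, stringsAsFactors = FALSE),
    converged_truth = !(seq_len(n) %in% spec$diverged_region),
    noise_scale = scale
  )
}

#' Generate a contact map with controlled accuracy
#'
#' Samples \code{round(ppv * n_contacts)} true pairs (reference C-beta
#' distance <= 8 Å, C-alpha for glycine, sequence separation >= 5) and fills
#' the remainder with false pairs (distance > 8 Å). Confidence scores are
#' drawn so that true pairs rank higher on average.
#'
#' @param reference a \code{structure_model}.
#' @param n_contacts map size.
#' @param ppv target fraction of true contacts.
#' @param seed integer seed.
#' @param min_separation sequence-separation floor, default 5.
#' @return list with \code{records} (data.frame \code{i}, \code{j},
#'   \code{score}) and \code{truth} (logical, aligned with records).
#' @export
make_contact_map <- function(reference, n_contacts, ppv, seed,
                             min_separation = 5) {
  stopifnot(ppv >= 0, ppv <= 1, n_contacts >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  res <- sort(unique(reference$atoms$resno))
  res3 <- reference$atoms$resid[match(res, reference$atoms$resno)]
  ats <- ifelse(toupper(res3) == "GLY", "CA", "CB")
  xyz <- atom_coords(reference, res, ats)
  dmat <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(dmat), arr.ind = TRUE)
  sep_ok <- abs(res[idx[, 1]] - res[idx[, 2]]) >= min_separation
  idx <- idx[sep_ok, , drop = FALSE]
  d <- dmat[idx]
  true_pool <- which(d <= 8)
  false_pool <- which(d > 8)

  n_true <- round(ppv * n_contacts)
  n_false <- n_contacts - n_true
  if (length(true_pool) < n_true) {
    stop(sprintf("reference has only %d true contacts; %d required (deficit %d)",
                 length(true_pool), n_true, n_true - length(true_pool)))
  }
  if (length(false_pool) < n_false) {
    stop(sprintf("reference has only %d non-contact pairs; %d required",
                 length(false_pool), n_false))
  }
  pick_t <- sample(true_pool, n_true)
  pick_f <- sample(false_pool, n_false)
  sel <- c(pick_t, pick_f)
  truth <- rep(c(TRUE, FALSE), c(n_true, n_false))
  score <- c(stats::rnorm(n_true, 2.0, 0.5), stats::rnorm(n_false, 1.0, 0.5))

  records <- data.frame(
    i = pmin(res[idx[sel, 1]], res[idx[sel, 2]]),
    j = pmax(res[idx[sel, 1]], res[idx[sel, 2]]),
    score = score,
    res_i = NA_character_, res_j = NA_character_,
    stringsAsFactors = FALSE
  )
  ord <- order(-records$score)
  list(records = records[ord, , drop = FALSE], truth = truth[ord])
}
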