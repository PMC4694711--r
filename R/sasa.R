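# Shrake-Rupley solvent-accessible surface area.

# van der Waals radii (Å) by element; frozen so results are reproducible.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
.vdw_default <- 1.70

.atom_element <- function(elety) {
  # first alphabetic character of the atom name (PDB heavy-atom convention)
  substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", elety)), 1, 1)
}

# deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
.sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue side-chain solvent-accessible surface area
#'
#' Shrake-Rupley sphere sampling: each atom is covered with a deterministic
#' quasi-uniform lattice of \code{n_points} test points at radius
#' \code{r_vdw + probe}; a point is accessible when it lies outside the
#' probe-expanded sphere of every other atom. The per-atom SASA is the
#' accessible fraction times the sphere area, and the per-residue value sums
#' over side-chain heavy atoms (everything except the backbone atoms N, CA,
#' C, O, OXT). Glycine, having no side-chain heavy atoms, reports 0.
#'
#' @param model a \code{structure_model} with heavy-atom coordinates.
#' @param probe probe radius (Å), default 1.4 (water).
#' @param n_points test points per atom, default 960.
#' @return named numeric vector: side-chain SASA (Å^2) per residue index.
#' @export
sasa <- function(model, probe = 1.4, n_points = 960) {
  at <- model$atoms
  heavy <- .atom_element(at$elety) != "H"
  at <- at[heavy, , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  elem <- .atom_element(at$elety)
  rad <- unname(.vdw_radii[elem])
  rad[is.na(rad)] <- .vdw_default
  rext <- rad + probe
  n_at <- nrow(at)
  pts <- .sphere_points(n_points)

  area <- numeric(n_at)
  for (a in seq_len(n_at)) {
    # neighbours that could occlude any test point of atom a
    dvec <- xyz[-a, , drop = FALSE]
    dd <- sqrt(rowSums(sweep(dvec, 2, xyz[a, ])^2))
    nb <- which(dd < rext[a] + rext[-a])
    test <- sweep(pts * rext[a], 2, xyz[a, ], `+`)
    if (length(nb)) {
      nb_idx <- seq_len(n_at)[-a][nb]
      acc <- rep(TRUE, n_points)
      for (b in nb_idx) {
        d2 <- rowSums(sweep(test, 2, xyz[b, ])^2)
        acc <- acc & d2 > rext[b]^2
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else {
      frac <- 1
    }
    area[a] <- frac * 4 * pi * rext[a]^2
  }

  backbone <- at$elety %in% c("N", "CA", "C", "O", "OXT")
  res <- sort(unique(model$atoms$resno))
  out <- vapply(res, function(r) {
    sum(area[at$resno == r & !backbone])
  }, numeric(1))
  names(out) <- res
  out
}
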