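# TM-score: length-normalised global fold similarity.

#' TM-score length normalisation constant
#'
#' \deqn{d_0(L) = 1.24 (L - 15)^{1/3} - 1.8}
#' clamped below at 0.5 Å (the conventional floor for very short chains).
#'
#' @param L_ref reference length (residues).
#' @return d0 in Å.
#' @export
tm_d0 <- function(L_ref) {
  d0 <- 1.24 * (pmax(L_ref - 15, 0))^(1 / 3) - 1.8
  pmax(d0, 0.5)
}

.tm_of_fit <- function(X, Y, d0, L_ref) {
  d2 <- rowSums((X - Y)^2)
  sum(1 / (1 + d2 / d0^2)) / L_ref
}

#' TM-score of a model against a reference
#'
#' \deqn{TM = \max \frac{1}{L_{ref}} \sum_i \frac{1}{1 + (d_i/d_0)^2}}
#' maximised over superpositions. Model and reference are assumed to share a
#' residue numbering (no alignment search); the maximisation uses the
#' standard fragment-seeding heuristic: seed superpositions from windows of
#' several lengths, then iteratively refit on the residues currently within a
#' distance cutoff until the selection reaches a fixed point, keeping the
#' best score seen. The full-length Kabsch fit is always among the seeds, so
#' the result is bounded below by the plain-superposition score. Normalised
#' by the number of reference residues.
#'
#' @param model,reference \code{structure_model}s with common residue indices.
#' @return TM-score in (0, 1]; 1 for identical structures.
#' @export
tm_score <- function(model, reference) {
  res_ref <- sort(unique(reference$atoms$resno))
  shared <- sort(intersect(res_ref, unique(model$atoms$resno)))
  if (length(shared) < 3) stop("TM-score needs >= 3 shared residues")
  L_ref <- length(res_ref)
  d0 <- tm_d0(L_ref)
  X <- ca_matrix(model, shared)
  Y <- ca_matrix(reference, shared)
  n <- nrow(X)
  d_cut <- max(d0, 4.5)

  best <- 0
  try_fit <- function(sel) {
    # iterative inclusion: refit on sel, reselect by distance, to fixed point
    for (iter in 1:30) {
      if (length(sel) < 3) break
      fit <- kabsch(X[sel, , drop = FALSE], Y[sel, , drop = FALSE])
      Xf <- fit$transform(X)
      best <<- max(best, .tm_of_fit(Xf, Y, d0, L_ref))
      d <- sqrt(rowSums((Xf - Y)^2))
      new_sel <- which(d < d_cut)
      if (length(new_sel) < 3) new_sel <- order(d)[1:4]
      if (length(new_sel) == length(sel) && all(new_sel == sel)) break
      sel <- new_sel
    }
  }

  try_fit(seq_len(n))  # full-length Kabsch seed
  for (l in unique(pmax(4, c(n, n %/% 2, n %/% 4)))) {
    step <- max(1, l %/% 2)
    starts <- unique(c(seq(1, n - l + 1, by = step), n - l + 1))
    for (s in starts) try_fit(s:(s + l - 1))
  }
  min(best, 1)
}
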