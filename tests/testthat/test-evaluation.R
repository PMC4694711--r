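test_that("PPV counts true contacts against the reference distances", {
  ref <- bundle_ref()
  # a map built from true contacts only
  cm1 <- make_contact_map(ref, 40, 1.0, seed = 2)
  sel1 <- suppressWarnings(select_top_contacts(cm1$records, 60))
  expect_equal(as.numeric(compute_ppv(sel1, ref)), 1.0)
  # planted 30/50 accuracy is recovered exactly
  cm2 <- make_contact_map(ref, 50, 0.6, seed = 2)
  sel2 <- suppressWarnings(select_top_contacts(cm2$records, 60))
  expect_equal(as.numeric(compute_ppv(sel2, ref)), 0.60)

  # oracle recount on random maps
  for (s in 1:10) {
    cm <- make_contact_map(ref, 30, runif(1, 0.2, 0.9), seed = s)
    sel <- suppressWarnings(select_top_contacts(cm$records, 60))
    got <- compute_ppv(sel, ref)
    seqs <- model_sequence(ref)
    d <- vapply(seq_len(nrow(sel$records)), function(k) {
      i <- sel$records$i[k]; j <- sel$records$j[k]
      a1 <- if (seqs[i] == "G") "CA" else "CB"
      a2 <- if (seqs[j] == "G") "CA" else "CB"
      sqrt(sum((atom_coords(ref, i, a1) - atom_coords(ref, j, a2))^2))
    }, 0)
    expect_equal(as.numeric(got), mean(d <= 8))
  }
})

test_that("contacts outside the reference are excluded from the denominator", {
  ref <- bundle_ref()
  rec <- data.frame(i = c(1, 2, 70), j = c(10, 20, 80), score = 3:1)
  sel <- suppressWarnings(select_top_contacts(rec, 90))
  ppv <- compute_ppv(sel, ref)
  expect_equal(attr(ppv, "n_evaluable"), 2)
  expect_equal(attr(ppv, "n_excluded"), 1)
  none <- suppressWarnings(select_top_contacts(
    data.frame(i = 70, j = 80, score = 1), 90))
  expect_error(compute_ppv(none, ref), "undefined")
})

test_that("RMSD is zero on identity and under rigid motion", {
  ref <- bundle_ref()
  expect_equal(rmsd(ref, ref), 0, tolerance = 1e-9)
  set.seed(5)
  moved <- transform_model(ref, evrestraints:::random_rotation(),
                           runif(3, -40, 40))
  expect_lt(rmsd(moved, ref), 1e-9)
  expect_lt(abs(tm_score(moved, ref) - 1), 1e-9)
})

test_that("RMSD matches a closed-form toy computation", {
  # 4 points; model = reference with one point displaced; optimal fit found
  # by a brute-force rotation grid around the Kabsch solution
  P <- matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0, 0, 0, 10), ncol = 3, byrow = TRUE)
  Q <- P; Q[4, 3] <- 12
  m <- structure_model(data.frame(resno = 1:4, resid = "ALA", elety = "CA",
                                  x = P[, 1], y = P[, 2], z = P[, 3]), "m")
  r <- structure_model(data.frame(resno = 1:4, resid = "ALA", elety = "CA",
                                  x = Q[, 1], y = Q[, 2], z = Q[, 3]), "r")
  ours <- rmsd(m, r)
  # brute-force grid over rotations (0.1 degree around z is irrelevant here;
  # scan all three Euler axes coarsely then refine around the best)
  grid_rmsd <- function(ax_range, ay_range, az_range) {
    best <- c(Inf, 0, 0, 0)
    cP <- sweep(P, 2, colMeans(P)); cQ <- sweep(Q, 2, colMeans(Q))
    for (ax in ax_range) for (ay in ay_range) for (az in az_range) {
      Rx <- matrix(c(1, 0, 0, 0, cos(ax), -sin(ax), 0, sin(ax), cos(ax)), 3, byrow = TRUE)
      Ry <- matrix(c(cos(ay), 0, sin(ay), 0, 1, 0, -sin(ay), 0, cos(ay)), 3, byrow = TRUE)
      Rz <- matrix(c(cos(az), -sin(az), 0, sin(az), cos(az), 0, 0, 0, 1), 3, byrow = TRUE)
      v <- sqrt(mean(rowSums((cP %*% t(Rx %*% Ry %*% Rz) - cQ)^2)))
      if (v < best[1]) best <- c(v, ax, ay, az)
    }
    best
  }
  coarse <- seq(-0.3, 0.3, by = 0.02)
  b <- grid_rmsd(coarse, coarse, coarse)
  fine <- function(c0) seq(c0 - 0.02, c0 + 0.02, by = 0.1 * pi / 180)
  oracle <- grid_rmsd(fine(b[2]), fine(b[3]), fine(b[4]))[1]
  expect_lte(ours, oracle + 1e-9)           # Kabsch is optimal
  expect_equal(ours, oracle, tolerance = 1e-3)
  expect_error(rmsd(m, r, selection = 1:2), ">= 3")
})

test_that("secondary-structure RMSD restricts to H/E residues", {
  spec <- fixture_spec(40, "helix", seed = 3)
  ref <- make_structure(spec)
  # noise only on the second half ("loop"); helix labels on the first half
  noisy <- ref
  set.seed(8)
  idx <- noisy$atoms$resno > 20
  noisy$atoms$x[idx] <- noisy$atoms$x[idx] + rnorm(sum(idx), 0, 3)
  noisy$id <- "noisy"
  sse <- c(rep("H", 20), rep("C", 20))
  expect_lt(rmsd_sse(noisy, ref, sse), rmsd(noisy, ref))
  expect_equal(rmsd_sse(noisy, ref, rep("H", 40)), rmsd(noisy, ref))
  expect_error(rmsd_sse(noisy, ref, rep("C", 40)), "no helix/strand")
  expect_error(rmsd_sse(noisy, ref, "H"), "labels")
})

test_that("the TM-score normalisation constant follows the d0 formula", {
  expect_equal(tm_d0(117), 1.24 * 102^(1 / 3) - 1.8, tolerance = 1e-12)
  expect_equal(tm_d0(117), 3.9937, tolerance = 1e-4)
  expect_equal(tm_d0(10), 0.5)  # clamped floor for short chains
})

test_that("the TM heuristic dominates random superpositions and Kabsch", {
  spec <- fixture_spec(60, "two_helix_bundle", seed = 13,
                       diverged_region = 1:25, noise_sd_diverged = 6)
  ref <- make_structure(spec)
  ens <- make_ensemble(ref, spec, n_models = 2)
  model <- ens$models[[1]]
  tm <- tm_score(model, ref)
  X <- ca_matrix(model); Y <- ca_matrix(ref)
  d0 <- tm_d0(60)
  score_of <- function(Xr) sum(1 / (1 + rowSums((Xr - Y)^2) / d0^2)) / 60
  # plain Kabsch superposition never beats the heuristic
  expect_gte(tm + 1e-12, score_of(superpose(X, Y)))
  # nor do 2000 random rigid placements
  set.seed(99)
  cX <- sweep(X, 2, colMeans(X)); cY <- colMeans(Y)
  rand_best <- max(vapply(1:2000, function(k) {
    score_of(sweep(cX %*% t(evrestraints:::random_rotation()), 2,
                   cY + runif(3, -1, 1), `+`))
  }, 0))
  expect_gte(tm, rand_best)
  expect_true(tm > 0 && tm <= 1)
})

test_that("restraint confusion reproduces a planted truth table", {
  ref <- bundle_ref()
  cm <- make_contact_map(ref, 40, 0.5, seed = 17)
  sel <- suppressWarnings(select_top_contacts(cm$records, 60))
  rst <- contacts_to_restraints(sel, model_sequence(ref))
  # models identical to the reference agree perfectly
  conf <- restraint_confusion(list(ref, ref), ref, rst)
  expect_equal(conf$frac_native_satisfied_also_satisfied, 1.0)
  expect_equal(conf$frac_native_violated_also_violated, 1.0)
  expect_equal(conf$n_native_satisfied + conf$n_native_violated, nrow(rst))

  # planted confusion: a noisy model recounted by brute force
  spec <- split_spec()
  ens <- make_ensemble(ref, spec, n_models = 3)
  conf2 <- restraint_confusion(ens$models, ref, rst)
  nat <- is_satisfied(ref, rst)
  sat <- vapply(ens$models, is_satisfied, logical(nrow(rst)), restraints = rst)
  expect_equal(conf2$frac_native_satisfied_also_satisfied,
               mean(colMeans(sat[nat, ])))
  expect_equal(conf2$frac_native_violated_also_violated,
               mean(colMeans(!sat[!nat, ])))
  # permutation invariance
  perm <- sample(nrow(rst))
  rp <- rst[perm, ]; class(rp) <- class(rst)
  conf3 <- restraint_confusion(ens$models, ref, rp)
  expect_equal(conf3$frac_native_satisfied_also_satisfied,
               conf2$frac_native_satisfied_also_satisfied)
})
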