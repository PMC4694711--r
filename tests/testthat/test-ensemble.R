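toy_models <- function(energies, ids = NULL) {
  lapply(seq_along(energies), function(k) {
    at <- data.frame(resno = 1:3, resid = "ALA", elety = "CA",
                     x = c(0, 3.8, 7.6), y = 0, z = 0)
    structure_model(at, id = if (is.null(ids)) sprintf("m%02d", k) else ids[k],
                    energy = energies[k])
  })
}

test_that("energy ranking keeps the n lowest and matches a full sort", {
  m <- toy_models(c(3, 1, 2))
  top2 <- rank_models(m, 2)
  expect_equal(vapply(top2, function(x) x$energy, 0), c(1, 2))
  expect_warning(all3 <- rank_models(m, 10), "returning all")
  expect_equal(length(all3), 3)
  expect_error(rank_models(toy_models(c(1, NA)), 1), "without energy")

  set.seed(3)
  for (k in 1:20) {
    e <- round(rnorm(40), 2)
    got <- vapply(rank_models(toy_models(e), 10), function(x) x$energy, 0)
    expect_equal(got, sort(e)[1:10])  # brute-force oracle
  }
  # deterministic tie-break by id
  tied <- toy_models(c(1, 1, 1), ids = c("c", "a", "b"))
  expect_equal(vapply(rank_models(tied, 2), function(x) x$id, ""), c("a", "b"))
})

test_that("identical and rigidly moved copies have zero variability", {
  ref <- bundle_ref()
  copies <- lapply(1:5, function(k) { m <- ref; m$id <- paste0("c", k); m })
  st <- per_residue_convergence(copies)
  expect_true(all(st$per_residue_variability < 1e-9))
  expect_equal(st$fraction_converged, 1)

  set.seed(9)
  moved <- lapply(copies, function(m) {
    transform_model(m, R = evrestraints:::random_rotation(),
                    t = runif(3, -30, 30))
  })
  st2 <- per_residue_convergence(moved)
  expect_true(all(st2$per_residue_variability < 1e-6))
  expect_error(per_residue_convergence(copies[1]), ">= 2 models")
})

test_that("convergence is invariant under a global rigid motion", {
  ens <- split_ensemble()
  st <- per_residue_convergence(ens$models)
  set.seed(21)
  R <- evrestraints:::random_rotation(); tr <- runif(3, -10, 10)
  moved <- lapply(ens$models, transform_model, R = R, t = tr)
  st2 <- per_residue_convergence(moved)
  expect_equal(st$per_residue_variability, st2$per_residue_variability,
               tolerance = 1e-6)
})

test_that("bimodal-noise ensembles recover the planted partition", {
  ens <- split_ensemble()
  st <- per_residue_convergence(ens$models, threshold = 2.0)
  agreement <- mean(st$converged_mask == ens$converged_truth)
  expect_gte(agreement, 0.95)
})

test_that("raising the threshold never lowers the converged fraction", {
  ens <- split_ensemble()
  fr <- vapply(c(0.5, 1, 2, 4, 8), function(th) {
    per_residue_convergence(ens$models, threshold = th)$fraction_converged
  }, 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("success and refinement gates use strict inequalities", {
  expect_equal(classify_success(stats_with_fraction(0.49)), "unsuccessful")
  expect_equal(classify_success(stats_with_fraction(0.50)), "successful")
  expect_equal(classify_success(stats_with_fraction(1.0)), "successful")
  expect_true(needs_refinement(stats_with_fraction(0.89)))
  expect_false(needs_refinement(stats_with_fraction(0.90)))
  expect_false(needs_refinement(stats_with_fraction(0.95)))
})

test_that("pair distance statistics use the population SD", {
  # two models, one pair at 4 and 6 Å
  m1 <- structure_model(data.frame(resno = 1:2, resid = "ALA", elety = "CA",
                                   x = c(0, 4), y = 0, z = 0), "a", -1)
  m2 <- structure_model(data.frame(resno = 1:2, resid = "ALA", elety = "CA",
                                   x = c(0, 6), y = 0, z = 0), "b", -2)
  st <- pair_distance_stats(list(m1, m2))
  expect_equal(st$pairs$mean, 5)
  expect_equal(st$pairs$sd, 1)  # population, not sample, SD

  # identical models: all SDs zero
  st0 <- pair_distance_stats(list(m1, m1))
  expect_equal(st0$pairs$sd, 0)

  # random ensembles match a brute-force double loop
  ens <- split_ensemble()
  st <- pair_distance_stats(ens$models[1:5], atom = "CA")
  idx <- sample(nrow(st$pairs), 40)
  for (k in idx) {
    i <- st$pairs$i[k]; j <- st$pairs$j[k]
    d <- vapply(ens$models[1:5], function(m) {
      sqrt(sum((ca_matrix(m, i) - ca_matrix(m, j))^2))
    }, 0)
    expect_equal(st$pairs$mean[k], mean(d), tolerance = 1e-9)
    expect_equal(st$pairs$sd[k], sqrt(mean((d - mean(d))^2)), tolerance = 1e-9)
  }
})

test_that("converged-pair restraints apply the distance and SD filters", {
  st <- structure(list(pairs = data.frame(
    i = c(1, 2, 3), j = c(11, 12, 13),
    mean = c(6.0, 9.0, 6.0), sd = c(0.5, 0.2, 1.2))), class = "ensemble_stats")
  rst <- derive_converged_restraints(st)
  expect_equal(nrow(rst), 1)        # mean 9 excluded; sd 1.2 excluded
  expect_equal(rst$lb, 5.0)
  expect_equal(rst$ub, 7.0)
  expect_equal(rst$sd, 1.0)
  expect_equal(rst$atom1, "CA")
  expect_equal(rst$kind, "bounded")
  # exact SD boundary is excluded (strictly below 1 Å)
  st$pairs$sd[3] <- 1.0
  expect_equal(nrow(derive_converged_restraints(st)), 1)
})

test_that("converged-pair derivation matches a brute-force filter", {
  ens <- split_ensemble()
  low <- rank_models(ens$models, 30)
  st <- pair_distance_stats(low, atom = "CA")
  rst <- derive_converged_restraints(st)
  oracle <- st$pairs[st$pairs$mean <= 8 & st$pairs$sd < 1, ]
  expect_equal(nrow(rst), nrow(oracle))
  expect_equal(rst$res1, oracle$i)
  expect_equal(rst$lb, oracle$mean - 1)
  expect_equal(rst$ub - rst$lb, rep(2, nrow(rst)))
  expect_true(all(rst$res1 %in% 1:60 & rst$res2 %in% 1:60))
})

test_that("low-rank contact rescue keeps unconverged short-range pairs only", {
  st <- structure(list(pairs = data.frame(
    i = c(1, 2, 3), j = c(11, 12, 13),
    mean = c(7.0, 12.0, 7.0), sd = c(2.0, 2.0, 2.0))), class = "ensemble_stats")
  all_rec <- data.frame(i = c(1, 2, 3), j = c(11, 12, 13),
                        score = c(0.3, 0.2, 0.1))
  used <- suppressWarnings(select_top_contacts(
    data.frame(i = 3, j = 13, score = 0.1), 20))
  rst <- derive_refinement_contacts(all_rec, used, st)
  # (2,12) fails d <= 8; (3,13) already used; only (1,11) survives
  expect_equal(nrow(rst), 1)
  expect_equal(c(rst$res1, rst$res2), c(1, 11))
  expect_equal(c(rst$lb, rst$ub), c(1.5, 8.0))
  expect_equal(rst$kind, "bounded")
  # glycine-aware atom naming when a sequence is supplied
  rst2 <- derive_refinement_contacts(all_rec, used, st,
                                     sequence = c("G", rep("L", 19)))
  expect_equal(rst2$atom1, "CA")
  expect_equal(rst2$atom2, "CB")
})

test_that("ambiguous grouping is a seeded uniform partition", {
  rst <- derive_converged_restraints(structure(list(pairs = data.frame(
    i = 1:6, j = 11:16, mean = 6, sd = 0.1)), class = "ensemble_stats"))
  s1 <- make_ambiguous(rst, group_size = 2, seed = 42, n_sets = 3)
  s2 <- make_ambiguous(rst, group_size = 2, seed = 42, n_sets = 3)
  expect_identical(s1, s2)  # fully reproducible
  for (set in s1) {
    expect_true(all(table(set$group) == 2))       # partition into pairs
    expect_equal(sort(unique(set$group)), 1:3)
  }
  # remainder group may be smaller
  rst5 <- rst[1:5, ]; class(rst5) <- class(rst)
  s5 <- make_ambiguous(rst5, group_size = 2, seed = 1)[[1]]
  expect_equal(sort(as.vector(table(s5$group))), c(1, 2, 2))
  expect_error(make_ambiguous(rst[1, ], group_size = 2, seed = 1), "at least")

  # uniformity over the 15 perfect matchings of 6 elements
  draws <- make_ambiguous(rst, group_size = 2, seed = 7, n_sets = 1000)
  canon <- vapply(draws, function(set) {
    paste(sort(tapply(seq_len(6), set$group, paste, collapse = "-")),
          collapse = "|")
  }, "")
  counts <- table(canon)
  expect_equal(length(counts), 15)
  p <- suppressWarnings(chisq.test(as.vector(counts),
                                   p = rep(1 / 15, 15))$p.value)
  expect_gt(p, 0.01)
})
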