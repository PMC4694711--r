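test_that("sigmoid potential matches its closed form", {
  expect_equal(sigmoid_score(8.0, 8.0, 1.0), 0.0)
  expect_equal(sigmoid_score(10.0, 8.0, 1.0), 1 / (1 + exp(-2)) - 0.5,
               tolerance = 1e-12)
  expect_equal(sigmoid_score(10.0), 0.38079708, tolerance = 1e-7)
  # bonus floor at short distance
  expect_equal(sigmoid_score(0), -0.5, tolerance = 1e-3)
  expect_gt(sigmoid_score(1e-9), -0.5)
})

test_that("sigmoid is monotone, bounded and antisymmetric about x0", {
  x <- seq(0, 30, by = 0.01)
  y <- sigmoid_score(x)
  expect_true(all(diff(y) > 0))
  expect_true(all(y > -0.5 & y < 0.5))
  d <- runif(200, 0, 10)
  expect_equal(sigmoid_score(8 + d), -sigmoid_score(8 - d), tolerance = 1e-12)
  # plateau: the derivative vanishes at large x (violations exert no force)
  eps <- 1e-4
  slope <- (sigmoid_score(25 + eps) - sigmoid_score(25 - eps)) / (2 * eps)
  expect_lt(slope, 1e-6)
  expect_error(sigmoid_score(5, 8, 0), "m must be")
})

test_that("bounded potential: flat bottom, quadratic walls, linear tail", {
  lb <- 5; ub <- 7; sd <- 1
  xs <- runif(100, lb, ub)
  expect_true(all(bounded_score(xs, lb, ub, sd) == 0))
  expect_equal(bounded_score(lb - 1, lb, ub, sd), 1.0)
  expect_equal(bounded_score(lb - 0.3, lb, ub, sd), 0.09, tolerance = 1e-12)
  # both branches agree at the quadratic/linear crossover ub + 0.5*sd
  expect_equal(bounded_score(ub + 0.5, lb, ub, 1), 0.25)
  # continuity at every breakpoint
  for (b in c(lb, ub, ub + 0.5 * sd)) {
    expect_equal(bounded_score(b - 1e-6, lb, ub, sd),
                 bounded_score(b + 1e-6, lb, ub, sd), tolerance = 1e-5)
  }
  # linear tail with slope 1/sd
  for (sdv in c(0.5, 1, 2)) {
    x1 <- ub + 0.5 * sdv + 1; x2 <- x1 + 3
    slope <- (bounded_score(x2, lb, ub, sdv) - bounded_score(x1, lb, ub, sdv)) /
      (x2 - x1)
    expect_equal(slope, 1 / sdv, tolerance = 1e-12)
  }
  expect_true(all(bounded_score(seq(0, 20, 0.1), lb, ub, sd) >= 0))
  expect_error(bounded_score(5, 7, 5), "lb < ub")
  expect_error(bounded_score(5, 3, 7, sd = 0), "sd > 0")
})

test_that("restraint scores equal potentials of measured distances", {
  # two residues placed 5 apart, two more 20 apart
  at <- data.frame(
    resno = c(1, 1, 2, 2, 3, 3, 4, 4),
    resid = "LEU",
    elety = rep(c("CA", "CB"), 4),
    x = c(0, 0, 5, 5, 0, 0, 20, 20),
    y = c(0, 1, 0, 1, 5, 6, 5, 6),
    z = 0
  )
  m <- structure_model(at, id = "toy")
  rec <- data.frame(i = c(1, 3), j = c(2, 4), score = c(2, 1))
  sel <- suppressWarnings(select_top_contacts(rec, 10, min_separation = 1))
  rst <- contacts_to_restraints(sel, c("L", "L", "L", "L"))
  sc <- restraint_score(m, rst)
  expect_equal(sc$distance, c(5, 20))
  expect_equal(sc$score, sigmoid_score(c(5, 20)), tolerance = 1e-12)
  expect_lt(sc$score[1], 0)  # satisfied restraint is a bonus
  expect_equal(sc$satisfied, c(TRUE, FALSE))
  expect_equal(is_satisfied(m, rst), c(TRUE, FALSE))

  # ambiguous pair scores as its best-satisfied member
  amb <- make_ambiguous(rst, group_size = 2, seed = 1, n_sets = 1)[[1]]
  sca <- restraint_score(m, amb)
  expect_equal(sca$group_score, rep(sigmoid_score(5), 2), tolerance = 1e-12)
  # oracle: exhaustive over the two members
  expect_equal(unique(sca$group_score), min(sca$score))
})

test_that("satisfaction is a strict <= cutoff and matches brute force", {
  at <- data.frame(resno = 1:2, resid = "ALA", elety = "CA",
                   x = c(0, 7.99), y = 0, z = 0)
  m <- structure_model(at, "m1")
  r <- read_restraint_file(textConnection_file(
    "AtomPair CA 1 CA 2 SUMFUNC 2 SIGMOID 8 1 CONSTANTFUNC -0.5"))
  expect_true(is_satisfied(m, r))
  m$atoms$x[2] <- 8.01
  expect_false(is_satisfied(m, r))

  # brute-force equivalence on a synthetic model
  ref <- bundle_ref()
  cmap <- make_contact_map(ref, 40, 0.5, seed = 9)
  sel <- suppressWarnings(select_top_contacts(cmap$records, 60))
  rst <- contacts_to_restraints(sel, model_sequence(ref))
  flags <- is_satisfied(ref, rst)
  for (k in seq_len(nrow(rst))) {
    p <- atom_coords(ref, rst$res1[k], rst$atom1[k])
    q <- atom_coords(ref, rst$res2[k], rst$atom2[k])
    expect_identical(unname(flags[k]), sqrt(sum((p - q)^2)) <= 8)
  }
})

test_that("missing atoms are reported by residue and atom", {
  at <- data.frame(resno = 1:2, resid = "GLY", elety = "CA",
                   x = c(0, 5), y = 0, z = 0)
  m <- structure_model(at, "nogly")
  r <- read_restraint_file(textConnection_file(
    "AtomPair CB 1 CA 2 SUMFUNC 2 SIGMOID 8 1 CONSTANTFUNC -0.5"))
  expect_error(restraint_score(m, r), "CB of residue 1")
})
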