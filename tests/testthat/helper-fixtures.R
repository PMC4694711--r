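# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, maker) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, maker(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

bundle_spec <- function() fixture_spec(n_residues = 60, fold = "two_helix_bundle",
                                       seed = 11)

bundle_ref <- function() cached("bundle_ref", function() {
  make_structure(bundle_spec())
})

# 30-model ensemble around the bundle with residues 40-60 planted diverged
split_spec <- function() fixture_spec(
  n_residues = 60, fold = "two_helix_bundle",
  noise_sd_converged = 0.5, noise_sd_diverged = 5.0,
  diverged_region = 40:60, seed = 11
)

split_ensemble <- function() cached("split_ensemble", function() {
  make_ensemble(bundle_ref(), split_spec(), n_models = 30)
})

# a random contact table over seq_len residues with n rows, seeded
random_contact_table <- function(n, seq_len, seed, min_sep_frac = 0) {
  set.seed(seed)
  i <- sample.int(seq_len - 1, n, replace = TRUE)
  j <- pmin(i + sample.int(max(2, seq_len %/% 2), n, replace = TRUE), seq_len)
  ok <- i < j
  data.frame(i = i[ok], j = j[ok], score = round(runif(sum(ok)), 3),
             res_i = NA_character_, res_j = NA_character_)
}

# an ensemble_stats stand-in with a chosen converged fraction
stats_with_fraction <- function(frac, n = 100) {
  k <- round(frac * n)
  structure(list(
    n_models = 30, residues = seq_len(n),
    per_residue_variability = c(rep(0.5, k), rep(5, n - k)),
    converged_mask = c(rep(TRUE, k), rep(FALSE, n - k)),
    fraction_converged = k / n, threshold = 2
  ), class = "ensemble_stats")
}

# write literal lines to a temp file, returning its path
textConnection_file <- function(lines) {
  tf <- tempfile(fileext = ".txt")
  writeLines(lines, tf)
  tf
}

# rotate a point about an axis through 'origin' (Rodrigues)
rotate_about_axis <- function(pt, origin, axis, angle_deg) {
  th <- angle_deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  v <- pt - origin
  vrot <- v * cos(th) + c(
    k[2] * v[3] - k[3] * v[2],
    k[3] * v[1] - k[1] * v[3],
    k[1] * v[2] - k[2] * v[1]
  ) * sin(th) + k * sum(k * v) * (1 - cos(th))
  origin + vrot
}

# push a residue's gamma atom into a different chi1 well (rotate about CA-CB)
flip_chi1 <- function(model, resno, by = 120) {
  at <- model$atoms
  ca <- unlist(at[at$resno == resno & at$elety == "CA", c("x", "y", "z")])
  cb <- unlist(at[at$resno == resno & at$elety == "CB", c("x", "y", "z")])
  g_row <- which(at$resno == resno &
                   !(at$elety %in% c("N", "CA", "C", "O", "CB")))
  g <- unlist(at[g_row, c("x", "y", "z")])
  at[g_row, c("x", "y", "z")] <- as.list(rotate_about_axis(g, cb, cb - ca, by))
  model$atoms <- at
  model
}
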