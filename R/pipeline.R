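# Pipeline drivers behind the command-line interface: core restraint
# generation, the optional refinement round, evaluation and simulation.

#' Protocol configuration
#'
#' All tunable thresholds of the protocol, with the published defaults:
#' top-L selection with minimum sequence separation 5; sigmoid potential
#' x0 = 8 Å, m = 1; contact/satisfaction cutoff 8 Å; per-residue convergence
#' threshold 2 Å measured on the 30 lowest-energy models; final ensemble of
#' 10; success requires at least half the residues converged; refinement
#' triggers below 90% convergence; converged-pair restraints need pair SD
#' below 1 Å; rescued contacts get wide bounds 1.5-8 Å; burial below 40 Å^2;
#' chi1 convergence below 10 degrees.
#'
#' @param ... named overrides of the defaults.
#' @return a \code{protocol_config} list.
#' @export
protocol_config <- function(...) {
  cfg <- list(
    min_separation = 5L,
    sigmoid_x0 = 8.0, sigmoid_m = 1.0,
    contact_cutoff = 8.0,
    convergence_threshold = 2.0,
    n_low_energy_convergence = 30L,
    n_final = 10L,
    success_fraction = 0.5,
    refinement_trigger = 0.9,
    converged_pair_sd_max = 1.0,
    refinement_lb = 1.5, refinement_ub = 8.0,
    sasa_cut = 40.0, chi1_sd_cut = 10.0,
    ambiguous_group_size = 2L,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  num <- vapply(cfg, is.numeric, TRUE)
  if (any(vapply(cfg[num], function(v) any(v <= 0), TRUE) &
          !names(cfg)[num] %in% "seed")) {
    stop("all thresholds must be positive")
  }
  structure(cfg, class = "protocol_config")
}

.input_digest <- function(paths) {
  paths <- paths[!vapply(paths, is.null, TRUE)]
  out <- lapply(paths, function(p) unname(tools::md5sum(p)))
  out
}

.write_provenance <- function(path, stage, config, inputs, counts) {
  rec <- list(
    package = "evrestraints",
    version = as.character(utils::packageVersion("evrestraints")),
    stage = stage,
    config = unclass(config),
    inputs = .input_digest(inputs),
    counts = counts
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Core round: contacts to first-round sigmoidal restraints
#'
#' Reads a ranked contact table and a FASTA sequence, applies top-L selection
#' and writes the sigmoidal restraint file plus a provenance record
#' (\code{core_provenance.json}).
#'
#' @param contacts path to the contact table.
#' @param fasta path to the sequence FASTA.
#' @param out_dir output directory (created if missing).
#' @param config a [protocol_config()].
#' @param dialect contact-table dialect, see [parse_contacts()].
#' @return list with \code{restraint_file}, \code{contact_set},
#'   \code{restraints}, invisibly.
#' @export
run_core <- function(contacts, fasta, out_dir,
                     config = protocol_config(),
                     dialect = "plain") {
  if (!file.exists(contacts)) stop("contact file not found: ", contacts)
  if (!file.exists(fasta)) stop("FASTA file not found: ", fasta)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seq <- read_fasta_seq(fasta)
  rec <- parse_contacts(contacts, dialect = dialect)
  sel <- select_top_contacts(rec, seq_len = length(seq),
                             min_separation = config$min_separation)
  rst <- contacts_to_restraints(sel, seq, x0 = config$sigmoid_x0,
                                m = config$sigmoid_m)
  rst_file <- file.path(out_dir, "core_restraints.cst")
  write_restraint_file(rst, rst_file)
  .write_provenance(
    file.path(out_dir, "core_provenance.json"), "core", config,
    list(contacts = contacts, fasta = fasta),
    list(seq_len = length(seq), n_input_contacts = nrow(rec),
         L = sel$L, n_selected = nrow(sel$records), n_restraints = nrow(rst))
  )
  invisible(list(restraint_file = rst_file, contact_set = sel,
                 restraints = rst))
}

#' Refinement round: convergence analysis and restraint re-picking
#'
#' Ranks the models by energy, measures per-residue convergence on the
#' \code{n_low_energy_convergence} lowest-energy models, classifies the
#' prediction, and — when the converged fraction falls below the refinement
#' trigger — derives the second-round restraints: strict bounded restraints
#' for converged CA-CA pairs, wide bounded restraints for rescued low-rank
#' contacts, and \code{n_sets} random ambiguous groupings of the latter. A
#' convergence report and provenance record are always written; restraint
#' files only when refinement is warranted.
#'
#' @param models directory of PDB models, or a list of \code{structure_model}.
#' @param scores path to the score table (ignored when \code{models} already
#'   carry energies).
#' @param contacts path to the full contact table.
#' @param used the first-round \code{contact_set}, or a path to the contact
#'   table from which it is reselected.
#' @param fasta optional FASTA path (for glycine-aware restraint atoms and
#'   for reselecting \code{used} from a path).
#' @param out_dir output directory.
#' @param config a [protocol_config()].
#' @param n_sets number of ambiguous groupings to emit.
#' @param dialect contact-table dialect.
#' @return list with \code{stats}, \code{classification}, \code{refine}
#'   (logical), and when refining: \code{converged_restraints},
#'   \code{refinement_restraints}, \code{files}; invisibly.
#' @export
run_refine <- function(models, scores = NULL, contacts, used = NULL,
                       fasta = NULL, out_dir, config = protocol_config(),
                       n_sets = 1, dialect = "plain") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model_dir <- if (is.character(models)) models else NULL
  if (is.character(models)) models <- read_model_set(models, scores)
  seq <- if (!is.null(fasta)) read_fasta_seq(fasta) else NULL

  low <- rank_models(models, config$n_low_energy_convergence)
  stats <- per_residue_convergence(low, threshold = config$convergence_threshold)
  classification <- classify_success(stats, min_fraction = config$success_fraction)
  refine <- needs_refinement(stats, threshold = config$refinement_trigger)

  report <- list(
    n_models = length(models),
    n_low_energy = length(low),
    fraction_converged = stats$fraction_converged,
    classification = classification,
    needs_refinement = refine,
    residues = stats$residues,
    per_residue_variability = round(unname(stats$per_residue_variability), 4),
    converged_mask = unname(stats$converged_mask)
  )
  jsonlite::write_json(report, file.path(out_dir, "convergence_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  out <- list(stats = stats, classification = classification, refine = refine)
  counts <- list(fraction_converged = stats$fraction_converged,
                 classification = classification)

  if (refine) {
    rec <- parse_contacts(contacts, dialect = dialect)
    if (is.null(used)) {
      if (is.null(seq)) stop("reselecting first-round contacts needs a FASTA")
      used <- select_top_contacts(rec, length(seq),
                                  min_separation = config$min_separation)
    }
    pstats <- pair_distance_stats(low, atom = "CA")
    conv <- derive_converged_restraints(
      pstats, d_max = config$contact_cutoff,
      sd_max = config$converged_pair_sd_max
    )
    resc <- derive_refinement_contacts(
      rec, used, pstats, sd_min = config$converged_pair_sd_max,
      d_max = config$contact_cutoff, sequence = seq,
      lb = config$refinement_lb, ub = config$refinement_ub
    )
    files <- character(0)
    f_conv <- file.path(out_dir, "converged_pairs.cst")
    write_restraint_file(conv, f_conv)
    files <- c(files, f_conv)
    if (nrow(resc) >= config$ambiguous_group_size) {
      sets <- make_ambiguous(resc, group_size = config$ambiguous_group_size,
                             seed = config$seed, n_sets = n_sets)
      for (s in seq_along(sets)) {
        f <- file.path(out_dir, sprintf("refinement_contacts_set%d.cst", s))
        write_restraint_file(sets[[s]], f)
        files <- c(files, f)
      }
    } else if (nrow(resc) > 0) {
      f <- file.path(out_dir, "refinement_contacts_set1.cst")
      write_restraint_file(resc, f)
      files <- c(files, f)
    }
    out$converged_restraints <- conv
    out$refinement_restraints <- resc
    out$files <- files
    counts$n_converged_restraints <- nrow(conv)
    counts$n_rescued_contacts <- nrow(resc)
  }

  .write_provenance(
    file.path(out_dir, "refine_provenance.json"), "refine", config,
    list(models = NULL, contacts = if (refine) contacts else NULL,
         fasta = fasta),
    counts
  )
  invisible(out)
}

#' Simulate a full synthetic test case to disk
#'
#' Writes reference and ensemble PDBs, a score table, a contact table with
#' controlled PPV, the sequence FASTA and a ground-truth JSON (planted chi1
#' wells, converged mask, contact labels).
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory.
#' @param n_models ensemble size.
#' @return list with the generated objects and file paths, invisibly.
#' @export
run_simulate <- function(spec, out_dir, n_models = 30) {
  dir.create(file.path(out_dir, "models"), showWarnings = FALSE,
             recursive = TRUE)
  ref <- make_structure(spec)
  ens <- make_ensemble(ref, spec, n_models = n_models)
  cmap <- make_contact_map(ref, spec$n_contacts, spec$contact_ppv, spec$seed)

  ref_file <- file.path(out_dir, "reference.pdb")
  write_pdb_model(ref, ref_file)
  for (m in ens$models) {
    write_pdb_model(m, file.path(out_dir, "models", paste0(m$id, ".pdb")))
  }
  score_file <- file.path(out_dir, "scores.tsv")
  writeLines(c("model_id\tenergy",
               sprintf("%s\t%.6f", ens$scores$model_id, ens$scores$energy)),
             score_file)
  contact_file <- file.path(out_dir, "contacts.txt")
  writeLines(sprintf("%d %d %.6f", cmap$records$i, cmap$records$j,
                     cmap$records$score), contact_file)
  fasta_file <- file.path(out_dir, "sequence.fasta")
  writeLines(c(">synthetic", paste(aa321(attr(ref, "sequence")),
                                   collapse = "")), fasta_file)
  truth_file <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(
    list(spec = unclass(spec),
         chi1_truth = attr(ref, "chi1_truth"),
         converged_truth = ens$converged_truth,
         contact_truth = cmap$truth),
    truth_file, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(list(
    reference = ref, ensemble = ens, contact_map = cmap,
    files = list(reference = ref_file, models = file.path(out_dir, "models"),
                 scores = score_file, contacts = contact_file,
                 fasta = fasta_file, truth = truth_file)
  ))
}
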