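# Structure models: a light container over per-atom coordinates, plus PDB and
# table I/O. Residue numbering inside a structure_model is 1-based and
# sequential; the PDB reader maps author numbering onto it.

#' Construct a structure model
#'
#' @param atoms data.frame with columns \code{resno} (1-based sequential
#'   residue index), \code{resid} (three-letter residue name), \code{elety}
#'   (atom name, e.g. "CA"), \code{x}, \code{y}, \code{z} (Å).
#' @param id model identifier.
#' @param energy optional scalar energy (engine units, e.g. REU) used only
#'   for ranking.
#' @return object of class \code{structure_model}.
#' @export
structure_model <- function(atoms, id = "model", energy = NA_real_) {
  need <- c("resno", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in model ", id)
  }
  ca <- atoms$elety == "CA"
  missing_ca <- setdiff(unique(atoms$resno), atoms$resno[ca])
  if (length(missing_ca)) {
    stop("residue(s) without CA in model ", id, ": ",
         paste(utils::head(missing_ca, 5), collapse = ", "))
  }
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, id = id, energy = energy),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model '%s': %d residues, %d atoms%s\n",
              x$id, length(unique(x$atoms$resno)), nrow(x$atoms),
              if (is.na(x$energy)) "" else sprintf(", energy %.3f", x$energy)))
  invisible(x)
}

#' Number of residues in a model
#' @param model a \code{structure_model}.
#' @export
n_residues <- function(model) length(unique(model$atoms$resno))

#' Coordinates of named atoms
#'
#' @param model a \code{structure_model}.
#' @param resno residue indices (recycled against \code{elety}).
#' @param elety atom names.
#' @return numeric matrix (length(resno) x 3). Errors naming the residue and
#'   atom if any requested atom is absent.
#' @export
atom_coords <- function(model, resno, elety) {
  at <- model$atoms
  key <- paste(at$resno, at$elety)
  idx <- match(paste(resno, elety), key)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop(sprintf("atom %s of residue %d not found in model '%s'",
                 elety[miss], resno[miss], model$id))
  }
  as.matrix(at[idx, c("x", "y", "z"), drop = FALSE])
}

#' C-alpha coordinate matrix of a model
#' @param model a \code{structure_model}.
#' @param resno residue selection (default: all residues, ascending).
#' @return n x 3 matrix with rownames = residue indices.
#' @export
ca_matrix <- function(model, resno = NULL) {
  if (is.null(resno)) resno <- sort(unique(model$atoms$resno))
  m <- atom_coords(model, resno, rep("CA", length(resno)))
  rownames(m) <- resno
  m
}

#' One-letter sequence of a model
#' @param model a \code{structure_model}.
#' @return character vector of one-letter codes (X for non-standard).
#' @export
model_sequence <- function(model) {
  resno <- sort(unique(model$atoms$resno))
  res3 <- model$atoms$resid[match(resno, model$atoms$resno)]
  unname(aa321(res3))
}

# three-letter <-> one-letter residue codes
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
          "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

aa321 <- function(res3) {
  out <- .aa1[match(toupper(res3), .aa3)]
  out[is.na(out)] <- "X"
  out
}

aa123 <- function(res1) {
  out <- .aa3[match(toupper(res1), .aa1)]
  out[is.na(out)] <- "UNK"
  out
}

#' Read a structure model from a PDB file
#'
#' Thin wrapper over \code{bio3d::read.pdb}: keeps the first model of
#' multi-model files, prefers altloc 'A' (blank altloc always kept), rejects
#' insertion codes with a clear error, and renumbers residues sequentially
#' from 1 in chain/author order.
#'
#' @param path PDB file.
#' @param id model id (default: file name without extension).
#' @param energy optional energy to attach.
#' @return a \code{structure_model}.
#' @export
read_pdb_model <- function(path, id = NULL, energy = NA_real_) {
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (any(!is.na(at$insert) & at$insert != "")) {
    stop("PDB file ", path, " contains insertion codes; renumber it first")
  }
  keep_alt <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep_alt, , drop = FALSE]
  # sequential 1-based numbering over (chain, author resno) in file order
  ukey <- paste(at$chain, at$resno)
  resno <- match(ukey, unique(ukey))
  structure_model(
    data.frame(resno = resno, resid = at$resid, elety = at$elety,
               x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE),
    id = id, energy = energy
  )
}

#' Write a structure model as a PDB file
#'
#' Fixed-width ATOM records, coordinates to 3 decimals (PDB precision),
#' chain A, occupancy 1.00, B-factor 0.00.
#'
#' @param model a \code{structure_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pdb_model <- function(model, path) {
  at <- model$atoms
  elem <- substr(at$elety, 1, 1)
  lines <- sprintf(
    "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(at)),
    ifelse(nchar(at$elety) < 4, paste0(" ", at$elety), at$elety),
    at$resid, at$resno, at$x, at$y, at$z, elem
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(lines, "TER", "END"), con, sep = "\n")
  invisible(path)
}

#' Read a model-energy score table
#'
#' Whitespace/tab-separated table with columns \code{model_id} and
#' \code{energy}; a header line is detected and skipped; '#' comments ignored.
#'
#' @param path path to the table.
#' @return data.frame with columns \code{model_id} (character), \code{energy}
#'   (numeric).
#' @export
read_score_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  f1 <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(f1) >= 2 && is.na(suppressWarnings(as.numeric(f1[2])))) {
    lines <- lines[-1]  # header
  }
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(parts, length, 1L) < 2)
  if (length(bad)) stop("score table line ", bad[1], ": need model_id and energy")
  data.frame(
    model_id = vapply(parts, `[`, "", 1),
    energy = as.numeric(vapply(parts, `[`, "", 2)),
    stringsAsFactors = FALSE
  )
}

#' Read a directory of PDB models with energies
#'
#' @param dir directory containing \code{*.pdb} files.
#' @param scores optional score table (path or data.frame from
#'   [read_score_table()]) keyed by file name without extension.
#' @return list of \code{structure_model}.
#' @export
read_model_set <- function(dir, scores = NULL) {
  files <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  if (!length(files)) stop("no .pdb files in ", dir)
  if (is.character(scores)) scores <- read_score_table(scores)
  lapply(files, function(f) {
    id <- sub("\\.pdb$", "", basename(f))
    e <- NA_real_
    if (!is.null(scores)) {
      hit <- match(id, scores$model_id)
      if (!is.na(hit)) e <- scores$energy[hit]
    }
    read_pdb_model(f, id = id, energy = e)
  })
}

#' Read a protein sequence from FASTA
#' @param path FASTA file; first record used.
#' @return one-letter character vector.
#' @export
read_fasta_seq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA header in ", path)
  end <- if (length(hdr) > 1) hdr[2] - 1 else length(lines)
  seqs <- paste(lines[(hdr[1] + 1):end], collapse = "")
  strsplit(toupper(gsub("\\s", "", seqs)), "")[[1]]
}

#' Read a per-residue secondary-structure assignment
#'
#' Accepts either a single line of one-letter codes (H/E/C/...) or a
#' two-column \code{resno ss} table; '#' comments ignored.
#'
#' @param path assignment file.
#' @return character vector of per-residue codes.
#' @export
read_sse <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("empty secondary-structure file: ", path)
  if (length(lines) == 1 && !grepl("\\s", trimws(lines))) {
    return(strsplit(toupper(trimws(lines)), "")[[1]])
  }
  parts <- strsplit(trimws(lines), "\\s+")
  resno <- as.integer(vapply(parts, `[`, "", 1))
  ss <- toupper(vapply(parts, `[`, "", 2))
  out <- rep("C", max(resno))
  out[resno] <- ss
  out
}
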