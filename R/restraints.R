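# Restraint container and the Rosetta-style constraint-file dialect.

# A restraint_set is a data.frame with one row per atom-pair restraint:
#   res1, atom1, res2, atom2 : endpoints (1-based residue index, atom name)
#   kind                     : "sigmoid" or "bounded"
#   x0, m                    : sigmoid parameters (NA for bounded)
#   lb, ub, sd               : bounded parameters (NA for sigmoid)
#   group                    : ambiguity group id (NA = unambiguous)

new_restraint_set <- function(df) {
  cols <- c("res1", "atom1", "res2", "atom2", "kind",
            "x0", "m", "lb", "ub", "sd", "group")
  for (cl in setdiff(cols, names(df))) df[[cl]] <- NA
  df <- df[, cols, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("restraint_set", "data.frame")
  df
}

#' Build an empty restraint set
#' @return a zero-row \code{restraint_set}.
#' @keywords internal
empty_restraint_set <- function() {
  new_restraint_set(data.frame(
    res1 = integer(), atom1 = character(), res2 = integer(),
    atom2 = character(), kind = character(), x0 = numeric(), m = numeric(),
    lb = numeric(), ub = numeric(), sd = numeric(), group = integer(),
    stringsAsFactors = FALSE
  ))
}

#' Restraint atom name for a residue
#'
#' Contact restraints act between side-chain proxy atoms: C-beta, except for
#' glycine (which has none), where C-alpha is used instead.
#'
#' @param aa one-letter (or three-letter) amino-acid code(s).
#' @return \code{"CB"} or \code{"CA"} per residue.
#' @keywords internal
contact_atom <- function(aa) {
  gly <- toupper(aa) %in% c("G", "GLY")
  ifelse(gly, "CA", "CB")
}

#' Convert selected contacts to sigmoidal distance restraints
#'
#' Each predicted contact becomes one C-beta/C-beta distance restraint scored
#' with the shallow sigmoidal potential \eqn{1/(1+e^{-m(x-x_0)}) - 0.5} with
#' \eqn{x_0 = 8} Å and \eqn{m = 1}: a satisfied contact (distance below ~8 Å)
#' contributes a bonus approaching -0.5, while a violated one scores ~0 with
#' vanishing gradient, so false-positive predictions cannot misguide folding.
#' Glycine endpoints use C-alpha.
#'
#' @param contacts a \code{contact_set} from [select_top_contacts()].
#' @param sequence protein sequence as a one-letter string (or a character
#'   vector of one-letter codes).
#' @param x0,m sigmoid midpoint (Å) and steepness (1/Å).
#' @return a \code{restraint_set} with one sigmoid restraint per contact.
#' @export
contacts_to_restraints <- function(contacts, sequence, x0 = 8.0, m = 1.0) {
  stopifnot(inherits(contacts, "contact_set"))
  aa <- .as_aa_vector(sequence)
  rec <- contacts$records
  if (nrow(rec) == 0) return(empty_restraint_set())
  if (max(rec$i, rec$j) > length(aa)) {
    stop(sprintf("contact index %d exceeds sequence length %d",
                 max(rec$i, rec$j), length(aa)))
  }
  new_restraint_set(data.frame(
    res1 = rec$i, atom1 = contact_atom(aa[rec$i]),
    res2 = rec$j, atom2 = contact_atom(aa[rec$j]),
    kind = "sigmoid", x0 = x0, m = m,
    lb = NA_real_, ub = NA_real_, sd = NA_real_, group = NA_integer_,
    stringsAsFactors = FALSE
  ))
}

.as_aa_vector <- function(sequence) {
  if (length(sequence) == 1 && nchar(sequence) > 1) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  toupper(as.character(sequence))
}

.fmt_num <- function(x) {
  # canonical number formatting so write -> read -> write is byte-identical
  vapply(x, function(v) format(v, digits = 15, trim = TRUE,
                               scientific = FALSE), character(1))
}

.restraint_line <- function(r) {
  head <- sprintf("AtomPair %s %d %s %d", r$atom1, r$res1, r$atom2, r$res2)
  if (r$kind == "sigmoid") {
    # emitted as sigmoid + constant offset so satisfied restraints are a bonus
    sprintf("%s SUMFUNC 2 SIGMOID %s %s CONSTANTFUNC -0.5",
            head, .fmt_num(r$x0), .fmt_num(r$m))
  } else {
    sprintf("%s BOUNDED %s %s %s 0.5 restraint",
            head, .fmt_num(r$lb), .fmt_num(r$ub), .fmt_num(r$sd))
  }
}

#' Write restraints in the Rosetta constraint-file dialect
#'
#' One line per restraint:
#' \preformatted{
#' AtomPair <atom1> <res1> <atom2> <res2> SUMFUNC 2 SIGMOID <x0> <m> CONSTANTFUNC -0.5
#' AtomPair <atom1> <res1> <atom2> <res2> BOUNDED <lb> <ub> <sd> 0.5 restraint
#' }
#' Restraints sharing an ambiguity group id are wrapped in an
#' \code{AmbiguousConstraint} ... \code{END_AMBIGUOUS} block (scored by the
#' best-satisfied member). Canonical formatting makes
#' write -> [read_restraint_file()] -> write byte-identical.
#'
#' @param restraints a \code{restraint_set}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_restraint_file <- function(restraints, path) {
  stopifnot(inherits(restraints, "restraint_set"))
  lines <- character(0)
  plain <- restraints[is.na(restraints$group), , drop = FALSE]
  for (k in seq_len(nrow(plain))) {
    lines <- c(lines, .restraint_line(plain[k, ]))
  }
  groups <- unique(restraints$group[!is.na(restraints$group)])
  for (g in sort(groups)) {
    memb <- restraints[!is.na(restraints$group) & restraints$group == g, ,
                       drop = FALSE]
    lines <- c(lines, "AmbiguousConstraint")
    for (k in seq_len(nrow(memb))) {
      lines <- c(lines, .restraint_line(memb[k, ]))
    }
    lines <- c(lines, "END_AMBIGUOUS")
  }
  con <- file(path, open = "wb")  # LF endings on every platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a restraint file written by [write_restraint_file()]
#'
#' @param path path to a constraint file in the dialect documented in
#'   [write_restraint_file()].
#' @return a \code{restraint_set}.
#' @export
read_restraint_file <- function(path) {
  if (!file.exists(path)) stop("restraint file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rows <- list()
  group <- NA_integer_
  next_group <- 1L
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "AmbiguousConstraint") {
      group <- next_group
      next_group <- next_group + 1L
      next
    }
    if (line == "END_AMBIGUOUS") {
      group <- NA_integer_
      next
    }
    f <- strsplit(line, "\\s+")[[1]]
    if (f[1] != "AtomPair") stop(sprintf("line %d: unrecognised record '%s'", ln, f[1]))
    base <- list(atom1 = f[2], res1 = as.integer(f[3]),
                 atom2 = f[4], res2 = as.integer(f[5]))
    if (f[6] == "SUMFUNC") {
      rows[[length(rows) + 1L]] <- data.frame(
        res1 = base$res1, atom1 = base$atom1, res2 = base$res2,
        atom2 = base$atom2, kind = "sigmoid",
        x0 = as.numeric(f[9]), m = as.numeric(f[10]),
        lb = NA_real_, ub = NA_real_, sd = NA_real_, group = group,
        stringsAsFactors = FALSE
      )
    } else if (f[6] == "BOUNDED") {
      rows[[length(rows) + 1L]] <- data.frame(
        res1 = base$res1, atom1 = base$atom1, res2 = base$res2,
        atom2 = base$atom2, kind = "bounded",
        x0 = NA_real_, m = NA_real_,
        lb = as.numeric(f[7]), ub = as.numeric(f[8]), sd = as.numeric(f[9]),
        group = group, stringsAsFactors = FALSE
      )
    } else {
      stop(sprintf("line %d: unknown function tag '%s'", ln, f[6]))
    }
  }
  if (length(rows) == 0) return(empty_restraint_set())
  new_restraint_set(do.call(rbind, rows))
}

#' @export
print.restraint_set <- function(x, ...) {
  n_amb <- length(unique(x$group[!is.na(x$group)]))
  cat(sprintf("restraint_set: %d restraints (%d sigmoid, %d bounded, %d ambiguity groups)\n",
              nrow(x), sum(x$kind == "sigmoid"), sum(x$kind == "bounded"), n_amb))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
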