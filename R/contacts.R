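# Reading and selecting residue-residue contact predictions.

#' Parse a ranked contact-prediction table
#'
#' Reads a whitespace- or comma-separated table of predicted residue-residue
#' contacts, as produced by coevolution-based predictors (plmDCA / EVcouplings
#' and relatives). Two column layouts ("dialects") are supported:
#' \describe{
#'   \item{\code{plain}}{three columns: \code{i j score}.}
#'   \item{\code{evcouplings}}{five columns: \code{i res_i j res_j score},
#'     where \code{res_i}/\code{res_j} are one-letter amino-acid codes.}
#' }
#' Lines starting with \code{#} and blank lines are ignored. Records are
#' normalised so that \code{i < j}; when the same pair occurs more than once
#' (all-by-all tables may list both orientations) the highest score is kept.
#' Input order of first occurrence is preserved, which downstream selection
#' uses only as stable-sort metadata.
#'
#' @param path path to the contact table.
#' @param dialect column layout, \code{"plain"} or \code{"evcouplings"}.
#' @return a \code{data.frame} with columns \code{i}, \code{j} (integer,
#'   1-based, \code{i < j}), \code{score} (numeric) and, for the
#'   \code{evcouplings} dialect, \code{res_i}, \code{res_j}.
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines(c("# rank i j score", "2 10 1.5", "4 9 0.7", "10 2 0.3"), tf)
#' parse_contacts(tf)  # (2,10) keeps score 1.5
parse_contacts <- function(path, dialect = c("plain", "evcouplings")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("contact table not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  n_cols <- if (dialect == "plain") 3L else 5L

  recs <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    fields <- strsplit(trimws(gsub(",", " ", lines[ln])), "\\s+")[[1]]
    if (length(fields) != n_cols) {
      stop(sprintf(
        "line %d: expected %d columns for dialect '%s', found %d",
        ln, n_cols, dialect, length(fields)
      ))
    }
    if (dialect == "plain") {
      i <- .parse_index(fields[1], ln)
      j <- .parse_index(fields[2], ln)
      score <- .parse_score(fields[3], ln)
      recs[[k]] <- data.frame(i = i, j = j, score = score,
                              res_i = NA_character_, res_j = NA_character_,
                              stringsAsFactors = FALSE)
    } else {
      i <- .parse_index(fields[1], ln)
      j <- .parse_index(fields[3], ln)
      score <- .parse_score(fields[5], ln)
      recs[[k]] <- data.frame(i = i, j = j, score = score,
                              res_i = fields[2], res_j = fields[4],
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(i = integer(), j = integer(), score = numeric(),
                      res_i = character(), res_j = character(),
                      stringsAsFactors = FALSE)
  }
  if (any(out$i == out$j)) {
    bad <- keep[which(out$i == out$j)[1]]
    stop(sprintf("line %d: self-contact (i == j)", bad))
  }
  # normalise to i < j, swapping residue annotations along
  flip <- out$i > out$j
  if (any(flip)) {
    tmp <- out$i[flip]; out$i[flip] <- out$j[flip]; out$j[flip] <- tmp
    tmp <- out$res_i[flip]; out$res_i[flip] <- out$res_j[flip]
    out$res_j[flip] <- tmp
  }
  # duplicates: keep the maximum score, first-occurrence position
  key <- paste(out$i, out$j)
  if (anyDuplicated(key)) {
    best <- tapply(out$score, key, max)
    first <- !duplicated(key)
    out <- out[first, , drop = FALSE]
    out$score <- as.numeric(best[paste(out$i, out$j)])
  }
  rownames(out) <- NULL
  out
}

.parse_index <- function(x, line) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v) || v != round(v)) {
    stop(sprintf("line %d: residue index '%s' is not an integer", line, x))
  }
  if (v < 1) stop(sprintf("line %d: residue index %s < 1", line, x))
  as.integer(v)
}

.parse_score <- function(x, line) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop(sprintf("line %d: score '%s' is not numeric", line, x))
  v
}

#' Top-L contact selection
#'
#' Applies the standard selection rule for coevolution-predicted contacts:
#' drop pairs closer than \code{min_separation} residues in sequence, rank the
#' rest by descending confidence score, and keep the top \code{L}, where
#' \code{L} is the sequence length rounded down to the nearest multiple of 10.
#' Ties in score are broken by ascending \code{(i, j)} so that selection is
#' deterministic across platforms.
#'
#' @param records contact records as returned by [parse_contacts()].
#' @param seq_len length of the protein sequence (residues); must be >= 10.
#' @param min_separation minimum sequence separation \code{|i - j|} (default 5).
#' @return a \code{contact_set}: list with \code{records} (the selected rows,
#'   ranked), \code{seq_len}, \code{L} and \code{min_separation}.
#' @export
select_top_contacts <- function(records, seq_len, min_separation = 5) {
  stopifnot(is.data.frame(records))
  if (!is.numeric(seq_len) || length(seq_len) != 1 || seq_len < 10) {
    stop("seq_len must be a single number >= 10 (top-L count would be 0)")
  }
  seq_len <- as.integer(seq_len)
  L <- (seq_len %/% 10L) * 10L
  keep <- abs(records$i - records$j) >= min_separation
  surv <- records[keep, , drop = FALSE]
  ord <- order(-surv$score, surv$i, surv$j)
  surv <- surv[ord, , drop = FALSE]
  if (nrow(surv) < L) {
    warning(sprintf(
      "only %d contacts survive the separation filter; top-L wants %d",
      nrow(surv), L
    ))
  } else {
    surv <- surv[seq_len(L), , drop = FALSE]
  }
  rownames(surv) <- NULL
  structure(
    list(records = surv, seq_len = seq_len, L = L,
         min_separation = min_separation),
    class = "contact_set"
  )
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf(
    "contact_set: %d contacts (top-L = %d, seq_len = %d, min |i-j| = %d)\n",
    nrow(x$records), x$L, x$seq_len, x$min_separation
  ))
  invisible(x)
}

#' @export
length.contact_set <- function(x) nrow(x$records)
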