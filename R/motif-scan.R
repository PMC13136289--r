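#' Construct a protein record
#'
#' @param id protein identifier.
#' @param sequence amino-acid sequence (case-insensitive; a trailing `*`
#'   translation terminator is stripped with a warning).
#' @param features optional data frame with columns `name`, `start`, `end`
#'   giving 1-based inclusive annotated intervals (e.g. a PDE catalytic
#'   center).
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, features = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("'id' must be a single non-empty string")
  }
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L) stop("'sequence' must be a single string")
  if (grepl("\\*$", sequence)) {
    warning("stripping trailing '*' terminator from sequence of ", id)
    sequence <- sub("\\*+$", "", sequence)
  }
  if (grepl("[^A-Z]", sequence)) {
    stop("sequence of ", id, " contains non-alphabetic characters")
  }
  if (!is.null(features)) {
    features <- as.data.frame(features)
    stopifnot(all(c("name", "start", "end") %in% names(features)))
    features$start <- as.integer(features$start)
    features$end <- as.integer(features$end)
    ok <- features$start >= 1L & features$start <= features$end &
      features$end <= nchar(sequence)
    if (!all(ok)) {
      stop("feature interval(s) out of bounds for ", id, ": ",
           paste(features$name[!ok], collapse = ", "))
    }
  }
  structure(list(id = id, sequence = sequence, features = features),
            class = "protein_record")
}

#' Enumerate all motif matches in one protein sequence
#'
#' Reports EVERY distinct combination of anchor positions satisfying all gap
#' bounds — full enumeration, not a leftmost-greedy regular-expression match,
#' because overlapping alternative placements of the binding signature are
#' biologically meaningful (the motif can span multiple pockets).  Ambiguity
#' letters (X, B, Z, U, O, J) are tolerated in the sequence but never match
#' an anchor class.
#'
#' @param record a [protein_record()] (or a bare sequence string, in which
#'   case `id` is used).
#' @param pattern a [motif_pattern()]; default [aba_motif()].
#' @param id identifier used when `record` is a bare string.
#' @return A data frame of class `motif_matches` with one row per match:
#'   `protein_id`, `start`, `end` (1-based inclusive span from first to last
#'   anchor), `anchor_positions` (list column of integer vectors),
#'   `anchor_residues` (concatenated matched letters).  Rows are sorted by
#'   span start, then lexicographically by anchor positions.
#' @examples
#' toy <- paste0("E", strrep("A", 7), "R", strrep("A", 8),
#'               "Y", strrep("A", 6), "K")
#' scan_sequence(toy, aba_motif())
#' @export
scan_sequence <- function(record, pattern = aba_motif(), id = "seq1") {
  if (!inherits(record, "protein_record")) {
    record <- protein_record(id, record)
  }
  stopifnot(inherits(pattern, "motif_pattern"))
  seq_chars <- strsplit(record$sequence, "")[[1L]]
  n <- length(seq_chars)
  k <- length(pattern$anchors)
  empty <- motif_matches(data.frame())
  if (n == 0L) return(empty)

  # positions matching each anchor class
  anchor_pos <- lapply(pattern$anchors, function(cls) {
    which(seq_chars %in% cls)
  })
  if (any(vapply(anchor_pos, length, integer(1L)) == 0L)) return(empty)

  # depth-first extension over anchors under the gap bounds
  combos <- list()
  extend <- function(prefix, depth) {
    if (depth > k) {
      combos[[length(combos) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    cand <- anchor_pos[[depth]]
    if (depth > 1L) {
      g <- pattern$gaps[[depth - 1L]]
      last <- prefix[depth - 1L]
      # spacer length = pos - last - 1 must lie in [g1, g2]
      cand <- cand[cand >= last + g[1L] + 1L & cand <= last + g[2L] + 1L]
    }
    for (p in cand) extend(c(prefix, p), depth + 1L)
  }
  extend(integer(0), 1L)
  if (length(combos) == 0L) return(empty)

  # sort by start, then lexicographically by the full position tuple
  key <- vapply(combos, function(p) {
    paste(sprintf("%09d", p), collapse = ",")
  }, character(1L))
  combos <- combos[order(key)]

  df <- data.frame(
    protein_id = record$id,
    start = vapply(combos, `[`, integer(1L), 1L),
    end = vapply(combos, function(p) p[k], integer(1L)),
    stringsAsFactors = FALSE
  )
  df$anchor_positions <- combos
  df$anchor_residues <- vapply(combos, function(p) {
    paste(seq_chars[p], collapse = "")
  }, character(1L))
  motif_matches(df)
}

motif_matches <- function(df) {
  if (nrow(df) == 0L) {
    df <- data.frame(protein_id = character(0), start = integer(0),
                     end = integer(0), stringsAsFactors = FALSE)
    df$anchor_positions <- list()
    df$anchor_residues <- character(0)
  }
  class(df) <- c("motif_matches", "data.frame")
  df
}

#' Scan a collection of protein records and summarise per-protein hits
#'
#' A protein counts once toward `n_with_match` regardless of how many
#' alternative anchor placements it contains, so overlapping matches never
#' inflate the proteome-level count.
#'
#' @param records a list of [protein_record()]s, or a named character vector
#'   of sequences, or a `Biostrings::AAStringSet`.
#' @param pattern a [motif_pattern()].
#' @return A list of class `scan_summary`: `matches` (combined
#'   `motif_matches` data frame), `n_proteins`, `n_with_match`,
#'   `fraction_with_match`, and `per_protein` (data frame of id, n_matches,
#'   has_match).
#' @export
scan_fasta <- function(records, pattern = aba_motif()) {
  records <- as_protein_records(records)
  if (length(records) == 0L) stop("need at least one protein record")
  ids <- vapply(records, `[[`, character(1L), "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate protein id(s): ", paste(dup, collapse = ", "))
  }
  match_list <- lapply(records, scan_sequence, pattern = pattern)
  matches <- do.call(rbind, match_list)
  matches <- motif_matches(as.data.frame(matches))
  n_per <- vapply(match_list, nrow, integer(1L))
  per_protein <- data.frame(
    protein_id = ids,
    n_matches = n_per,
    has_match = n_per > 0L,
    stringsAsFactors = FALSE
  )
  structure(list(
    matches = matches,
    per_protein = per_protein,
    n_proteins = length(records),
    n_with_match = sum(n_per > 0L),
    fraction_with_match = sum(n_per > 0L) / length(records)
  ), class = "scan_summary")
}

#' @export
print.scan_summary <- function(x, ...) {
  cat("<scan_summary> ", x$n_with_match, " of ", x$n_proteins,
      " proteins with >=1 motif match (fraction ",
      signif(x$fraction_with_match, 3), "); ",
      nrow(x$matches), " matches total\n", sep = "")
  invisible(x)
}

as_protein_records <- function(records) {
  if (inherits(records, "AAStringSet")) {
    records <- setNames(as.character(records), names(records))
  }
  if (is.character(records)) {
    ids <- names(records)
    if (is.null(ids)) ids <- paste0("seq", seq_along(records))
    # FASTA headers: keep the first whitespace-delimited token as the id
    ids <- sub("\\s.*$", "", ids)
    records <- Map(protein_record, ids, unname(records))
  }
  if (inherits(records, "protein_record")) records <- list(records)
  stopifnot(all(vapply(records, inherits, logical(1L), "protein_record")))
  records
}

#' Overlap between a motif match span and an annotated feature
#'
#' Both intervals are 1-based inclusive; the overlap of the AtKUP5
#' ABA-binding site (657-685) with its PDE catalytic center (669-706) is 17
#' residues.
#'
#' @param match a `motif_matches` row, a length-2 vector `c(start, end)`, or
#'   a list with `start`/`end`.
#' @param feature a length-2/3 vector or list with `start` and `end` (an
#'   optional first element or `name` field is ignored for arithmetic).
#' @return Overlap length in residues (0 for disjoint intervals).
#' @export
feature_overlap <- function(match, feature) {
  span <- interval_of(match)
  feat <- interval_of(feature)
  max(0L, min(span[2L], feat[2L]) - max(span[1L], feat[1L]) + 1L)
}

interval_of <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    v <- c(as.integer(x$start), as.integer(x$end))
  } else if (is.list(x) && !is.null(x$start)) {
    v <- c(as.integer(x$start), as.integer(x$end))
  } else {
    # vector form: optionally ("name", start, end); keep the numeric tail
    v <- suppressWarnings(as.integer(x))
    v <- utils::tail(v[!is.na(v)], 2L)
  }
  if (length(v) != 2L || anyNA(v)) {
    stop("cannot interpret interval: need start and end")
  }
  stopifnot(v[1L] <= v[2L])
  v
}

#' Convert between 1-based inclusive and 0-based half-open coordinates
#'
#' Internal coordinates follow the 1-based inclusive residue numbering used
#' in the protein literature (E657, Y678, K685); these helpers convert at
#' I/O boundaries to the 0-based half-open convention of BED-like formats.
#'
#' @param start,end interval bounds.
#' @return A length-2 integer vector in the other convention.
#' @export
to_zero_based <- function(start, end) c(as.integer(start) - 1L, as.integer(end))

#' @rdname to_zero_based
#' @export
to_one_based <- function(start, end) c(as.integer(start) + 1L, as.integer(end))
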