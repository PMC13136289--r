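#' Read protein sequences and optional feature annotations
#'
#' FASTA parsing (wrapped or unwrapped, multi-record) goes through
#' `Biostrings::readAAStringSet`; header ids are truncated at the first
#' whitespace.  Feature tables are tab-separated text with at least four
#' columns: protein_id, name, start, end (1-based inclusive).
#'
#' @param fasta_file path to a FASTA file of amino-acid sequences.
#' @param features_file optional path to the feature TSV.
#' @return A list of [protein_record()]s with features attached.
#' @export
read_protein_fasta <- function(fasta_file, features_file = NULL) {
  aa <- Biostrings::readAAStringSet(fasta_file)
  records <- as_protein_records(aa)
  if (!is.null(features_file)) {
    feats <- read_feature_table(features_file)
    records <- lapply(records, function(r) {
      f <- feats[feats$protein_id == r$id, c("name", "start", "end"),
                 drop = FALSE]
      if (nrow(f)) protein_record(r$id, r$sequence, features = f) else r
    })
  }
  records
}

#' @rdname read_protein_fasta
#' @param file path to a tab-separated feature file (header optional;
#'   columns protein_id, name, start, end).
#' @export
read_feature_table <- function(file) {
  first <- readLines(file, n = 1L)
  has_header <- grepl("protein_id", first, fixed = TRUE)
  df <- read.delim(file, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) {
    names(df)[1:4] <- c("protein_id", "name", "start", "end")
  }
  stopifnot(all(c("protein_id", "name", "start", "end") %in% names(df)))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start < 1L | df$start > df$end)) {
    stop("invalid feature interval(s): need 1 <= start <= end")
  }
  df
}

#' Write motif matches as tab-separated text
#'
#' One row per match: protein_id, start, end, anchor_positions
#' (comma-joined), anchor_residues, overlapping_feature, overlap_len.  When
#' the scanned records carry feature annotations, the feature with the
#' largest overlap is reported (empty and 0 when none overlaps).
#'
#' @param matches a `motif_matches` data frame from [scan_sequence()] or a
#'   `scan_summary` from [scan_fasta()].
#' @param file output path.
#' @param records optional list of [protein_record()]s supplying features.
#' @return The written data frame, invisibly.
#' @export
write_match_table <- function(matches, file, records = NULL) {
  if (inherits(matches, "scan_summary")) matches <- matches$matches
  feats_by_id <- list()
  if (!is.null(records)) {
    records <- as_protein_records(records)
    for (r in records) {
      if (!is.null(r$features)) feats_by_id[[r$id]] <- r$features
    }
  }
  out <- data.frame(
    protein_id = matches$protein_id,
    start = matches$start,
    end = matches$end,
    anchor_positions = vapply(matches$anchor_positions, paste,
                              character(1L), collapse = ","),
    anchor_residues = matches$anchor_residues,
    overlapping_feature = "",
    overlap_len = 0L,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(out))) {
    f <- feats_by_id[[out$protein_id[i]]]
    if (is.null(f) || nrow(f) == 0L) next
    ov <- vapply(seq_len(nrow(f)), function(j) {
      feature_overlap(c(out$start[i], out$end[i]), c(f$start[j], f$end[j]))
    }, numeric(1L))
    if (max(ov) > 0) {
      j <- which.max(ov)
      out$overlapping_feature[i] <- f$name[j]
      out$overlap_len[i] <- as.integer(max(ov))
    }
  }
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
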