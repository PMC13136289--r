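#' Construct a gapped-anchor motif pattern
#'
#' A gapped motif is an ordered series of anchor residue classes separated by
#' variable-length spacers.  The default is the conserved ABA-binding
#' signature found in plant phosphodiesterases and canonical ABA receptors:
#' `[DE].{7,9}[RH].{8,11}[FY].{6,7}[HRK]` — four anchors (acidic, basic,
#' aromatic, basic) with bounded gaps of 7-9, 8-11 and 6-7 residues.
#'
#' @param anchors list of character vectors, each the allowed residues of one
#'   anchor (uppercase one-letter codes from the 20 standard amino acids).
#' @param gaps list of length-2 integer vectors `c(min, max)`, one per
#'   inter-anchor spacer; `length(gaps) == length(anchors) - 1`.
#' @return An object of class `motif_pattern`.
#' @seealso [parse_motif()] for the text syntax, [scan_sequence()].
#' @examples
#' motif_pattern(list(c("D", "E"), c("R", "H")), list(c(7, 9)))
#' @export
motif_pattern <- function(anchors, gaps = list()) {
  if (!is.list(anchors) || length(anchors) == 0L) {
    stop("'anchors' must be a non-empty list of residue vectors")
  }
  anchors <- lapply(anchors, function(a) {
    a <- toupper(as.character(a))
    if (length(a) == 0L) stop("anchor residue sets must be non-empty")
    bad <- setdiff(a, AA_STANDARD)
    if (length(bad)) {
      stop("unknown residue letter(s) in anchor: ", paste(bad, collapse = ", "))
    }
    unique(a)
  })
  if (!is.list(gaps)) gaps <- list(gaps)
  if (length(gaps) != length(anchors) - 1L) {
    stop("need exactly ", length(anchors) - 1L,
         " gap(s) for ", length(anchors), " anchor(s), got ", length(gaps))
  }
  gaps <- lapply(gaps, function(g) {
    g <- as.integer(g)
    if (length(g) != 2L || anyNA(g)) stop("each gap must be c(min, max)")
    if (g[1L] < 0L || g[1L] > g[2L]) {
      stop("invalid gap bounds (", g[1L], ",", g[2L],
           "): need 0 <= min <= max")
    }
    g
  })
  structure(list(anchors = anchors, gaps = gaps), class = "motif_pattern")
}

#' Parse a gapped-pattern string into a motif pattern
#'
#' Accepts the PROSITE-like regular-expression syntax used in the literature:
#' bracketed residue classes alternating with `.{min,max}` spacers, e.g.
#' `"[DE].{7,9}[RH].{8,11}[FY].{6,7}[HRK]"`.  A fixed-length spacer may be
#' written `.{n}`.  The parse round-trips through [as.character()].
#'
#' @param pattern_text a single pattern string.
#' @return A [motif_pattern()] object.
#' @examples
#' parse_motif("[DE].{7,9}[RH].{8,11}[FY].{6,7}[HRK]")
#' @export
parse_motif <- function(pattern_text) {
  if (!is.character(pattern_text) || length(pattern_text) != 1L ||
      is.na(pattern_text) || !nzchar(pattern_text)) {
    stop("'pattern_text' must be a single non-empty string")
  }
  txt <- gsub("[[:space:]]", "", pattern_text)
  anchors <- list()
  gaps <- list()
  pos <- 1L
  n <- nchar(txt)
  expect_anchor <- TRUE
  while (pos <= n) {
    rest <- substr(txt, pos, n)
    if (expect_anchor) {
      m <- regmatches(rest, regexec("^\\[([A-Za-z]+)\\]", rest))[[1L]]
      if (length(m) == 0L) {
        stop("malformed pattern near '", substr(rest, 1L, 12L),
             "': expected a bracketed residue class like [DE]")
      }
      anchors[[length(anchors) + 1L]] <- strsplit(toupper(m[2L]), "")[[1L]]
      pos <- pos + nchar(m[1L])
    } else {
      m <- regmatches(rest,
                      regexec("^\\.\\{([0-9]+)(,([0-9]+))?\\}", rest))[[1L]]
      if (length(m) == 0L) {
        stop("malformed pattern near '", substr(rest, 1L, 12L),
             "': expected a spacer like .{7,9}")
      }
      lo <- as.integer(m[2L])
      hi <- if (nzchar(m[4L])) as.integer(m[4L]) else lo
      if (lo > hi) {
        stop("invalid gap bounds in '", m[1L], "': min ", lo,
             " exceeds max ", hi)
      }
      gaps[[length(gaps) + 1L]] <- c(lo, hi)
      pos <- pos + nchar(m[1L])
    }
    expect_anchor <- !expect_anchor
  }
  if (expect_anchor) {
    stop("malformed pattern: trailing spacer without a final anchor")
  }
  motif_pattern(anchors, gaps)
}

#' The default ABA-binding motif
#'
#' @return The four-anchor signature `[DE].{7,9}[RH].{8,11}[FY].{6,7}[HRK]`
#'   as a [motif_pattern()].
#' @export
aba_motif <- function() {
  parse_motif("[DE].{7,9}[RH].{8,11}[FY].{6,7}[HRK]")
}

#' @export
as.character.motif_pattern <- function(x, ...) {
  k <- length(x$anchors)
  out <- character(0)
  for (i in seq_len(k)) {
    out <- c(out, paste0("[", paste(x$anchors[[i]], collapse = ""), "]"))
    if (i < k) {
      g <- x$gaps[[i]]
      out <- c(out, paste0(".{", g[1L], ",", g[2L], "}"))
    }
  }
  paste(out, collapse = "")
}

#' @export
format.motif_pattern <- function(x, ...) as.character(x)

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern> ", as.character(x), "\n",
      "  anchors: ", length(x$anchors),
      ", span ", motif_span_range(x)[1L], "-", motif_span_range(x)[2L],
      " residues\n", sep = "")
  invisible(x)
}

# Minimal and maximal residue span (first to last anchor inclusive).
motif_span_range <- function(pattern) {
  k <- length(pattern$anchors)
  if (k == 1L) return(c(1L, 1L))
  lo <- sum(vapply(pattern$gaps, `[`, integer(1L), 1L)) + k
  hi <- sum(vapply(pattern$gaps, `[`, integer(1L), 2L)) + k
  c(lo, hi)
}
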