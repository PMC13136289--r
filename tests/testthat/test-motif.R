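test_that("pattern parsing handles the signature syntax and round-trips", {
  p <- parse_motif("[DE].{7,9}[RH].{8,11}[FY].{6,7}[HRK]")
  expect_length(p$anchors, 4)
  expect_equal(p$anchors[[1]], c("D", "E"))
  expect_equal(p$anchors[[4]], c("H", "R", "K"))
  expect_equal(p$gaps, list(c(7L, 9L), c(8L, 11L), c(6L, 7L)))
  expect_equal(as.character(p), "[DE].{7,9}[RH].{8,11}[FY].{6,7}[HRK]")
  expect_equal(as.character(parse_motif(as.character(p))), as.character(p))

  one <- parse_motif("[A]")
  expect_length(one$anchors, 1)
  expect_length(one$gaps, 0)

  fixed <- parse_motif("[DE].{7}[RH]")  # fixed-length spacer
  expect_equal(fixed$gaps[[1]], c(7L, 7L))
})

test_that("pattern parsing rejects malformed input with informative errors", {
  expect_error(parse_motif("[DE].{9,7}[RH]"), "min 9 exceeds max 7")
  expect_error(parse_motif("[DE].{7,9}"), "trailing spacer")
  expect_error(parse_motif("DE.{7,9}[RH]"), "bracketed residue class")
  expect_error(parse_motif("[DE][RH]"), "spacer")
  expect_error(motif_pattern(list(c("D", "1"))), "unknown residue")
  expect_error(motif_pattern(list("D", "R"), list(c(5, 3))), "0 <= min <= max")
  expect_error(motif_pattern(list("D", "R"), list()), "exactly 1 gap")
})

test_that("scanning finds the exact anchor tuple in a minimal-span sequence", {
  toy <- paste0("E", strrep("A", 7), "R", strrep("A", 8),
                "Y", strrep("A", 6), "K")
  m <- scan_sequence(toy, aba_motif())
  expect_equal(nrow(m), 1)
  expect_equal(m$anchor_positions[[1]], c(1L, 9L, 18L, 25L))
  expect_equal(m$anchor_residues, "ERYK")
  expect_equal(c(m$start, m$end), c(1L, 25L))
})

test_that("scanning edge cases behave per contract", {
  expect_equal(nrow(scan_sequence("AAAA")), 0)
  expect_equal(nrow(scan_sequence(protein_record("p", "DERFY"),
                                  parse_motif("[W]"))), 0)
  expect_error(scan_sequence("DE RFY"), "non-alphabetic")
  expect_warning(r <- protein_record("p", "deaark*"), "terminator")
  expect_equal(r$sequence, "DEAARK")
  # ambiguity letters are tolerated but never match an anchor class
  expect_equal(nrow(scan_sequence(paste0("X", strrep("A", 7), "B",
                                         strrep("A", 8), "Z",
                                         strrep("A", 6), "U"))), 0)
})

test_that("scan_sequence equals the brute-force enumeration oracle", {
  set.seed(20240917)
  pat <- aba_motif()
  for (i in 1:200) {
    s <- random_seq(sample(30:200, 1), p_ambig = 0.05)
    got <- scan_sequence(s, pat)
    want <- oracle_scan(s, pat)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      got_mat <- do.call(rbind, got$anchor_positions)
      dimnames(want) <- NULL
      expect_equal(got_mat, want)
      # every reported match re-validates against the pattern
      chars <- strsplit(s, "")[[1]]
      for (r in seq_len(nrow(got_mat))) {
        pos <- got_mat[r, ]
        expect_true(all(diff(pos) > 0))
        for (a in seq_along(pat$anchors)) {
          expect_true(chars[pos[a]] %in% pat$anchors[[a]])
        }
        gaps <- diff(pos) - 1L
        for (g in seq_along(pat$gaps)) {
          expect_gte(gaps[g], pat$gaps[[g]][1])
          expect_lte(gaps[g], pat$gaps[[g]][2])
        }
      }
    }
  }
})

test_that("widening gap bounds never removes matches, narrowing never adds", {
  set.seed(42)
  base <- aba_motif()
  wide <- motif_pattern(base$anchors,
                        list(c(6, 10), c(7, 12), c(5, 8)))
  narrow <- motif_pattern(base$anchors,
                          list(c(8, 8), c(9, 10), c(7, 7)))
  key <- function(m) vapply(m$anchor_positions, paste, "", collapse = ",")
  for (i in 1:40) {
    s <- random_seq(150)
    m_base <- key(scan_sequence(s, base))
    expect_true(all(m_base %in% key(scan_sequence(s, wide))))
    expect_true(all(key(scan_sequence(s, narrow)) %in% m_base))
  }
})

test_that("proteome scanning counts proteins once and validates ids", {
  toy <- paste0("E", strrep("A", 7), "R", strrep("A", 8),
                "Y", strrep("A", 6), "K")
  seqs <- c(p1 = "AAAA", p2 = toy, p3 = "GGGG")
  s <- scan_fasta(seqs)
  expect_equal(s$n_proteins, 3)
  expect_equal(s$n_with_match, 1)
  expect_equal(s$fraction_with_match, 1 / 3)
  # a protein with several alternative placements still counts once
  multi <- paste0("E", strrep("A", 7), "RR", strrep("A", 8),
                  "Y", strrep("A", 6), "K")
  s2 <- scan_fasta(c(a = multi))
  expect_gt(nrow(s2$matches), 1)
  expect_equal(s2$n_with_match, 1)
  expect_error(scan_fasta(c(x = "AAAA", x = "CCCC")), "duplicate")
})

test_that("feature overlap follows 1-based inclusive arithmetic", {
  expect_equal(feature_overlap(c(657, 685), c(669, 706)), 17)
  expect_equal(feature_overlap(c(1, 10), c(20, 30)), 0)
  expect_equal(feature_overlap(c(5, 5), c(5, 5)), 1)
  expect_equal(feature_overlap(list(start = 657, end = 685),
                               list(name = "catalytic", start = 669,
                                    end = 706)), 17)
  expect_equal(to_zero_based(657, 685), c(656L, 685L))
  expect_equal(to_one_based(656, 685), c(657L, 685L))
})

test_that("FASTA and feature-table round trips preserve matches", {
  prot <- gen_proteome(seed = 9, n_seq = 8, n_planted = 4)
  fa <- tempfile(fileext = ".fasta")
  write_proteome_fasta(prot, fa)
  recs <- read_protein_fasta(fa)
  expect_length(recs, 8)
  expect_equal(unname(vapply(recs, `[[`, "", "sequence")),
               unname(prot$sequences))

  feat_file <- tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tname\tstart\tend",
               paste(prot$truth$protein_id[1], "planted_region",
                     prot$truth$start[1], prot$truth$end[1], sep = "\t")),
             feat_file)
  recs2 <- read_protein_fasta(fa, feat_file)
  withf <- recs2[[which(vapply(recs2, `[[`, "", "id") ==
                          prot$truth$protein_id[1])]]
  expect_equal(withf$features$name, "planted_region")

  out <- tempfile(fileext = ".tsv")
  tab <- write_match_table(scan_fasta(recs2), out, records = recs2)
  back <- read.delim(out)
  expect_equal(nrow(back), nrow(tab))
  planted_rows <- tab[tab$protein_id == prot$truth$protein_id[1] &
                        tab$start == prot$truth$start[1], ]
  expect_true(any(planted_rows$overlapping_feature == "planted_region"))
  expect_true(all(planted_rows$overlap_len > 0))
})
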