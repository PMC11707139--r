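# a 153 bp synthetic transposon end with GCGGGA planted at 0-based 10, 54, 98
# (1-based bp 11-16, 55-60, 99-104); filler is drawn once under a fixed seed
# and verified free of accidental GCGGGA/TCCCGC before use
planted_end <- function() {
  withr::with_seed(101, {
    repeat {
      filler <- rand_dna(153)
      s <- paste0(substr(filler, 1, 10), "GCGGGA",
                  substr(filler, 17, 54), "GCGGGA",
                  substr(filler, 61, 98), "GCGGGA",
                  substr(filler, 105, 153))
      occ <- gregexpr("GCGGGA|TCCCGC", s)[[1]]
      if (identical(as.integer(occ), c(11L, 55L, 99L))) return(s)
    }
  })
}

test_that("planted subterminal hexamers are recovered at their exact positions", {
  s <- planted_end()
  expect_equal(nchar(s), 153L)
  res <- find_repeated_motifs(c(LE = s), k = 6, min_count = 2)
  top <- res[res$count == max(res$count), ]
  expect_equal(unique(top$motif), "GCGGGA")
  expect_equal(sort(top$start), c(10L, 54L, 98L))
  expect_equal(unique(top$count), 3L)
  expect_true(all(top$orientation == "+"))
  # rank-1 motif comes first
  expect_equal(res$motif[1], "GCGGGA")
})

test_that("reverse-complement occurrences merge under a canonical motif", {
  s <- paste0("GCGGGA", strrep("T", 20), "TCCCGC")
  res <- find_repeated_motifs(c(x = s), k = 6, min_count = 2)
  hex <- res[res$count >= 2 & res$motif == "GCGGGA", ]
  expect_equal(nrow(hex), 2L)
  expect_setequal(hex$orientation, c("+", "-"))
  # without strand merging the two ends are separate singletons
  res1 <- find_repeated_motifs(c(x = s), k = 6, min_count = 2, both_strands = FALSE)
  expect_false("GCGGGA" %in% res1$motif[res1$count >= 2])
})

test_that("motif tallies equal the exhaustive k-mer oracle and self-check", {
  withr::with_seed(103, {
    s <- rand_dna(300)
  })
  got <- find_repeated_motifs(c(x = s), k = 6, min_count = 2, both_strands = TRUE)
  orc <- oracle_kmer_tally(s, 6, both_strands = TRUE)
  orc_counts <- table(orc$motif)
  keep <- names(orc_counts)[orc_counts >= 2]
  orc <- orc[orc$motif %in% keep, ]
  expect_equal(nrow(got), nrow(orc))
  got_sorted <- dplyr::arrange(got, motif, start)
  orc_sorted <- dplyr::arrange(orc, motif, start)
  expect_equal(got_sorted$motif, orc_sorted$motif)
  expect_equal(got_sorted$start, orc_sorted$start)
  expect_equal(got_sorted$orientation, orc_sorted$orientation)
  # occurrences verify their own invariant against the sequence
  for (i in seq_len(nrow(got))) {
    win <- substr(s, got$start[i] + 1, got$start[i] + 6)
    expect_true(win == got$motif[i] || win == oracle_revcomp(got$motif[i]))
  }
})

test_that("palindrome scoring matches closed-form cases", {
  hit <- find_imperfect_palindromes("TTAA", min_len = 4, max_len = 4,
                                    max_mismatches = 0)
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$score, 2L)

  p6 <- find_imperfect_palindromes("GAATTC", min_len = 6, max_len = 6,
                                   max_mismatches = 2, reduce = FALSE)
  expect_equal(p6$mismatches[p6$start == 0 & p6$length == 6], 0L)
  p6b <- find_imperfect_palindromes("GAATTG", min_len = 6, max_len = 6,
                                    max_mismatches = 2, reduce = FALSE)
  expect_equal(p6b$mismatches[p6b$start == 0 & p6b$length == 6], 1L)
})

test_that("palindrome hits equal the brute-force window oracle before reduction", {
  withr::with_seed(107, {
    s <- rand_dna(200)
  })
  got <- find_imperfect_palindromes(c(x = s), min_len = 8, max_len = 14,
                                    max_mismatches = 2, reduce = FALSE)
  orc <- oracle_palindromes(s, 8, 14, 2)
  if (is.null(orc)) {
    expect_equal(nrow(got), 0L)
  } else {
    orc <- orc[order(orc$start, orc$length), ]
    expect_equal(got$start, orc$start)
    expect_equal(got$length, orc$length)
    expect_equal(got$mismatches, orc$mismatches)
  }
  # greedy reduction returns a non-overlapping subset
  red <- find_imperfect_palindromes(c(x = s), min_len = 8, max_len = 14,
                                    max_mismatches = 2, reduce = TRUE)
  if (nrow(red) > 1) {
    expect_true(all(red$start[-1] >= (red$start + red$length)[-nrow(red)]))
  }
})

test_that("palindrome score is invariant under reverse complementation", {
  withr::with_seed(109, {
    wins <- vapply(1:25, function(i) rand_dna(12), "")
  })
  for (w in wins) {
    a <- find_imperfect_palindromes(w, min_len = 12, max_len = 12,
                                    max_mismatches = 6, reduce = FALSE)
    b <- find_imperfect_palindromes(oracle_revcomp(w), min_len = 12, max_len = 12,
                                    max_mismatches = 6, reduce = FALSE)
    expect_equal(a$mismatches[a$start == 0], b$mismatches[b$start == 0])
  }
})

test_that("CKII scanning applies the minimal S/T-X-X-D/E rule", {
  res <- scan_ckii_sites("MSAAE")
  expect_equal(res$residue_index, 2L)
  expect_equal(res$residue, "S")
  expect_equal(res$window, "SAAE")

  expect_equal(nrow(scan_ckii_sites("MGGGG")), 0L)
  expect_equal(nrow(scan_ckii_sites("MSA")), 0L)

  withr::with_seed(113, {
    prot <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 200,
                         replace = TRUE), collapse = "")
  })
  got <- scan_ckii_sites(prot)
  expect_equal(got$residue_index, oracle_ckii(prot))
  expect_true(all(got$residue %in% c("S", "T")))
  expect_true(all(substr(got$window, 4, 4) %in% c("D", "E")))
})
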