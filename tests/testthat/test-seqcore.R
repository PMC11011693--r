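fx <- smim45_sequences()

test_that("FASTA round-trips and the packaged sequences have their documented lengths", {
  expect_equal(length(fx$exon2), 1268L)
  expect_equal(length(fx$mrna68), 207L)
  expect_equal(length(fx$mrna107), 324L)
  expect_equal(length(fx$intervening), 324L)
  expect_equal(length(fx$silencer), 230L)
  expect_equal(length(fx$devseq_rna), 54L)

  set.seed(7)
  recs <- lapply(1:3, function(i)
    seq_record(paste0("r", i), random_dna(sample(10:200, 1)), "dna",
               description = paste("random record", i)))
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, tmp, width = 37L)
  back <- read_fasta(tmp)
  expect_equal(lapply(back, as.character),
               setNames(lapply(recs, as.character), paste0("r", 1:3)))

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), empty)
  expect_length(read_fasta(empty), 0L)

  ## blocks printed with position numbers and spaces parse cleanly
  numbered <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "  1 acgta cgtac", " 11 gt"), numbered)
  expect_equal(as.character(read_fasta(numbered)$x), "acgtacgtacgt")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("acgt", ">x", "acgt"), bad)
  expect_error(read_fasta(bad), "line 1")
})

test_that("translation reproduces the early developmental peptide and obeys the length law", {
  expect_equal(as.character(translate_seq(fx$devseq_rna)),
               "SGLELVRVCGGGMQRDKT")
  expect_equal(as.character(translate_seq("atg")), "M")
  expect_equal(as.character(translate_seq("tga")), "*")
  p107 <- as.character(translate_seq(fx$mrna107))
  expect_equal(substr(p107, 98, 107), "VWGERASMGR")
  expect_error(translate_seq(seq_record("p", "MKV", "protein")), "dna")

  set.seed(11)
  for (rep in 1:20) {
    s <- random_dna(sample(1:30, 1))
    fr <- sample(1:3, 1)
    st <- sample(c("+", "-"), 1)
    expect_equal(length(translate_seq(s, fr, st)),
                 max(0L, (nchar(s) - fr + 1L) %/% 3L))
  }
})

test_that("ORF scanning finds the packaged ORFs and respects the ATG..stop contract", {
  o107 <- find_orfs(fx$mrna107, frame_set = 1L, min_aa = 50L)
  expect_equal(nrow(o107), 1L)
  expect_equal(o107$start, 1L)
  expect_equal(o107$length_aa, 107L)
  expect_equal(o107$end, 324L)  # stop codon included in the nt interval

  o68 <- find_orfs(fx$mrna68, frame_set = 1L, min_aa = 50L)
  expect_equal(o68$length_aa, 68L)
  expect_equal(o68$start, 1L)

  expect_equal(nrow(find_orfs("cccccc")), 0L)

  ## nested starts reported only on request
  s <- "atgaaaatgaaatag"
  expect_equal(nrow(find_orfs(s, 1L)), 1L)
  expect_equal(nrow(find_orfs(s, 1L, all_starts = TRUE)), 2L)
})

test_that("composition matches the documented 107 aa mRNA line and counts always sum", {
  cp <- composition(fx$mrna107)
  expect_equal(cp$length_bp, 324L)
  expect_equal(unname(cp$counts["g"]), 119L)
  expect_equal(unname(cp$percents["g"]), 36)

  cd <- composition(fx$devseq_rna)
  expect_equal(unname(cd$counts["g"]), 25L)
  expect_equal(cd$gc_percent_rounded >= 46 - 1e-9 &&
                 unname(cd$percents["g"]) == 46, TRUE)

  expect_equal(composition("gggg")$percents[["g"]], 100)
  e <- composition(seq_record("e", "", allow_empty = TRUE))
  expect_true(e$undefined)
  expect_equal(e$length_bp, 0L)

  set.seed(3)
  for (rep in 1:10) {
    s <- paste0(random_dna(sample(5:40, 1)), "nn")
    cp <- composition(s)
    expect_equal(sum(cp$counts) + cp$other_count, cp$length_bp)
  }
})

test_that("locate recovers the documented exon-2 coordinates", {
  p68 <- locate(fx$mrna68, fx$exon2, 0L)
  expect_equal(p68$start, 15L)
  expect_equal(p68$end, 221L)
  expect_equal(p68$n_mismatch, 0L)

  ## the printed 107 aa mRNA differs from exon 2 at one base; both fixtures
  ## are kept verbatim, so the scan tolerates mismatches
  p107 <- locate(fx$mrna107, fx$exon2, 2L)
  expect_equal(p107$start, 546L)
  expect_equal(p107$end, 869L)
  expect_equal(p107$n_mismatch, 1L)

  s <- random_dna(40)
  expect_equal(locate(s, s, 0L)$start, 1L)
  expect_error(locate("acgtacgt", "acg"), "longer")

  ## zero-mismatch locate agrees with naive substring search
  set.seed(5)
  for (rep in 1:20) {
    hay <- random_dna(60)
    at <- sample(1:50, 1)
    nd <- substr(hay, at, at + 8)
    naive <- regexpr(nd, hay, fixed = TRUE)[[1]]
    expect_equal(locate(nd, hay, 0L)$start, naive)
  }

  ## ambiguity codes never match
  expect_null(locate("acgt", "annnnn", 0L))
  expect_equal(locate("nn", "aann", 2L)$n_mismatch, 2L)
})

test_that("silencer overlap geometry partitions the packaged silencer", {
  ov <- annotate_silencer_overlaps(fx$mrna68, fx$silencer, fx$intervening)
  expect_equal(ov$overlap_a, 38L)
  expect_equal(ov$overlap_intervening, 192L)
  expect_equal(ov$silencer_len, 230L)
  expect_true(ov$fully_partitioned)

  s <- random_dna(25)
  self <- annotate_silencer_overlaps(s, s, s)
  expect_equal(self$overlap_a, 25L)

  dis <- annotate_silencer_overlaps("aaaa", "cccc", "gggg")
  expect_equal(dis$overlap_a, 0L)
  expect_equal(dis$overlap_intervening, 0L)

  ## overlap is the arg-max of explicit string-equality checks
  set.seed(9)
  for (rep in 1:10) {
    orf <- random_dna(20); sil <- random_dna(15); itv <- random_dna(20)
    ov <- annotate_silencer_overlaps(orf, sil, itv)
    brute_a <- 0L
    for (L in 1:15) if (substr(orf, 21 - L, 20) == substr(sil, 1, L)) brute_a <- L
    expect_equal(ov$overlap_a, brute_a)
  }
})

test_that("tandem repeat scan matches the brute-force oracle and finds the AGAG microsatellite", {
  ## the 4 bp microsatellite in the 3' region of the 107 aa mRNA; the
  ## leftmost-maximal rule may phase the unit as agag or gaga
  runs <- tandem_repeats(fx$mrna107, 4L, 3L)
  hit <- runs[runs$start >= 260 & runs$start <= 295, ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$unit %in% c("agag", "gaga"))
  expect_gte(hit$copies, 6L)

  r <- tandem_repeats("aaaaaaaa", 1L)
  expect_equal(r$unit, "a")
  expect_equal(r$copies, 8L)

  expect_error(tandem_repeats("acgt", 0L), "unit_len")

  set.seed(13)
  for (rep in 1:25) {
    s <- paste(sample(c("a", "g"), 30, replace = TRUE), collapse = "")
    for (u in 1:3) {
      got <- tandem_repeats(s, u, 2L)
      want <- brute_tandem(s, u, 2L)
      expect_equal(nrow(got), length(want))
      if (length(want)) {
        expect_equal(got$start, vapply(want, `[[`, numeric(1), "start"))
        expect_equal(got$copies, vapply(want, `[[`, numeric(1), "copies"))
      }
    }
  }
})

test_that("motif scan finds the silencer motifs", {
  sil <- as.character(fx$silencer)
  for (m in c("ctccc", "gcc", "cctgg", "cagtgg")) {
    hits <- motif_scan(fx$silencer, m)
    expect_gt(nrow(hits), 0)
    ## brute-force position check
    brute <- which(vapply(seq_len(nchar(sil) - nchar(m) + 1L), function(i)
      substr(sil, i, i + nchar(m) - 1L) == m, logical(1)))
    expect_equal(hits$start, brute)
  }
  expect_equal(nrow(motif_scan("acgt", "gg")), 0L)
  expect_error(motif_scan("acgt", ""), "empty motif")
  ## case-insensitive, overlapping occurrences
  expect_equal(motif_scan("aAaA", "aa")$start, 1:3)
})

test_that("reverse complement is an involution consistent with minus-strand translation", {
  expect_equal(reverse_complement("atgc"), "gcat")
  set.seed(17)
  s <- random_dna(33)
  expect_equal(reverse_complement(reverse_complement(s)), s)
  expect_equal(as.character(translate_seq(fx$devseq_rna, 1, "-")),
               as.character(translate_seq(reverse_complement(fx$devseq_rna))))
})
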