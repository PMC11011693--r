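fx <- smim45_sequences()
sch <- scoring_scheme()

test_that("the guidepost ORF is located on both strands of exon 2", {
  hit <- locate_guidepost(fx$exon2, fx$mrna68, sch)
  expect_equal(hit$interval, c(15L, 221L))
  expect_equal(hit$strand, "+")
  expect_equal(hit$identity_pct, 100)

  rc <- reverse_complement(fx$exon2)
  hit_rc <- locate_guidepost(rc, fx$mrna68, sch)
  expect_equal(hit_rc$strand, "-")
  ## same interval after mapping back through the reverse complement
  n <- length(fx$exon2)
  expect_equal(c(n - hit_rc$interval[2] + 1L, n - hit_rc$interval[1] + 1L),
               c(15L, 221L))

  set.seed(37)
  expect_null(locate_guidepost(random_dna(2000), fx$mrna68, sch))
})

test_that("the candidate window sits 3' of the guidepost and is clipped at the region end", {
  hit <- locate_guidepost(fx$exon2, fx$mrna68, sch)
  win <- extract_candidate_window(fx$exon2, hit, downstream_bp = 1047L)
  expect_equal(win$interval, c(222L, 1268L))
  expect_false(win$empty)
  ## the window contains the 107 aa mRNA locus at exon positions 546-869
  loc107 <- locate(fx$mrna107, as.character(win$seq), 2L)
  expect_equal(loc107$start + win$interval[1] - 1L, 546L)

  edge_hit <- list(interval = c(10L, 1268L), strand = "+")
  expect_true(extract_candidate_window(fx$exon2, edge_hit)$empty)
  expect_error(extract_candidate_window(fx$exon2, NULL), "synteny")

  ## strand symmetry: the minus-strand window holds the same sequence
  rc <- reverse_complement(fx$exon2)
  hit_rc <- locate_guidepost(rc, fx$mrna68, sch)
  win_rc <- extract_candidate_window(rc, hit_rc, downstream_bp = 1047L)
  expect_equal(as.character(win_rc$seq), as.character(win$seq))
})

test_that("the early developmental peptide is detected in its source window", {
  dev <- translate_seq(fx$devseq_rna)
  hit <- locate_guidepost(fx$exon2, fx$mrna68, sch)
  win <- extract_candidate_window(fx$exon2, hit)
  found <- detect_devseq(win$seq, dev, sch)
  expect_s3_class(found, "homology_hit")
  expect_equal(percent_identity(found$aa_alignment, "columns"), 100)
  expect_equal(found$aa_alignment$n_columns, 18L)
  ## the nt interval maps back to the 54-nt source inside the window
  ntseq <- substr(as.character(win$seq), found$nt_interval[1],
                  found$nt_interval[2])
  expect_equal(ntseq, as.character(fx$devseq_rna))

  ## a planted mouse-like homolog scores 12/17 against the human peptide
  mouse_aa <- "SGLE*VTVYGGGVQKGKT"
  ## encode it (reusing the human codons where the residues agree)
  codons <- c("tca","ggc","ttg","gaa","tga","gtg","acg","gtg","tat","ggt",
              "ggg","ggt","gtg","cag","aaa","ggg","aaa","acc")
  set.seed(41)
  planted <- paste0(random_dna(60), paste(codons, collapse = ""), random_dna(60))
  got <- detect_devseq(planted, translate_seq(fx$devseq_rna), sch)
  ## the head-to-head convention scores the homolog 12/17; the local
  ## alignment clips trailing mismatch-rich columns but lands on the
  ## planted copy
  expect_equal(devseq_identity(translate_seq(fx$devseq_rna), mouse_aa),
               100 * 12 / 17)
  expect_gte(got$aa_alignment$n_identical, 8L)
  expect_true(got$nt_interval[1] >= 55L && got$nt_interval[2] <= 120L)

  expect_null(detect_devseq("ac", dev, sch))

  ## under the null, windows of matched length and composition rarely reach
  ## a reportable call
  set.seed(43)
  cfg <- twilight_config()
  hits <- vapply(1:40, function(i) {
    w <- random_dna(length(win$seq), gc = 0.6)
    !is.null(detect_devseq(w, dev, sch, cfg = cfg))
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})

test_that("an exact nucleotide copy of the peptide yields 100% identity in exactly one frame", {
  dev <- translate_seq(fx$devseq_rna)
  set.seed(47)
  for (off in 0:2) {
    w <- paste0(random_dna(30 + off), as.character(fx$devseq_rna), random_dna(30))
    perfect <- 0L
    for (fr in 1:3) {
      p <- as.character(translate_seq(w, fr))
      if (grepl(as.character(dev), p, fixed = TRUE)) perfect <- perfect + 1L
    }
    expect_equal(perfect, 1L)
    hit <- detect_devseq(w, dev, sch)
    expect_equal(percent_identity(hit$aa_alignment, "columns"), 100)
  }
})

test_that("progression profiling covers the whole target on self-comparison", {
  target <- translate_seq(fx$mrna107)
  target <- seq_record("t107", substr(as.character(target), 1, 107), "protein")
  prof <- progression_profile(fx$mrna107, target, sch)
  expect_equal(prof$total_identical, 107L)
  expect_equal(max(prof$blocks$length), 107L)
  expect_length(prof$frameshift_breakpoints, 0L)
  expect_true(prof$has_start_met)
})

test_that("deleting one agag unit causes a frameshift that truncates the C-terminal block", {
  target <- seq_record("t107",
                       substr(as.character(translate_seq(fx$mrna107)), 1, 107),
                       "protein")
  s <- as.character(fx$mrna107)
  mutant <- paste0(substr(s, 1, 268), substr(s, 273, nchar(s)))  # drop 4 bp unit
  prof <- progression_profile(mutant, target, sch)
  expect_gt(length(prof$frameshift_breakpoints), 0L)
  ## every identity block in the original frame ends before the C-terminal
  ## decapeptide (target positions 98-107) ...
  f1 <- prof$blocks[prof$blocks$frame == 1L, ]
  expect_true(all(f1$start + f1$length - 1L < 98L))
  ## ... which reappears in a different reading frame downstream of the
  ## slippage site, exactly as a frameshifted homolog should
  tail_blocks <- prof$blocks[prof$blocks$start + prof$blocks$length - 1L >= 98L, ]
  expect_gt(nrow(tail_blocks), 0L)
  expect_true(all(tail_blocks$frame != 1L))
})

test_that("random windows show little identity-block coverage", {
  target <- seq_record("t107",
                       substr(as.character(translate_seq(fx$mrna107)), 1, 107),
                       "protein")
  set.seed(53)
  cov <- vapply(1:10, function(i)
    progression_profile(random_dna(324, gc = 0.6), target, sch)$total_identical,
    integer(1))
  expect_lt(mean(cov), 25)
})
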