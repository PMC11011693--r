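## Synteny-anchored homolog location. The caller supplies, per species, the
## genomic segment between the two syntenic anchor genes; a deeply conserved
## guidepost ORF is located inside it by local alignment, and the candidate
## region for the de novo ORF is the window downstream of the guidepost on
## its strand. Region coordinates are 1-based inclusive on the input strand.

#' Locate the conserved guidepost ORF in a genomic region
#'
#' Best local alignment of the guidepost nucleotide sequence against both
#' strands of the region. The hit is accepted if column identity is at least
#' `min_identity` percent and the aligned length covers at least `min_cov`
#' of the guidepost; otherwise `NULL` (absence is a valid result).
#'
#' @param region DNA [seq_record()] or character; the inter-anchor segment.
#' @param guidepost_nt DNA sequence of the guidepost ORF mRNA.
#' @param scheme A [scoring_scheme()].
#' @param min_identity Identity floor in percent (default 60).
#' @param min_cov Minimum aligned fraction of the guidepost (default 0.5).
#' @return `NULL`, or a list `(interval, strand, identity_pct, score,
#'   alignment)` with `interval` in region coordinates on the input strand.
#' @export
locate_guidepost <- function(region, guidepost_nt, scheme = scoring_scheme(),
                             min_identity = 60, min_cov = 0.5) {
  reg <- as_residues(region, "dna")
  gp <- as_residues(guidepost_nt, "dna")
  n <- nchar(reg)
  fwd <- local_align(gp, reg, scheme)
  rev <- local_align(gp, reverse_complement(reg), scheme)
  use_rev <- rev$score > fwd$score
  aln <- if (use_rev) rev else fwd
  if (aln$n_columns == 0L) return(NULL)
  ident <- percent_identity(aln, "columns")
  gp_cov <- (aln$a_interval[2] - aln$a_interval[1] + 1L) / nchar(gp)
  if (ident < min_identity || gp_cov < min_cov) return(NULL)
  interval <- if (use_rev) {
    c(n - aln$b_interval[2] + 1L, n - aln$b_interval[1] + 1L)
  } else {
    aln$b_interval
  }
  list(interval = as.integer(interval),
       strand = if (use_rev) "-" else "+",
       identity_pct = ident,
       score = aln$score,
       alignment = aln)
}

#' Candidate window downstream of the guidepost
#'
#' Returns the `downstream_bp` nucleotides 3' of the guidepost hit on its
#' strand, clipped at the region end. The window sequence is returned
#' oriented 5'->3' on the guidepost strand.
#'
#' @param region DNA [seq_record()] or character.
#' @param guidepost_hit Result of [locate_guidepost()] (required).
#' @param downstream_bp Window size in bp (default 1200, sized to span an
#'   intervening sequence plus silencer plus target ORF with margin).
#' @return A list `(interval, strand, seq, empty)`; `interval` in region
#'   coordinates, `seq` a DNA [seq_record()] on the hit strand; `empty` is
#'   TRUE when the guidepost abuts the region end.
#' @export
extract_candidate_window <- function(region, guidepost_hit,
                                     downstream_bp = 1200L) {
  if (is.null(guidepost_hit)) stop("guidepost_hit is required (synteny prerequisite)")
  reg <- as_residues(region, "dna")
  n <- nchar(reg)
  if (guidepost_hit$strand == "+") {
    s <- guidepost_hit$interval[2] + 1L
    e <- min(s + downstream_bp - 1L, n)
    empty <- s > n
    res <- if (empty) "" else substr(reg, s, e)
  } else {
    e <- guidepost_hit$interval[1] - 1L
    s <- max(1L, e - downstream_bp + 1L)
    empty <- e < 1L
    res <- if (empty) "" else reverse_complement(substr(reg, s, e))
  }
  list(interval = if (empty) c(NA_integer_, NA_integer_) else as.integer(c(s, e)),
       strand = guidepost_hit$strand,
       seq = seq_record("window", res, "dna", allow_empty = TRUE),
       empty = empty)
}

#' Detect the early developmental peptide in a candidate window
#'
#' Translates the window in frames 1-3 (on the window's own strand), locally
#' aligns each frame's protein against the query peptide, and reports the
#' best frame by score as a homology hit. If a twilight configuration is
#' supplied, hits that would classify as "none" are dropped.
#'
#' @param window DNA [seq_record()] or character (already oriented).
#' @param dev_aa Protein query ([seq_record()] or character).
#' @param scheme A [scoring_scheme()]; its match/mismatch scores are reused
#'   at the amino-acid level.
#' @param cfg Optional [twilight_config()] used as a reporting threshold.
#' @param synteny Logical flag recorded on the hit (guidepost context).
#' @return `NULL`, or a list of class `homology_hit`: `frame`, `aa_alignment`,
#'   `nt_interval` (window coordinates), `identity_pct`, `evalue`, `synteny`.
#' @export
detect_devseq <- function(window, dev_aa, scheme = scoring_scheme(),
                          cfg = NULL, synteny = TRUE) {
  res <- as_residues(window, "dna")
  if (nchar(res) < 3L) return(NULL)
  q <- as_residues(dev_aa, "protein")
  best <- NULL
  for (fr in 1:3) {
    prot <- as.character(translate_seq(res, frame = fr))
    if (!nzchar(prot)) next
    aln <- local_align(q, prot, scheme, alphabet = "protein")
    if (is.null(best) || aln$score > best$aln$score)
      best <- list(frame = fr, prot = prot, aln = aln)
  }
  if (is.null(best) || best$aln$n_columns == 0L) return(NULL)
  aln <- best$aln
  ident <- percent_identity(aln, "columns")
  ev <- evalue(aln$score, m = nchar(q), n = nchar(best$prot), scheme)
  nt_start <- (aln$b_interval[1] - 1L) * 3L + best$frame
  nt_end <- aln$b_interval[2] * 3L + best$frame - 1L
  hit <- structure(list(frame = best$frame,
                        aa_alignment = aln,
                        nt_interval = c(nt_start, nt_end),
                        identity_pct = ident,
                        evalue = ev$evalue,
                        synteny = synteny),
                   class = "homology_hit")
  if (!is.null(cfg)) {
    lbl <- classify_similarity(ident, ev$evalue, synteny, aln$n_columns, cfg)
    if (lbl == "none") return(NULL)
  }
  hit
}

#' Progression profile of a growing ORF
#'
#' Globally aligns each frame translation of the window against the target
#' protein and extracts maximal runs of identical aligned columns of length
#' at least `min_block`, mapped to target coordinates. Where blocks from
#' several frames cover the same target position, the longest block wins;
#' `frameshift_breakpoints` are target positions at which the best-matching
#' frame changes between consecutive covered positions.
#'
#' @param window DNA [seq_record()] or character.
#' @param target_aa Protein [seq_record()] or character; the mature ORF.
#' @param scheme A [scoring_scheme()].
#' @param min_block Minimum identity-block length in residues (default 3).
#' @return A list of class `progression_profile`: `blocks` (data.frame with
#'   `frame`, `start`, `length` in target coordinates), `total_identical`
#'   (distinct target positions covered), `has_start_met`,
#'   `frameshift_breakpoints`.
#' @export
progression_profile <- function(window, target_aa, scheme = scoring_scheme(),
                                min_block = 3L) {
  tgt <- as_residues(target_aa, "protein")
  res <- as_residues(window, "dna")
  nt <- nchar(tgt)
  blocks <- list()
  for (fr in 1:3) {
    prot <- as.character(translate_seq(res, frame = fr))
    if (nchar(prot) == 0L) next
    aln <- global_align(tgt, prot, scheme, alphabet = "protein")
    av <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
    bv <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
    tpos <- cumsum(av != "-")          # target coordinate per column
    ident <- av != "-" & bv != "-" & av == bv
    r <- rle(ident)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_block)) {
      blocks[[length(blocks) + 1L]] <- data.frame(
        frame = fr, start = tpos[starts[k]], length = r$lengths[k])
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(frame = integer(), start = integer(), length = integer())
  ## assign each covered target position to the longest covering block
  owner <- integer(nt)                  # 0 = uncovered, else block row
  if (nrow(blocks)) {
    ord <- order(blocks$length)         # longer blocks assigned last -> win
    for (i in ord) {
      idx <- blocks$start[i]:(blocks$start[i] + blocks$length[i] - 1L)
      owner[idx] <- i
    }
  }
  covered <- which(owner > 0L)
  frames_at <- ifelse(owner > 0L, blocks$frame[pmax(owner, 1L)], NA_integer_)
  breakpoints <- integer()
  if (length(covered) > 1L) {
    for (j in seq_len(length(covered) - 1L)) {
      p1 <- covered[j]; p2 <- covered[j + 1L]
      if (frames_at[p1] != frames_at[p2]) breakpoints <- c(breakpoints, p2)
    }
  }
  structure(list(blocks = blocks,
                 total_identical = length(covered),
                 has_start_met = length(covered) > 0L && covered[1L] == 1L &&
                   substr(tgt, 1L, 1L) == "M",
                 frameshift_breakpoints = breakpoints),
            class = "progression_profile")
}
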