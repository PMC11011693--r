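## Substitution classification across an ancestor / intermediate / descendant
## triple, wobble (synonymous) analysis, and repeat-slippage event detection.
## The triple view mirrors a species ladder: a change present in the
## intermediate AND inherited by the descendant is "evolutionarily fixed"
## (biased); a change confined to the intermediate lineage is "random"
## (a dead end).

#' Classify substitutions across an aligned sequence triple
#'
#' Columns are categorised as: `conserved` (all three equal), `fixed`
#' (intermediate and descendant share a state differing from the ancestor),
#' `random_mid` (the intermediate differs from both ancestor and descendant
#' - a lineage-specific dead end, including apparent reversions),
#' `desc_specific` (only the descendant differs), `other` (any gap). The
#' categories partition the columns.
#'
#' @param anc,mid,desc Aligned nucleotide strings of equal length (gaps `-`).
#' @return A list of class `mutation_sites`: `sites` (data.frame `column`,
#'   `anc`, `mid`, `desc`, `category`) and `counts` (named integer vector).
#' @examples
#' classify_triple("ag", "gg", "gg")$counts
#' @export
classify_triple <- function(anc, mid, desc) {
  a <- strsplit(tolower(as.character(anc)), "", fixed = TRUE)[[1]]
  m <- strsplit(tolower(as.character(mid)), "", fixed = TRUE)[[1]]
  d <- strsplit(tolower(as.character(desc)), "", fixed = TRUE)[[1]]
  if (length(unique(c(length(a), length(m), length(d)))) != 1L)
    stop("aligned sequences must have equal length")
  gap <- a == "-" | m == "-" | d == "-"
  category <- ifelse(gap, "other",
              ifelse(a == m & m == d, "conserved",
              ifelse(m == d & m != a, "fixed",
              ifelse(m != a & m != d, "random_mid",
              "desc_specific"))))
  sites <- data.frame(column = seq_along(a), anc = a, mid = m, desc = d,
                      category = category, stringsAsFactors = FALSE)
  cats <- c("conserved", "fixed", "random_mid", "desc_specific", "other")
  counts <- vapply(cats, function(cc) sum(category == cc), integer(1))
  structure(list(sites = sites, counts = counts), class = "mutation_sites")
}

#' Scoring scheme for aligning orthologous segments
#'
#' Global comparison of orthologous genomic segments calls for much stiffer
#' gap penalties than a local similarity search: at the gap costs tuned for
#' search (open 5, extend 2 against match 2 / mismatch -3), sequences a few
#' tens of percent diverged accumulate compensating micro-gaps that shift
#' the register of whole segments. With gap open 12 / extend 6 a gap is
#' only opened where an actual insertion or deletion forces one, which is
#' the regime substitution classification and indel detection need.
#'
#' @return A [scoring_scheme()] with `gap_open = 12`, `gap_extend = 6`.
#' @export
ortholog_scheme <- function() scoring_scheme(gap_open = 12, gap_extend = 6)

#' Project two pairwise alignments into a three-row alignment
#'
#' Globally aligns the intermediate sequence against the ancestor and
#' against the descendant, then projects both alignments onto the
#' intermediate's positions (the spine). Ancestor- or descendant-specific
#' insertions relative to the intermediate are dropped; deletions appear as
#' gaps and classify as `other`.
#'
#' @param anc,mid,desc DNA [seq_record()]s or characters.
#' @param scheme A [scoring_scheme()]; defaults to [ortholog_scheme()].
#' @return A list of three equal-length aligned strings `anc`, `mid`,
#'   `desc`, each column anchored at one intermediate-sequence position.
#' @export
align_triple <- function(anc, mid, desc, scheme = ortholog_scheme()) {
  project <- function(aln) {
    ## per mid position, the character aligned to it ('-' if deleted)
    mv <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
    ov <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
    ov[mv != "-"]
  }
  a1 <- global_align(mid, anc, scheme)
  a2 <- global_align(mid, desc, scheme)
  list(anc = paste(project(a1), collapse = ""),
       mid = as_residues(mid, "dna"),
       desc = paste(project(a2), collapse = ""))
}

#' Wobble-position report for two in-frame coding sequences
#'
#' Codon-by-codon comparison of two coding sequences starting at codon
#' position 1. A codon with one or more nucleotide differences is synonymous
#' when both codons translate to the same amino acid.
#'
#' @param orf_a,orf_b In-frame DNA sequences of equal length divisible by 3.
#' @return A list of class `wobble_report`: `n_nt_diffs`, `n_synonymous`,
#'   `n_nonsynonymous` (codon counts), `n_third_position` (nucleotide
#'   differences at codon position 3).
#' @examples
#' wobble_report("gga", "ggg")  # third-position synonymous change
#' @export
wobble_report <- function(orf_a, orf_b) {
  ra <- as_residues(orf_a, "dna")
  rb <- as_residues(orf_b, "dna")
  if (nchar(ra) != nchar(rb)) stop("sequences must have equal length")
  if (nchar(ra) %% 3L != 0L) stop("length must be divisible by 3")
  av <- strsplit(ra, "", fixed = TRUE)[[1]]
  bv <- strsplit(rb, "", fixed = TRUE)[[1]]
  diff <- av != bv
  codon_pos <- rep_len(1:3, length(av))
  code <- genetic_code()$table
  n_codon <- length(av) %/% 3L
  starts <- 3L * (seq_len(n_codon) - 1L) + 1L
  ca <- substring(ra, starts, starts + 2L)
  cb <- substring(rb, starts, starts + 2L)
  changed <- ca != cb
  syn <- changed & !is.na(code[ca]) & !is.na(code[cb]) & code[ca] == code[cb]
  structure(list(n_nt_diffs = sum(diff),
                 n_synonymous = sum(syn),
                 n_nonsynonymous = sum(changed) - sum(syn),
                 n_third_position = sum(diff & codon_pos == 3L)),
            class = "wobble_report")
}

#' Detect insertion/deletion events and repeat slippage between two sequences
#'
#' Globally aligns `a` against `b`; every maximal gap run becomes an event
#' (`deletion` when `b` lacks sequence present in `a`, `insertion` when `b`
#' gains sequence). An event is a slippage candidate when the gapped-out
#' string consists of whole copies of a unit of length at most
#' `unit_len_max` and an adjacent window in the carrying sequence repeats
#' that unit - the signature of slipped-strand mispairing at a tandem
#' repeat. Events whose length is not a multiple of 3 shift the reading
#' frame.
#'
#' @param a,b DNA [seq_record()]s or characters.
#' @param unit_len_max Maximum repeat-unit length considered (default 6).
#' @param scheme A [scoring_scheme()]; defaults to [ortholog_scheme()].
#' @return A data.frame of class `repeat_events`: `position` (1-based in
#'   `a` coordinates, position of the column preceding the gap), `unit`
#'   (the gapped string), `kind`, `slippage_candidate`, `frame_consequence`.
#' @export
detect_repeat_events <- function(a, b, unit_len_max = 6L,
                                 scheme = ortholog_scheme()) {
  aln <- global_align(a, b, scheme)
  av <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  bv <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  apos <- cumsum(av != "-")
  events <- list()
  for (row in list(list(g = bv, other = av, kind = "deletion"),
                   list(g = av, other = bv, kind = "insertion"))) {
    r <- rle(row$g == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      cols <- starts[k]:ends[k]
      gstr <- paste(row$other[cols], collapse = "")
      carrier <- paste(row$other[row$other != "-"], collapse = "")
      ## position of the gap within the carrier sequence
      cpos <- sum(row$other[seq_len(starts[k] - 1L)] != "-")
      L <- nchar(gstr)
      slip <- FALSE
      for (u in seq_len(min(unit_len_max, L))) {
        if (L %% u != 0L) next
        unit <- substr(gstr, 1L, u)
        if (paste(rep(unit, L %/% u), collapse = "") != gstr) next
        before <- if (cpos >= u) substr(carrier, cpos - u + 1L, cpos) else ""
        after <- substr(carrier, cpos + L + 1L, cpos + L + u)
        if (identical(before, unit) || identical(after, unit)) { slip <- TRUE; break }
      }
      events[[length(events) + 1L]] <- data.frame(
        position = if (starts[k] > 1L) apos[starts[k] - 1L] else 0L,
        unit = gstr, kind = row$kind, slippage_candidate = slip,
        frame_consequence = if (L %% 3L != 0L) "frameshift" else "none",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, events)
  if (is.null(out))
    out <- data.frame(position = integer(), unit = character(),
                      kind = character(), slippage_candidate = logical(),
                      frame_consequence = character(), stringsAsFactors = FALSE)
  class(out) <- c("repeat_events", class(out))
  out
}

#' C-terminal consequence of a coding change
#'
#' Translates both mRNAs in frame 1 and reports the longest shared
#' amino-acid prefix and the divergent tails, exposing the downstream
#' protein consequence of a frameshift.
#'
#' @param mrna_a,mrna_b DNA [seq_record()]s or characters.
#' @return A list: `shared_prefix_aa_len`, `a_tail`, `b_tail`.
#' @export
cterminal_consequence <- function(mrna_a, mrna_b) {
  pa <- as.character(translate_seq(mrna_a))
  pb <- as.character(translate_seq(mrna_b))
  k <- .common_prefix_len(pa, pb)
  list(shared_prefix_aa_len = k,
       a_tail = substr(pa, k + 1L, nchar(pa)),
       b_tail = substr(pb, k + 1L, nchar(pb)))
}
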