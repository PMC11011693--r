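#' Scoring scheme with Karlin-Altschul parameters
#'
#' Match/mismatch scores with affine gaps: a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`. The defaults are the standard blastn
#' settings for somewhat-similar sequences (reward 2, penalty -3, gap open 5,
#' extend 2). `lambda` is the Karlin-Altschul scale for the ungapped score
#' system under the given base frequencies; it is computed by bisection
#' unless supplied. `K` defaults to 0.1 and is configurable; because lambda
#' and K describe the ungapped system, absolute Expect values differ from
#' gapped BLAST values and are meaningful for ordering and thresholding.
#'
#' @param match Match reward (> 0).
#' @param mismatch Mismatch penalty (< 0).
#' @param gap_open,gap_extend Affine gap costs (>= 0, charged positively).
#' @param lambda Karlin-Altschul lambda; computed if `NULL`.
#' @param K Karlin-Altschul K.
#' @param base_freqs Background letter frequencies (must sum to 1).
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = 5,
                           gap_extend = 2, lambda = NULL, K = 0.1,
                           base_freqs = rep(0.25, 4)) {
  if (!(match > 0 && mismatch < 0)) stop("need match > 0 > mismatch")
  if (gap_open < 0 || gap_extend < 0) stop("gap costs must be >= 0")
  if (abs(sum(base_freqs) - 1) > 1e-8) stop("base_freqs must sum to 1")
  if (K <= 0) stop("K must be positive")
  if (is.null(lambda))
    lambda <- karlin_altschul_lambda(match, mismatch, base_freqs)
  if (lambda <= 0) stop("lambda must be positive")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 base_freqs = base_freqs),
            class = "scoring_scheme")
}

#' Karlin-Altschul lambda for a match/mismatch score system
#'
#' Solves \eqn{\sum_{ij} p_i p_j e^{\lambda s(i,j)} = 1} for \eqn{\lambda > 0}
#' by bisection (tolerance 1e-9). With match score `a`, mismatch score `b`
#' and identical-letter probability \eqn{q = \sum_i p_i^2} this is
#' \eqn{q e^{\lambda a} + (1-q) e^{\lambda b} = 1}, which has a unique
#' positive root whenever the expected score is negative.
#'
#' @param match,mismatch Scores (match > 0 > mismatch).
#' @param base_freqs Background letter frequencies.
#' @return The positive root lambda.
#' @examples
#' karlin_altschul_lambda(1, -1)  # log(3) for uniform base frequencies
#' @export
karlin_altschul_lambda <- function(match, mismatch, base_freqs = rep(0.25, 4)) {
  q <- sum(base_freqs^2)
  es <- q * match + (1 - q) * mismatch
  if (es >= 0) stop("expected score must be negative for lambda to exist")
  f <- function(l) q * exp(l * match) + (1 - q) * exp(l * mismatch) - 1
  hi <- 1
  while (f(hi) <= 0) hi <- hi * 2
  lo <- 0
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Expect value of an alignment score
#'
#' \eqn{E = K m n e^{-\lambda S}} for search-space lengths m, n. Computed in
#' log space for numerical range.
#'
#' @param score Alignment score S.
#' @param m,n Lengths of the two search spaces (> 0).
#' @param scheme A [scoring_scheme()] supplying lambda and K.
#' @return A list of class `expect_value`: `score`, `m`, `n`, `evalue`,
#'   `log10_evalue`.
#' @export
evalue <- function(score, m, n, scheme) {
  if (m <= 0 || n <= 0) stop("m and n must be positive")
  loge <- log(scheme$K) + log(m) + log(n) - scheme$lambda * score
  structure(list(score = score, m = m, n = n,
                 evalue = exp(loge), log10_evalue = loge / log(10)),
            class = "expect_value")
}

## Substitution matrix over the characters of both sequences. Identity
## scoring: diagonal = match except that any pairing involving an ambiguity
## code scores mismatch. '*' is an ordinary symbol.
.subst_matrix <- function(chars, scheme, alphabet) {
  m <- matrix(scheme$mismatch, length(chars), length(chars),
              dimnames = list(chars, chars))
  diag(m) <- scheme$match
  if (alphabet == "dna") {
    amb <- setdiff(chars, c("a", "c", "g", "t"))
    m[amb, ] <- scheme$mismatch
    m[, amb] <- scheme$mismatch
  } else {
    amb <- intersect(chars, "X")
    m[amb, ] <- scheme$mismatch
    m[, amb] <- scheme$mismatch
  }
  m
}

.alignment_from_pa <- function(pa, mode) {
  a_al <- as.character(Biostrings::pattern(pa))
  b_al <- as.character(Biostrings::subject(pa))
  if (nchar(a_al) == 0L) {           # empty local alignment (score clamped to 0)
    return(structure(list(aligned_a = "", aligned_b = "", score = 0,
                          a_interval = c(NA_integer_, NA_integer_),
                          b_interval = c(NA_integer_, NA_integer_),
                          n_identical = 0L, n_columns = 0L,
                          n_gap_columns = 0L, mode = mode),
                     class = "pairwise_alignment"))
  }
  av <- strsplit(a_al, "", fixed = TRUE)[[1]]
  bv <- strsplit(b_al, "", fixed = TRUE)[[1]]
  gap <- av == "-" | bv == "-"
  structure(list(
    aligned_a = a_al, aligned_b = b_al,
    score = Biostrings::score(pa),
    a_interval = c(Biostrings::start(Biostrings::pattern(pa)),
                   Biostrings::end(Biostrings::pattern(pa))),
    b_interval = c(Biostrings::start(Biostrings::subject(pa)),
                   Biostrings::end(Biostrings::subject(pa))),
    n_identical = sum(!gap & av == bv),
    n_columns = length(av),
    n_gap_columns = sum(gap),
    mode = mode
  ), class = "pairwise_alignment")
}

## pairwiseAlignment trims terminal gap columns from its aligned views when
## a global alignment begins or ends in an indel; restore them so that a
## global alignment always spans both sequences end to end.
.pad_global <- function(aln, ra, rb) {
  a1 <- aln$a_interval[1]; a2 <- aln$a_interval[2]
  b1 <- aln$b_interval[1]; b2 <- aln$b_interval[2]
  na <- nchar(ra); nb <- nchar(rb)
  if (a1 > 1L || b1 > 1L) {
    lead_a <- paste0(substr(ra, 1L, a1 - 1L), strrep("-", b1 - 1L))
    lead_b <- paste0(strrep("-", a1 - 1L), substr(rb, 1L, b1 - 1L))
    aln$aligned_a <- paste0(lead_a, aln$aligned_a)
    aln$aligned_b <- paste0(lead_b, aln$aligned_b)
  }
  if (a2 < na || b2 < nb) {
    aln$aligned_a <- paste0(aln$aligned_a, substr(ra, a2 + 1L, na),
                            strrep("-", nb - b2))
    aln$aligned_b <- paste0(aln$aligned_b, strrep("-", na - a2),
                            substr(rb, b2 + 1L, nb))
  }
  aln$a_interval <- c(1L, na)
  aln$b_interval <- c(1L, nb)
  aln$n_columns <- nchar(aln$aligned_a)
  av <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  bv <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  aln$n_gap_columns <- sum(av == "-" | bv == "-")
  aln
}

.pairwise <- function(a, b, scheme, type, alphabet) {
  ra <- if (alphabet == "dna") as_residues(a, "dna") else as_residues(a, "protein")
  rb <- if (alphabet == "dna") as_residues(b, "dna") else as_residues(b, "protein")
  if (!nzchar(ra) || !nzchar(rb)) stop("cannot align an empty sequence")
  chars <- sort(unique(strsplit(paste0(ra, rb), "", fixed = TRUE)[[1]]))
  mat <- .subst_matrix(chars, scheme, alphabet)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::BString(ra), Biostrings::BString(rb),
    substitutionMatrix = mat,
    gapOpening = scheme$gap_open - scheme$gap_extend,
    gapExtension = scheme$gap_extend,
    type = type)
  aln <- .alignment_from_pa(pa, mode = type)
  if (type == "global") aln <- .pad_global(aln, ra, rb)
  aln
}

#' Pairwise alignment with affine gaps
#'
#' `global_align()` is Needleman-Wunsch-style end-to-end alignment,
#' `local_align()` Smith-Waterman highest-scoring local alignment. A gap of
#' length L costs `gap_open + (L - 1) * gap_extend`. Local alignments have
#' score >= 0; an all-negative comparison yields an empty alignment.
#'
#' @param a,b Sequences ([seq_record()] or character); both the same alphabet.
#' @param scheme A [scoring_scheme()].
#' @param alphabet `"dna"` or `"protein"`.
#' @return A list of class `pairwise_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `score`, `a_interval`, `b_interval`
#'   (1-based inclusive source coordinates), `n_identical`, `n_columns`,
#'   `n_gap_columns`, `mode`.
#' @export
global_align <- function(a, b, scheme = scoring_scheme(), alphabet = "dna") {
  .pairwise(a, b, scheme, "global", alphabet)
}

#' @rdname global_align
#' @export
local_align <- function(a, b, scheme = scoring_scheme(), alphabet = "dna") {
  .pairwise(a, b, scheme, "local", alphabet)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<%s alignment> score %.1f, %d/%d identical (%d gap cols)\n",
              x$mode, x$score, x$n_identical, x$n_columns, x$n_gap_columns))
  cat(" a:", x$aligned_a, "\n b:", x$aligned_b, "\n")
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' The numerator is the number of identical aligned columns; the denominator
#' depends on the convention: `"columns"` uses all alignment columns,
#' `"shorter_seq"` the length of the shorter source sequence, and
#' `"exclude_stops"` all columns except those where either aligned symbol is
#' `*` (identities in excluded columns are not counted).
#'
#' @param aln A `pairwise_alignment`.
#' @param convention Denominator convention.
#' @return Percent identity (unrounded). Use [trunc_percent()] or
#'   [round_half_up()] for display.
#' @export
percent_identity <- function(aln,
                             convention = c("columns", "shorter_seq",
                                            "exclude_stops")) {
  convention <- match.arg(convention)
  av <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  bv <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  if (convention == "exclude_stops") {
    keep <- av != "*" & bv != "*"
    av <- av[keep]; bv <- bv[keep]
  }
  num <- sum(av == bv & av != "-")
  den <- switch(convention,
    columns = aln$n_columns,
    shorter_seq = {
      la <- nchar(gsub("-", "", aln$aligned_a, fixed = TRUE))
      lb <- nchar(gsub("-", "", aln$aligned_b, fixed = TRUE))
      min(la, lb)
    },
    exclude_stops = length(av))
  if (den == 0L) stop("zero denominator in percent_identity")
  100 * num / den
}

#' Truncate a percentage at a number of decimals
#'
#' Identity percentages are conventionally truncated (not rounded) at the
#' displayed precision, so 70.588 prints as 70.5 at one decimal.
#'
#' @param x Numeric.
#' @param digits Decimals kept.
#' @export
trunc_percent <- function(x, digits = 2L) trunc_dec(x, digits)

#' Identity of two early-developmental peptides
#'
#' Head-to-head ungapped comparison over the first `min(length(a), length(b))`
#' columns; columns where either symbol is a stop (`*`) are excluded from
#' both numerator and denominator.
#'
#' @param a,b Protein sequences ([seq_record()] or character).
#' @return Unrounded percent identity.
#' @examples
#' devseq_identity("SGLELVRVCGGGMQRDKT", "SGLE*VTVYGGGVQKGKT")  # 70.588...
#' @export
devseq_identity <- function(a, b) {
  ra <- as_residues(a, "protein")
  rb <- as_residues(b, "protein")
  if (!nzchar(ra) || !nzchar(rb)) stop("empty input")
  k <- min(nchar(ra), nchar(rb))
  av <- strsplit(substr(ra, 1L, k), "", fixed = TRUE)[[1]]
  bv <- strsplit(substr(rb, 1L, k), "", fixed = TRUE)[[1]]
  keep <- av != "*" & bv != "*"
  if (!any(keep)) stop("no comparable columns (all stops)")
  100 * sum(av[keep] == bv[keep]) / sum(keep)
}
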