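## Exact-scan layer: ungapped location, motif hits, tandem repeats, and the
## silencer overlap geometry. Coordinates are 1-based inclusive throughout.
## Ambiguity codes ('n' etc.) never match in any of these scans.

## TRUE where both characters are unambiguous bases and equal.
.base_match <- function(a, b) {
  ok <- a %in% c("a", "c", "g", "t") & b %in% c("a", "c", "g", "t")
  ok & a == b
}

#' Locate a query sequence in a larger sequence by ungapped scan
#'
#' Slides the needle along the haystack and returns the lowest-mismatch
#' window, ties broken by leftmost start. Positions where either sequence has
#' an ambiguity code count as mismatches.
#'
#' @param needle,haystack DNA [seq_record()] or character scalars.
#' @param max_mismatch Maximum mismatches tolerated; if the best window
#'   exceeds this, `NULL` is returned.
#' @return A list `(start, end, n_mismatch)` in 1-based inclusive haystack
#'   coordinates, or `NULL`.
#' @examples
#' locate("cgt", "aacgtt")
#' @export
locate <- function(needle, haystack, max_mismatch = 0L) {
  nd <- strsplit(as_residues(needle, "dna"), "", fixed = TRUE)[[1]]
  hy <- strsplit(as_residues(haystack, "dna"), "", fixed = TRUE)[[1]]
  k <- length(nd); n <- length(hy)
  if (k == 0L) stop("empty needle")
  if (k > n) stop("needle longer than haystack (", k, " > ", n, ")")
  n_win <- n - k + 1L
  mm <- vapply(seq_len(n_win), function(s) {
    sum(!.base_match(nd, hy[s:(s + k - 1L)]))
  }, integer(1))
  best <- which.min(mm)  # leftmost minimum
  if (mm[best] > max_mismatch) return(NULL)
  list(start = best, end = best + k - 1L, n_mismatch = mm[best])
}

#' Scan for literal sequence motifs
#'
#' Case-insensitive exact matching of each motif, all (possibly overlapping)
#' occurrences, positions sorted ascending.
#'
#' @param seq DNA [seq_record()] or character scalar.
#' @param motifs Character vector of literal motifs.
#' @return A data.frame with columns `motif`, `start` (1-based).
#' @export
motif_scan <- function(seq, motifs) {
  res <- as_residues(seq, "dna")
  if (any(!nzchar(motifs))) stop("empty motif")
  rows <- lapply(motifs, function(m) {
    m_lc <- tolower(m)
    k <- nchar(m_lc)
    hits <- integer()
    from <- 1L
    repeat {
      p <- regexpr(m_lc, substr(res, from, nchar(res)), fixed = TRUE)
      if (p < 0L) break
      hits <- c(hits, from + p - 1L)
      from <- from + p  # allow overlaps
    }
    if (length(hits))
      data.frame(motif = m, start = hits, stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(motif = character(), start = integer(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find tandem repeats of a fixed unit length
#'
#' Reports maximal runs of an exactly repeated unit. Runs are found left to
#' right; once a run is reported the scan resumes past it, so overlapping
#' descriptions of the same run are suppressed (the leftmost maximal run
#' wins). Units containing ambiguity codes are skipped.
#'
#' @param seq DNA [seq_record()] or character scalar.
#' @param unit_len Repeat unit length in bp (>= 1).
#' @param min_copies Minimum number of tandem copies to report.
#' @return A data.frame with columns `start`, `unit`, `copies`; the run
#'   occupies `start .. start + unit_len * copies - 1`.
#' @examples
#' tandem_repeats("ttagagagagtt", 2, 3)
#' @export
tandem_repeats <- function(seq, unit_len, min_copies = 2L) {
  if (unit_len < 1L) stop("unit_len must be >= 1")
  res <- as_residues(seq, "dna")
  n <- nchar(res)
  rows <- list()
  i <- 1L
  while (i + unit_len - 1L <= n) {
    unit <- substr(res, i, i + unit_len - 1L)
    if (grepl("[^acgt]", unit)) { i <- i + 1L; next }
    k <- 1L
    while (i + (k + 1L) * unit_len - 1L <= n &&
           substr(res, i + k * unit_len, i + (k + 1L) * unit_len - 1L) == unit) {
      k <- k + 1L
    }
    if (k >= min_copies) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = i, unit = unit, copies = k, stringsAsFactors = FALSE)
      i <- i + k * unit_len
    } else {
      i <- i + 1L
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(start = integer(), unit = character(),
                      copies = integer(), stringsAsFactors = FALSE))
  out
}

## Longest L such that the first L characters of a and b agree.
.common_prefix_len <- function(a, b) {
  k <- min(nchar(a), nchar(b))
  if (k == 0L) return(0L)
  av <- strsplit(substr(a, 1L, k), "", fixed = TRUE)[[1]]
  bv <- strsplit(substr(b, 1L, k), "", fixed = TRUE)[[1]]
  neq <- which(av != bv)
  if (length(neq)) neq[1L] - 1L else k
}

#' Silencer overlap geometry
#'
#' Measures how a silencer block straddles the boundary between an upstream
#' ORF mRNA and the downstream intervening sequence: `overlap_a` is the
#' longest suffix of the ORF mRNA equal to a prefix of the silencer
#' ("silencer1"); `overlap_intervening` is the longest prefix of the
#' remaining silencer equal to a prefix of the intervening sequence
#' ("silencer2"). When the two overlaps sum to the silencer length, the
#' silencer is fully partitioned by its neighbours.
#'
#' @param orf_mrna,silencer,intervening DNA [seq_record()]s or characters.
#' @return A list: `overlap_a`, `overlap_intervening`, `silencer_len`,
#'   `fully_partitioned`.
#' @export
annotate_silencer_overlaps <- function(orf_mrna, silencer, intervening) {
  orf <- as_residues(orf_mrna, "dna")
  sil <- as_residues(silencer, "dna")
  itv <- as_residues(intervening, "dna")
  overlap_a <- 0L
  for (L in seq_len(min(nchar(orf), nchar(sil)))) {
    if (substr(orf, nchar(orf) - L + 1L, nchar(orf)) == substr(sil, 1L, L))
      overlap_a <- L
  }
  rest <- substr(sil, overlap_a + 1L, nchar(sil))
  overlap_i <- .common_prefix_len(rest, itv)
  list(overlap_a = overlap_a,
       overlap_intervening = overlap_i,
       silencer_len = nchar(sil),
       fully_partitioned = (overlap_a + overlap_i) == nchar(sil))
}

#' Lay out gene components on an exon
#'
#' Locates each component on the exon by ungapped scan and combines the
#' intervals with the silencer overlap geometry.
#'
#' @param exon DNA [seq_record()]; the reference sequence.
#' @param orf_a,orf_b,intervening,silencer Component sequences.
#' @param max_mismatch Mismatch tolerance passed to [locate()].
#' @return A list of class `gene_layout` with one `(start, end)` interval per
#'   component plus `overlap_a_len` and `overlap_intervening_len`.
#' @export
gene_layout <- function(exon, orf_a, orf_b, intervening, silencer,
                        max_mismatch = 2L) {
  loc <- function(x) {
    hit <- locate(x, exon, max_mismatch)
    if (is.null(hit)) stop("component not located on exon within ",
                           max_mismatch, " mismatches")
    c(hit$start, hit$end)
  }
  ov <- annotate_silencer_overlaps(orf_a, silencer, intervening)
  structure(list(exon = exon,
                 orf_a_interval = loc(orf_a),
                 orf_b_interval = loc(orf_b),
                 intervening_interval = loc(intervening),
                 silencer_interval = loc(silencer),
                 overlap_a_len = ov$overlap_a,
                 overlap_intervening_len = ov$overlap_intervening),
            class = "gene_layout")
}

#' Write a gene layout as a BED-like TSV
#'
#' @param layout A [gene_layout()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_gene_layout <- function(layout, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coords=1-based-inclusive", con)
  df <- data.frame(
    feature = c("orf_a", "orf_b", "intervening", "silencer"),
    start = c(layout$orf_a_interval[1], layout$orf_b_interval[1],
              layout$intervening_interval[1], layout$silencer_interval[1]),
    end = c(layout$orf_a_interval[2], layout$orf_b_interval[2],
            layout$intervening_interval[2], layout$silencer_interval[2]))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
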