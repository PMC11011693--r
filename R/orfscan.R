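#' Scan for open reading frames
#'
#' An ORF is an ATG followed by an in-frame stop codon; the stop is included
#' in the nucleotide interval but excluded from the protein. Within a frame,
#' ORFs are reported longest first. By default only the longest ORF ending at
#' each stop is reported; `all_starts = TRUE` also reports ORFs from ATGs
#' nested inside a longer ORF.
#'
#' @param seq DNA [seq_record()] or character scalar.
#' @param frame_set Frames to scan (subset of 1:3, forward strand).
#' @param min_aa Minimum protein length in residues (stop excluded).
#' @param all_starts Report nested ATG starts as separate ORFs.
#' @return A data.frame with columns `start`, `end` (1-based inclusive nt
#'   coordinates, stop codon included), `frame`, `length_aa`, `protein`.
#' @examples
#' find_orfs("atgaaatga", min_aa = 1)
#' @export
find_orfs <- function(seq, frame_set = 1:3, min_aa = 1L, all_starts = FALSE) {
  stopifnot(all(frame_set %in% 1:3))
  out <- list()
  for (fr in frame_set) {
    prot <- as.character(translate_seq(seq, frame = fr))
    if (!nzchar(prot)) next
    aa <- strsplit(prot, "", fixed = TRUE)[[1]]
    stops <- which(aa == "*")
    prev_stop <- 0L
    rows <- list()
    for (s in stops) {
      mets <- which(aa[(prev_stop + 1L):(s - 1L)] == "M")
      if (length(mets)) {
        mets <- mets + prev_stop
        starts_aa <- if (all_starts) mets else mets[1L]
        for (m in starts_aa) {
          len_aa <- s - m
          if (len_aa >= min_aa) {
            rows[[length(rows) + 1L]] <- data.frame(
              start = (m - 1L) * 3L + fr,
              end = s * 3L + fr - 1L,
              frame = fr,
              length_aa = len_aa,
              protein = paste(aa[m:(s - 1L)], collapse = ""),
              stringsAsFactors = FALSE)
          }
        }
      }
      prev_stop <- s
    }
    if (length(rows)) {
      df <- do.call(rbind, rows)
      out[[length(out) + 1L]] <- df[order(-df$length_aa, df$start), ]
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      length_aa = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
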