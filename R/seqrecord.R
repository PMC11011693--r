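#' Sequence records
#'
#' A `seq_record` is a named nucleotide or amino-acid sequence. Nucleotide
#' residues are stored lowercase; amino-acid residues uppercase, with `*`
#' marking a stop codon. Ambiguity codes (`n` etc.) are tolerated in DNA but
#' never match in any scan (see [locate()], [motif_scan()], [tandem_repeats()]).
#'
#' @param id Short label.
#' @param residues Character scalar of residues.
#' @param alphabet `"dna"` or `"protein"`.
#' @param description Free-text description.
#' @param allow_empty Permit an empty sequence (default `FALSE`).
#' @return An object of class `seq_record` with fields `id`, `description`,
#'   `alphabet`, `residues`.
#' @examples
#' seq_record("ex", "ATGTGA")
#' @export
seq_record <- function(id, residues, alphabet = c("dna", "protein"),
                       description = "", allow_empty = FALSE) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- if (alphabet == "dna") tolower(residues) else toupper(residues)
  if (!allow_empty && !nzchar(residues))
    stop("empty sequence for record '", id, "'")
  bad <- if (alphabet == "dna") {
    gsub("[acgtnryswkmbdhv]", "", residues)
  } else {
    gsub("[A-Z*]", "", residues)
  }
  if (nzchar(bad))
    stop("record '", id, "': residues not in the ", alphabet,
         " alphabet: ", substr(bad, 1L, 10L))
  structure(list(id = id, description = description,
                 alphabet = alphabet, residues = residues),
            class = "seq_record")
}

#' @export
length.seq_record <- function(x) nchar(x$residues)

#' @export
as.character.seq_record <- function(x, ...) x$residues

#' @export
print.seq_record <- function(x, ...) {
  n <- length(x)
  head <- substr(x$residues, 1L, 60L)
  cat(sprintf("<seq_record %s> %s [%d %s]\n  %s%s\n",
              x$id, x$description, n,
              if (x$alphabet == "dna") "nt" else "aa",
              head, if (n > 60L) "..." else ""))
  invisible(x)
}

## Coerce character or seq_record input to a plain residue string.
as_residues <- function(x, alphabet = "dna") {
  if (inherits(x, "seq_record")) {
    if (x$alphabet != alphabet)
      stop("expected a ", alphabet, " sequence, got ", x$alphabet)
    x$residues
  } else if (is.character(x) && length(x) == 1L) {
    if (alphabet == "dna") tolower(x) else toupper(x)
  } else {
    stop("expected a seq_record or a character scalar")
  }
}

#' Read and write FASTA files
#'
#' `read_fasta()` accepts standard multi-record FASTA, wrapped or unwrapped.
#' Whitespace and digits inside sequence blocks are stripped, so sequence
#' blocks printed with position numbers paste through unchanged. The alphabet
#' of each record is inferred from its residues.
#'
#' @param path File path.
#' @param alphabet `"auto"` (default), `"dna"` or `"protein"`.
#' @return A named list of [seq_record()] objects.
#' @export
read_fasta <- function(path, alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  lines <- readLines(path, warn = FALSE)
  records <- list()
  id <- NULL; desc <- ""; chunks <- character()
  flush <- function() {
    if (is.null(id)) return()
    res <- gsub("[0-9[:space:]]", "", paste(chunks, collapse = ""))
    alph <- if (alphabet == "auto") {
      if (grepl("^[acgtnryswkmbdhv]*$", tolower(res))) "dna" else "protein"
    } else alphabet
    records[[id]] <<- seq_record(id, res, alph, desc, allow_empty = TRUE)
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, ">")) {
      flush()
      hdr <- sub("^>\\s*", "", ln)
      id <- sub("\\s.*$", "", hdr)
      desc <- if (grepl("\\s", hdr)) sub("^\\S+\\s+", "", hdr) else ""
      chunks <- character()
    } else {
      if (is.null(id))
        stop("malformed FASTA: line ", i, " precedes any '>' header")
      chunks <- c(chunks, ln)
    }
  }
  flush()
  records
}

#' @rdname read_fasta
#' @param records List of [seq_record()] objects (or a single one).
#' @param width Residues per line when writing.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "seq_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    hdr <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", hdr), con)
    n <- length(r)
    if (n > 0L) {
      starts <- seq(1L, n, by = width)
      writeLines(substring(r$residues, starts, pmin(starts + width - 1L, n)), con)
    }
  }
  invisible(path)
}

#' The standard genetic code
#'
#' @return A list with `table`, a 64-entry named character vector mapping
#'   lowercase codons to amino-acid letters, and `stop_symbol` (`"*"`).
#' @export
genetic_code <- function() {
  tab <- Biostrings::GENETIC_CODE
  names(tab) <- tolower(names(tab))
  list(table = tab, stop_symbol = "*")
}

#' Reverse complement
#'
#' @param seq DNA [seq_record()] or character scalar.
#' @return Object of the same type as the input.
#' @export
reverse_complement <- function(seq) {
  res <- as_residues(seq, "dna")
  rc <- tolower(as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(res)))))
  if (inherits(seq, "seq_record"))
    seq_record(seq$id, rc, "dna", seq$description)
  else rc
}

#' Translate a nucleotide sequence
#'
#' Translation starts at the frame offset and runs to the last complete
#' codon; trailing 1-2 nt are dropped. Stop codons are rendered `*` and
#' translation continues through them, so reading frames containing internal
#' stops translate in full. Codons containing ambiguity codes give `X`.
#'
#' @param seq DNA [seq_record()] or character scalar.
#' @param frame Reading frame, 1, 2 or 3 (offset `frame - 1`).
#' @param strand `"+"` or `"-"`; `"-"` translates the reverse complement.
#' @return A protein [seq_record()] of length `floor((n - frame + 1) / 3)`.
#' @examples
#' as.character(translate_seq("atgtga"))  # "M*"
#' @export
translate_seq <- function(seq, frame = 1L, strand = c("+", "-")) {
  strand <- match.arg(strand)
  if (inherits(seq, "seq_record") && seq$alphabet != "dna")
    stop("translate_seq() requires a dna sequence")
  res <- as_residues(seq, "dna")
  if (strand == "-") res <- reverse_complement(res)
  if (!frame %in% 1:3) stop("frame must be 1, 2 or 3")
  res <- substr(res, frame, nchar(res))
  n_codon <- nchar(res) %/% 3L
  id <- if (inherits(seq, "seq_record")) seq$id else "seq"
  if (n_codon == 0L)
    return(seq_record(paste0(id, "_aa"), "", "protein", allow_empty = TRUE))
  starts <- 3L * (seq_len(n_codon) - 1L) + 1L
  codons <- substring(res, starts, starts + 2L)
  code <- genetic_code()$table
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  seq_record(paste0(id, "_aa"), paste(aa, collapse = ""), "protein",
             sprintf("frame %d strand %s", frame, strand))
}

round_half_up <- function(x, digits = 0L) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

trunc_dec <- function(x, digits = 0L) {
  s <- 10^digits
  trunc(x * s + 1e-9 * sign(x)) / s
}

#' Base composition of a DNA sequence
#'
#' Counts of A, C, G, T plus `other_count` for ambiguity codes. Integer
#' percentages are truncated (the convention that reproduces the published
#' composition lines for the packaged sequences, e.g. 119/324 printing as
#' 36); `gc_percent` is reported both unrounded and truncated. With
#' `acgt_only = TRUE` (default) ambiguity codes are excluded from both the
#' GC numerator and denominator.
#'
#' @param seq DNA [seq_record()] or character scalar.
#' @param acgt_only Exclude non-ACGT symbols from the GC computation.
#' @return A list of class `composition_report`: `length_bp`, `counts`,
#'   `other_count`, `percents`, `gc_percent`, `gc_percent_rounded`,
#'   `undefined` (TRUE for an empty sequence).
#' @export
composition <- function(seq, acgt_only = TRUE) {
  res <- as_residues(seq, "dna")
  n <- nchar(res)
  bases <- c("a", "c", "g", "t")
  if (n == 0L) {
    counts <- stats::setNames(integer(4), bases)
    return(structure(list(length_bp = 0L, counts = counts, other_count = 0L,
                          percents = stats::setNames(rep(NA_real_, 4), bases),
                          gc_percent = NA_real_, gc_percent_rounded = NA_real_,
                          undefined = TRUE),
                     class = "composition_report"))
  }
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  counts <- vapply(bases, function(b) sum(chars == b), integer(1))
  other <- n - sum(counts)
  gc_den <- if (acgt_only) sum(counts) else n
  gc <- if (gc_den > 0L) 100 * (counts[["g"]] + counts[["c"]]) / gc_den else NA_real_
  structure(list(
    length_bp = n,
    counts = counts,
    other_count = other,
    percents = trunc_dec(100 * counts / n),
    gc_percent = gc,
    gc_percent_rounded = trunc_dec(gc),
    undefined = FALSE
  ), class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  if (x$undefined) { cat("<composition> empty sequence\n"); return(invisible(x)) }
  cat(sprintf("Full Length(%dbp) | A(%d%% %d) | T(%d%% %d) | G(%d%% %d) | C(%d%% %d)\n",
              x$length_bp,
              x$percents[["a"]], x$counts[["a"]],
              x$percents[["t"]], x$counts[["t"]],
              x$percents[["g"]], x$counts[["g"]],
              x$percents[["c"]], x$counts[["c"]]))
  cat(sprintf("GC%% = %.2f (rounds to %d)\n", x$gc_percent, x$gc_percent_rounded))
  invisible(x)
}
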