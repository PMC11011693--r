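#' Packaged SMIM45 sequences
#'
#' The sequences of the human SMIM45 exon 2 system: `exon2` (1268 bp),
#' `mrna68` (the 68 aa ORF mRNA, 207 nt), `mrna107` (the 107 aa ORF mRNA,
#' 324 nt), `intervening` (324 nt), `silencer` (LOC130067579, 230 nt),
#' `transcript_v1` (NM_001395940.1, 1540 nt) and `devseq_rna` (54 nt,
#' encoding the early developmental peptide SGLELVRVCGGGMQRDKT).
#'
#' @return A named list of [seq_record()] objects.
#' @export
smim45_sequences <- function() {
  read_fasta(system.file("extdata", "smim45_sequences.fasta",
                         package = "orfgenesis"))
}

#' Early-developmental peptide homologs across primates
#'
#' The per-species amino-acid sequences homologous to the human early
#' developmental peptide, with divergence ages. The orangutan row is
#' bundled for completeness but its printed-source identity is internally
#' inconsistent and it is excluded from identity checks.
#'
#' @return A data.frame with columns `species`, `sequence`, `age_mya`.
#' @export
devseq_table <- function() {
  utils::read.table(system.file("extdata", "devseq_primates.tsv",
                                package = "orfgenesis"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Trace a candidate ORF across a species panel
#'
#' Runs the synteny-anchored protocol for every species: locate the
#' guidepost ORF in the inter-anchor region, take the downstream candidate
#' window on the guidepost strand, locally align the target ORF nucleotide
#' sequence against the window, classify the similarity call under the
#' twilight rules, and infer the root species from the age-ordered calls.
#'
#' @param regions Named list of DNA [seq_record()], one per panel species.
#' @param panel Data.frame `name`, `age_mya`, oldest first.
#' @param guidepost_nt,target_nt DNA query sequences.
#' @param dev_aa Optional protein query; when supplied, per-species
#'   translated-frame hits are reported via [detect_devseq()].
#' @param scheme A [scoring_scheme()].
#' @param cfg A [twilight_config()].
#' @param downstream_bp Candidate window size (see
#'   [extract_candidate_window()]).
#' @return A list of class `orf_trace`: `calls` (one row per species,
#'   oldest first), `root` ([infer_root()] result, or NULL for panels of
#'   fewer than 3 species), `table` ([progression_table()]), `aa_hits`
#'   (named list, only if `dev_aa` given), `degenerate`.
#' @export
trace_panel <- function(regions, panel, guidepost_nt, target_nt,
                        dev_aa = NULL, scheme = scoring_scheme(),
                        cfg = twilight_config(), downstream_bp = 1200L) {
  if (!all(panel$name %in% names(regions)))
    stop("missing region sequence for species: ",
         paste(setdiff(panel$name, names(regions)), collapse = ", "))
  tgt_len <- nchar(as_residues(target_nt, "dna"))
  calls <- list(); aa_hits <- list()
  for (i in seq_len(nrow(panel))) {
    sp <- panel$name[i]; age <- panel$age_mya[i]
    region <- regions[[sp]]
    hit <- locate_guidepost(region, guidepost_nt, scheme)
    if (is.null(hit)) {
      calls[[i]] <- similarity_call(sp, age, synteny = FALSE, cfg = cfg)
      next
    }
    win <- extract_candidate_window(region, hit, downstream_bp)
    if (win$empty || length(win$seq) < 3L) {
      calls[[i]] <- similarity_call(sp, age, synteny = TRUE, cfg = cfg)
      next
    }
    aln <- local_align(target_nt, win$seq, scheme)
    if (aln$n_columns == 0L) {
      calls[[i]] <- similarity_call(sp, age, synteny = TRUE, cfg = cfg)
      next
    }
    ev <- evalue(aln$score, m = tgt_len, n = length(win$seq), scheme)
    calls[[i]] <- similarity_call(
      sp, age,
      identity_pct = percent_identity(aln, "columns"),
      evalue = ev$evalue,
      aligned_len = aln$n_columns,
      synteny = TRUE,
      match_start = aln$a_interval[1], match_end = aln$a_interval[2],
      cfg = cfg)
    if (!is.null(dev_aa))
      aa_hits[[sp]] <- detect_devseq(win$seq, dev_aa, scheme, synteny = TRUE)
  }
  calls <- do.call(rbind, calls)
  degenerate <- nrow(calls) < 3L
  structure(list(calls = calls,
                 root = if (degenerate) NULL else infer_root(calls),
                 table = progression_table(calls),
                 aa_hits = if (is.null(dev_aa)) NULL else aa_hits,
                 degenerate = degenerate),
            class = "orf_trace")
}

#' @export
print.orf_trace <- function(x, ...) {
  cat("<orf_trace>", nrow(x$calls), "species\n")
  print(x$table$table[, c("species", "age_mya", "evalue", "identity_pct",
                          "matched_len", "label")], digits = 3)
  if (!is.null(x$root)) print(x$root)
  invisible(x)
}

#' Consistency report for the bundled SMIM45 sequences
#'
#' Recomputes the documented characteristics of the packaged SMIM45
#' system - ORF lengths, the C-terminal decapeptide, mRNA composition,
#' exon coordinates, silencer overlap geometry, and the early-developmental
#' identity ladder - and compares each against its reference value.
#'
#' @return A data.frame (`check`, `computed`, `expected`, `pass`) with
#'   attribute `all_pass`.
#' @export
reference_report <- function() {
  fx <- smim45_sequences()
  dv <- devseq_table()
  hum <- dv$sequence[dv$species == "human"]
  idpct <- function(sp, d) {
    trunc_percent(devseq_identity(hum, dv$sequence[dv$species == sp]), d)
  }
  orfs68 <- find_orfs(fx$mrna68, frame_set = 1L, min_aa = 50L)
  orfs107 <- find_orfs(fx$mrna107, frame_set = 1L, min_aa = 50L)
  comp <- composition(fx$mrna107)
  p68 <- locate(fx$mrna68, fx$exon2, 0L)
  p107 <- locate(fx$mrna107, fx$exon2, 2L)
  ov <- annotate_silencer_overlaps(fx$mrna68, fx$silencer, fx$intervening)
  decapep <- substr(orfs107$protein[1], 98L, 107L)
  rows <- list(
    list("orf68_length_aa", orfs68$length_aa[1], 68),
    list("orf107_length_aa", orfs107$length_aa[1], 107),
    list("orf107_cterminal_decapeptide", decapep, "VWGERASMGR"),
    list("mrna107_length_bp", comp$length_bp, 324),
    list("mrna107_g_count", unname(comp$counts["g"]), 119),
    list("mrna68_exon2_start", p68$start, 15),
    list("mrna107_exon2_start", p107$start, 546),
    list("silencer_overlap_orf68_bp", ov$overlap_a, 38),
    list("silencer_overlap_intervening_bp", ov$overlap_intervening, 192),
    list("silencer_length_bp", ov$silencer_len, 230),
    list("devseq_identity_mouse", idpct("mouse", 1L), 70.5),
    list("devseq_identity_tarsier", idpct("tarsier", 2L), 35.29),
    list("devseq_identity_gorilla", idpct("gorilla", 1L), 52.9))
  df <- data.frame(
    check = vapply(rows, `[[`, character(1), 1L),
    computed = vapply(rows, function(r) format(r[[2]]), character(1)),
    expected = vapply(rows, function(r) format(r[[3]]), character(1)),
    stringsAsFactors = FALSE)
  df$pass <- df$computed == df$expected
  attr(df, "all_pass") <- all(df$pass)
  df
}

#' Command wrappers
#'
#' Thin orchestration around the package functions, suitable for scripting:
#' `run_simulate()` writes a simulated panel; `run_trace()` reads a panel
#' TSV plus per-species FASTAs, traces the target and writes the call table
#' and root inference; `run_reference_check()` writes the
#' [reference_report()].
#'
#' @param outdir Output directory.
#' @param config A [sim_config()].
#' @param seed Optional override of `config$seed`.
#' @return `run_simulate()`: the [emit_panel()] file list.
#' @export
run_simulate <- function(outdir, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    validate_sim_config(config)
  }
  emit_panel(config, outdir)
}

#' @rdname run_simulate
#' @param panel_tsv Panel TSV with columns `name`, `age_mya`, `fasta`
#'   (paths relative to the TSV's directory).
#' @param guidepost_nt,target_nt Query sequences; the packaged SMIM45
#'   guidepost and target ORF mRNAs by default.
#' @param ... Passed to [trace_panel()].
#' @return `run_trace()`: the `orf_trace`, invisibly; writes `calls.tsv`
#'   and `root.json` under `outdir` when given.
#' @export
run_trace <- function(panel_tsv, outdir = NULL, guidepost_nt = NULL,
                      target_nt = NULL, ...) {
  panel <- utils::read.table(panel_tsv, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  if (!all(c("name", "age_mya", "fasta") %in% names(panel)))
    stop("panel TSV needs columns name, age_mya, fasta")
  base <- dirname(panel_tsv)
  regions <- list()
  for (i in seq_len(nrow(panel))) {
    recs <- read_fasta(file.path(base, panel$fasta[i]))
    regions[[panel$name[i]]] <- recs[[1L]]
  }
  fx <- NULL
  if (is.null(guidepost_nt) || is.null(target_nt)) fx <- smim45_sequences()
  if (is.null(guidepost_nt)) guidepost_nt <- fx$mrna68
  if (is.null(target_nt)) target_nt <- fx$mrna107
  tr <- trace_panel(regions, panel[, c("name", "age_mya")],
                    guidepost_nt, target_nt, ...)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(tr$table$table, file.path(outdir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(tr$root))
      jsonlite::write_json(
        list(status = tr$root$status,
             root_candidates = tr$root$root_candidates),
        file.path(outdir, "root.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(tr)
}

#' @rdname run_simulate
#' @param path Optional TSV path for the report.
#' @return `run_reference_check()`: the report data.frame, invisibly;
#'   attribute `all_pass` indicates overall success.
#' @export
run_reference_check <- function(path = NULL) {
  df <- reference_report()
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
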