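#' Twilight-zone classification thresholds
#'
#' The twilight zone is the band of marginal similarity where true homology
#' cannot be separated from chance by identity or Expect value alone;
#' positional synteny with a conserved neighbour is used as the extra
#' constraint. Defaults: Expect threshold 0.05, twilight identity around
#' 55 percent (the tilde is honoured by accepting `twilight_slack` times the
#' nominal value, 49.5 by default), minimum 15 aligned columns.
#'
#' @param alpha Expect-value threshold for a significant call.
#' @param twilight_identity_pct Nominal twilight identity in percent.
#' @param min_aligned_len Minimum aligned columns for any call.
#' @param twilight_slack Multiplier applied to `twilight_identity_pct`.
#' @return A list of class `twilight_config`.
#' @export
twilight_config <- function(alpha = 0.05, twilight_identity_pct = 55,
                            min_aligned_len = 15L, twilight_slack = 0.9) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (!(twilight_identity_pct > 0 && twilight_identity_pct < 100))
    stop("twilight_identity_pct must be in (0, 100)")
  structure(list(alpha = alpha,
                 twilight_identity_pct = twilight_identity_pct,
                 min_aligned_len = min_aligned_len,
                 twilight_slack = twilight_slack),
            class = "twilight_config")
}

#' Classify a per-species similarity call
#'
#' Rules applied in order: (1) no alignment, fewer than `min_aligned_len`
#' aligned columns, or no synteny gives `"none"`; (2) Expect value strictly
#' below `alpha` gives `"significant"`; (3) synteny with identity at least
#' `twilight_slack * twilight_identity_pct` gives `"twilight"`; otherwise
#' `"none"`. An Expect value exactly at `alpha` therefore falls on the
#' twilight side.
#'
#' @param identity_pct Percent identity in `[0, 100]`.
#' @param evalue Expect value (`NA` for no alignment).
#' @param synteny Logical; is the hit syntenic with the guidepost?
#' @param aligned_len Aligned columns (`NA` for no alignment).
#' @param cfg A [twilight_config()].
#' @return One of `"significant"`, `"twilight"`, `"none"`.
#' @export
classify_similarity <- function(identity_pct, evalue, synteny, aligned_len,
                                cfg = twilight_config()) {
  if (!is.na(identity_pct) && (identity_pct < 0 || identity_pct > 100))
    stop("identity_pct outside [0, 100]")
  if (is.na(aligned_len) || is.na(identity_pct) || is.na(evalue) ||
      aligned_len < cfg$min_aligned_len || !isTRUE(synteny))
    return("none")
  if (evalue < cfg$alpha) return("significant")
  if (isTRUE(synteny) &&
      identity_pct >= cfg$twilight_slack * cfg$twilight_identity_pct)
    return("twilight")
  "none"
}

#' Build a similarity-call table row
#'
#' @param species Species name.
#' @param age_mya Divergence age in million years.
#' @param identity_pct,evalue,aligned_len Alignment summary (`NA` if none).
#' @param synteny Logical.
#' @param match_start,match_end Matched interval in query coordinates.
#' @param cfg A [twilight_config()].
#' @return A one-row data.frame with a `label` column.
#' @export
similarity_call <- function(species, age_mya, identity_pct = NA_real_,
                            evalue = NA_real_, aligned_len = NA_integer_,
                            synteny = FALSE, match_start = NA_integer_,
                            match_end = NA_integer_,
                            cfg = twilight_config()) {
  label <- classify_similarity(identity_pct, evalue, synteny, aligned_len, cfg)
  data.frame(species = species, age_mya = age_mya,
             identity_pct = identity_pct, evalue = evalue,
             aligned_len = aligned_len, synteny = synteny,
             match_start = if (label == "none") NA_integer_ else match_start,
             match_end = if (label == "none") NA_integer_ else match_end,
             label = label, stringsAsFactors = FALSE)
}

#' Infer the root species of origin from age-ordered similarity calls
#'
#' Given calls sorted oldest first, the root candidates are the maximal
#' age-prefix of species labelled `"none"`, provided the next-younger
#' species shows twilight or significant similarity. If the oldest species
#' is already non-`"none"` the root predates the panel (empty candidate
#' list, status `"predates_panel"`); if every species is `"none"` there is
#' no similarity anywhere (status `"no_similarity"`).
#'
#' @param calls A data.frame of similarity calls (rows as produced by
#'   [similarity_call()]), sorted oldest first, at least 3 species with
#'   strictly decreasing ages.
#' @return A list of class `root_inference`: `calls`, `root_candidates`,
#'   `status`, `rationale` (named character per candidate).
#' @export
infer_root <- function(calls) {
  if (nrow(calls) < 3L) stop("need calls for at least 3 species")
  if (any(diff(calls$age_mya) >= 0))
    stop("calls must be sorted oldest first with strictly decreasing ages")
  lab <- calls$label
  if (all(lab == "none")) {
    return(structure(list(calls = calls, root_candidates = character(),
                          status = "no_similarity",
                          rationale = character()),
                     class = "root_inference"))
  }
  if (lab[1L] != "none") {
    return(structure(list(calls = calls, root_candidates = character(),
                          status = "predates_panel",
                          rationale = character()),
                     class = "root_inference"))
  }
  k <- which(lab != "none")[1L] - 1L    # length of the none-prefix
  cand <- calls$species[seq_len(k)]
  rationale <- stats::setNames(
    rep("no synteny-anchored similarity; next-younger species shows similarity",
        k), cand)
  structure(list(calls = calls, root_candidates = cand,
                 status = "ok", rationale = rationale),
            class = "root_inference")
}

#' @export
print.root_inference <- function(x, ...) {
  cat("<root_inference>", x$status, "\n")
  if (length(x$root_candidates))
    cat(" candidates:", paste(x$root_candidates, collapse = ", "), "\n")
  invisible(x)
}

## Kendall concordance sign by explicit pair counting.
.kendall_sign <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(NA_integer_)
  nc <- 0L; nd <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (is.na(s)) next
      if (s > 0) nc <- nc + 1L else if (s < 0) nd <- nd + 1L
    }
  }
  if (nc == nd) 0L else if (nc > nd) 1L else -1L
}

#' Similarity-progression table with trend summary
#'
#' Orders calls by age descending and summarises the qualitative trend one
#' expects as species approach the present: Expect values fall and matched
#' segments lengthen. Trend signs are Kendall concordance signs computed by
#' explicit pair counting over species with an alignment.
#'
#' @param calls Data.frame of similarity calls.
#' @return A list of class `progression_table`: `table` (calls with a
#'   `matched_len` column, age-descending), `trend_age_logE`,
#'   `trend_age_matched_len` (+1, 0, -1 or NA), `degenerate` (TRUE when
#'   fewer than 2 species have alignments).
#' @export
progression_table <- function(calls) {
  tab <- calls[order(-calls$age_mya), , drop = FALSE]
  tab$matched_len <- ifelse(is.na(tab$match_start), NA_integer_,
                            tab$match_end - tab$match_start + 1L)
  have <- !is.na(tab$evalue) & tab$label != "none"
  degenerate <- sum(have) < 2L
  structure(list(
    table = tab,
    trend_age_logE = if (degenerate) NA_integer_ else
      .kendall_sign(tab$age_mya[have], log10(tab$evalue[have])),
    trend_age_matched_len = if (degenerate) NA_integer_ else
      .kendall_sign(tab$age_mya[have], tab$matched_len[have]),
    degenerate = degenerate
  ), class = "progression_table")
}
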