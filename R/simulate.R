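## Simulator of de novo ORF genesis along an age-ordered species panel.
## The model: an ancestral non-coding region carries a conserved guidepost
## ORF, a silencer block, and a stretch of random sequence where the target
## ORF will form. Evolution runs oldest to youngest along a chain of
## branches. On each branch, biased "fixed" events set target-locus
## positions to the target base, expanding contiguously outward from seeded
## positions (nearest-neighbour growth) and re-fixing positions knocked out
## by background noise; background substitutions hit the unprotected region;
## each species may additionally carry private dead-end changes (tip
## substitutions and at most one indel) that are never inherited. The
## terminal species can gain a tandem-repeat slippage duplication. Every
## event is logged so downstream inference can be scored against truth.

.BASES <- c("a", "c", "g", "t")

#' Default species panel for genesis simulations
#'
#' A ten-species ladder from an afrotherian outgroup to human, with
#' divergence ages (MYA) matching the species commonly used to trace
#' primate de novo ORF formation.
#'
#' @return A data.frame with columns `name`, `age_mya`, oldest first.
#' @export
default_panel <- function() {
  data.frame(
    name = c("aardvark", "mouse", "tree_shrew", "lemur", "tarsier",
             "rhesus", "orangutan", "gorilla", "chimpanzee", "human"),
    age_mya = c(99, 87, 68, 61, 58, 31, 20, 10, 6, 0),
    stringsAsFactors = FALSE)
}

#' Configuration for a genesis simulation
#'
#' Defaults encode the study conditions: the bundled 68 aa ORF mRNA as the
#' conserved guidepost, the bundled 107 aa ORF mRNA as the growth target,
#' the bundled silencer block (its first 38 bp conserved from the panel
#' start, the remaining 192 bp grown like the target), three seed positions
#' spread across the target, growth of 1.2 target-matching positions per
#' million years per seeded region, background substitution at 1 per site
#' per 100 MY outside the protected loci, and a 15 percent per-lineage
#' chance of a private dead-end indel.
#'
#' @param seed RNG seed.
#' @param panel Data.frame `name`, `age_mya`, strictly decreasing, oldest
#'   first.
#' @param region_len Ancestral region length in bp.
#' @param gc_content GC fraction of the random background.
#' @param guidepost_nt,target_orf_nt,silencer_block DNA sequences
#'   ([seq_record()] or character); defaults are the packaged SMIM45
#'   sequences.
#' @param n_seeds Number of seeded growth regions in the target.
#' @param growth_rate Target-matching positions fixed per MY per region.
#' @param background_rate Substitutions per site per 100 MY.
#' @param dead_end_prob Per-lineage probability of a private indel.
#' @param dead_end_tip_my Private-lineage branch length (MY) generating
#'   per-species dead-end substitutions at `background_rate`.
#' @param slippage_on_terminal Add a tandem-repeat slippage duplication on
#'   the terminal branch.
#' @param ancestor_gap_my Branch length from the unobserved ancestor to the
#'   oldest panel species.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       panel = default_panel(),
                       region_len = 1600L,
                       gc_content = 0.55,
                       guidepost_nt = NULL,
                       target_orf_nt = NULL,
                       silencer_block = NULL,
                       n_seeds = 3L,
                       growth_rate = 1.2,
                       background_rate = 1.0,
                       dead_end_prob = 0.15,
                       dead_end_tip_my = 2,
                       slippage_on_terminal = TRUE,
                       ancestor_gap_my = 5) {
  fixtures <- NULL
  need_fix <- is.null(guidepost_nt) || is.null(target_orf_nt) ||
    is.null(silencer_block)
  if (need_fix) fixtures <- smim45_sequences()
  if (is.null(guidepost_nt)) guidepost_nt <- fixtures$mrna68
  if (is.null(target_orf_nt)) target_orf_nt <- fixtures$mrna107
  if (is.null(silencer_block)) silencer_block <- fixtures$silencer
  cfg <- list(seed = as.integer(seed), panel = panel,
              region_len = as.integer(region_len), gc_content = gc_content,
              guidepost_nt = as_residues(guidepost_nt, "dna"),
              target_orf_nt = as_residues(target_orf_nt, "dna"),
              silencer_block = as_residues(silencer_block, "dna"),
              silencer1_len = 38L,
              n_seeds = as.integer(n_seeds), growth_rate = growth_rate,
              background_rate = background_rate,
              dead_end_prob = dead_end_prob,
              dead_end_tip_my = dead_end_tip_my,
              slippage_on_terminal = isTRUE(slippage_on_terminal),
              ancestor_gap_my = ancestor_gap_my)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!is.data.frame(panel) || !all(c("name", "age_mya") %in% names(panel)))
      stop("panel must be a data.frame with columns name, age_mya")
    if (nrow(panel) < 2L) stop("panel needs at least 2 species")
    if (any(diff(panel$age_mya) >= 0))
      stop("panel ages must be strictly decreasing (oldest first)")
    if (any(panel$age_mya < 0)) stop("ages must be nonnegative")
    if (anyDuplicated(panel$name)) stop("duplicate species names")
    if (growth_rate < 0 || background_rate < 0 || dead_end_prob < 0 ||
        dead_end_prob > 1 || dead_end_tip_my < 0 || ancestor_gap_my < 0)
      stop("rates must be nonnegative (dead_end_prob in [0, 1])")
    if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0, 1)")
    if (n_seeds < 1L) stop("n_seeds must be >= 1")
    need <- nchar(guidepost_nt) + nchar(target_orf_nt) + 200L
    if (region_len < need)
      stop("region_len must be >= len(guidepost) + len(target) + 200 = ", need)
    need2 <- nchar(guidepost_nt) + nchar(silencer_block) +
      nchar(target_orf_nt) + 80L + 2L
    if (region_len < need2)
      stop("region_len too small to lay out guidepost, silencer and target: ",
           "need >= ", need2)
  })
  invisible(cfg)
}

.random_bases <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)  # a c g t
  sample(.BASES, n, replace = TRUE, prob = p)
}

## Seed positions spread evenly across a locus of length L.
.seed_positions <- function(L, n) {
  pmin(pmax(round((seq_len(n) - 0.5) * L / n), 1L), L)
}

#' Simulate de novo ORF genesis along a species panel
#'
#' @param cfg A [sim_config()].
#' @return A list of class `genesis_sim`: `regions` (named list of DNA
#'   [seq_record()], one per species), `truth` (event log and ground truth,
#'   see Details), `config`.
#'
#' @details `truth` contains: `root_species` (species on whose branch the
#'   first seed fixed), `ancestral` (the ancestral region sequence; replaying
#'   the logged events over it reproduces every species exactly),
#'   `seed_positions` (absolute region coordinates),
#'   `loci` (guidepost/silencer/silencer1/silencer2/target intervals in
#'   ancestral coordinates), `fixed_events`, `background_events`,
#'   `random_events` (private tip substitutions), `indel_events`, and
#'   `per_species_target_identity` (fraction of inherited target-locus
#'   positions matching the target, per species).
#' @export
simulate_genesis <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  gp <- strsplit(cfg$guidepost_nt, "", fixed = TRUE)[[1]]
  sil <- strsplit(cfg$silencer_block, "", fixed = TRUE)[[1]]
  tgt <- strsplit(cfg$target_orf_nt, "", fixed = TRUE)[[1]]
  s1len <- min(cfg$silencer1_len, length(sil))
  Lg <- length(gp); Ls <- length(sil); Lt <- length(tgt)
  spacer <- 40L
  flank_total <- cfg$region_len - Lg - Ls - Lt - 2L * spacer
  f1 <- flank_total %/% 2L
  ## layout: flank1 | guidepost | spacer | silencer | spacer | target | flank2
  gp_s <- f1 + 1L; gp_e <- f1 + Lg
  sil_s <- gp_e + spacer + 1L; sil_e <- sil_s + Ls - 1L
  s2_s <- sil_s + s1len; s2_e <- sil_e
  tgt_s <- sil_e + spacer + 1L; tgt_e <- tgt_s + Lt - 1L

  chain <- .random_bases(cfg$region_len, cfg$gc_content)
  chain[gp_s:gp_e] <- gp
  chain[sil_s:(sil_s + s1len - 1L)] <- sil[seq_len(s1len)]
  ## silencer2 and target loci stay ancestral random sequence
  ancestral <- paste(chain, collapse = "")

  ## growth regions: n_seeds domains over the target + one over silencer2
  mk_region <- function(name, abs_pos, bases, seed_rel) {
    list(name = name, abs = abs_pos, bases = bases,
         seed = seed_rel, lo = NA_integer_, hi = NA_integer_)
  }
  regions <- list()
  seeds_rel <- .seed_positions(Lt, cfg$n_seeds)
  bounds <- round(c(0, (seeds_rel[-cfg$n_seeds] + seeds_rel[-1]) / 2, Lt))
  for (k in seq_len(cfg$n_seeds)) {
    dom <- (bounds[k] + 1L):bounds[k + 1L]
    regions[[length(regions) + 1L]] <- mk_region(
      paste0("target_", k), tgt_s - 1L + dom, tgt[dom],
      seeds_rel[k] - bounds[k])
  }
  n_target_regions <- length(regions)
  if (s2_e >= s2_s) {
    dom <- seq_len(s2_e - s2_s + 1L)
    regions[[length(regions) + 1L]] <- mk_region(
      "silencer2", s2_s - 1L + dom, sil[s1len + dom],
      .seed_positions(length(dom), 1L))
  }
  n_regions <- length(regions)

  protected <- c(gp_s:gp_e, sil_s:(sil_s + s1len - 1L))
  mutable <- setdiff(seq_len(cfg$region_len), protected)
  in_target <- logical(cfg$region_len); in_target[tgt_s:tgt_e] <- TRUE
  target_base <- rep(NA_character_, cfg$region_len)
  target_base[tgt_s:tgt_e] <- tgt

  fixed_ev <- list(); bg_ev <- list(); rnd_ev <- list(); indel_ev <- list()
  root_species <- NA_character_
  regions_state <- regions
  code <- genetic_code()$table

  ## remaining work in a region: ungrown positions + grown-but-deviant ones
  region_work <- function(r) {
    if (is.na(r$lo)) return(length(r$abs))
    span <- r$lo:r$hi
    deviant <- sum(chain[r$abs[span]] != r$bases[span])
    (length(r$abs) - length(span)) + deviant
  }

  apply_growth_event <- function(r, species) {
    ## returns list(region, event) ; repairs first, then contiguous extension
    if (!is.na(r$lo)) {
      span <- r$lo:r$hi
      dev <- span[chain[r$abs[span]] != r$bases[span]]
      if (length(dev)) {
        i <- if (length(dev) == 1L) dev else sample(dev, 1L)
        ev <- data.frame(species = species, position = r$abs[i],
                         from = chain[r$abs[i]], to = r$bases[i],
                         kind = "repair", region = r$name,
                         stringsAsFactors = FALSE)
        chain[r$abs[i]] <<- r$bases[i]
        return(list(region = r, event = ev))
      }
    }
    if (is.na(r$lo)) {
      i <- r$seed; kind <- "seed"
      r$lo <- i; r$hi <- i
    } else {
      can_lo <- r$lo > 1L; can_hi <- r$hi < length(r$abs)
      if (!can_lo && !can_hi) return(list(region = r, event = NULL))
      side <- if (can_lo && can_hi) sample(c("lo", "hi"), 1L)
              else if (can_lo) "lo" else "hi"
      if (side == "lo") { r$lo <- r$lo - 1L; i <- r$lo }
      else { r$hi <- r$hi + 1L; i <- r$hi }
      kind <- "extend"
    }
    ev <- data.frame(species = species, position = r$abs[i],
                     from = chain[r$abs[i]], to = r$bases[i],
                     kind = kind, region = r$name, stringsAsFactors = FALSE)
    chain[r$abs[i]] <<- r$bases[i]
    list(region = r, event = ev)
  }

  tips <- list()
  ident <- stats::setNames(numeric(nrow(cfg$panel)), cfg$panel$name)
  prev_age <- cfg$panel$age_mya[1L] + cfg$ancestor_gap_my
  for (sp_i in seq_len(nrow(cfg$panel))) {
    species <- cfg$panel$name[sp_i]
    delta <- prev_age - cfg$panel$age_mya[sp_i]
    prev_age <- cfg$panel$age_mya[sp_i]

    ## biased growth
    n_grow <- stats::rpois(1L, cfg$growth_rate * delta * n_regions)
    for (e in seq_len(n_grow)) {
      work <- vapply(regions_state, region_work, numeric(1))
      if (all(work == 0)) break
      ri <- sample.int(n_regions, 1L, prob = work)
      out <- apply_growth_event(regions_state[[ri]], species)
      regions_state[[ri]] <- out$region
      if (!is.null(out$event)) {
        fixed_ev[[length(fixed_ev) + 1L]] <- out$event
        if (is.na(root_species) && out$event$kind == "seed" &&
            ri <= n_target_regions)
          root_species <- species
      }
    }

    ## background substitutions (inherited)
    n_bg <- stats::rpois(1L, (cfg$background_rate / 100) * delta * length(mutable))
    if (n_bg > 0L) {
      pos <- sample(mutable, min(n_bg, length(mutable)))
      for (p in pos) {
        to <- sample(setdiff(.BASES, chain[p]), 1L)
        bg_ev[[length(bg_ev) + 1L]] <- data.frame(
          species = species, position = p, from = chain[p], to = to,
          stringsAsFactors = FALSE)
        chain[p] <- to
      }
    }

    ## guidepost drift: third-position synonymous changes only (logged with
    ## the other inherited substitutions so the chain replays exactly)
    n_gp <- stats::rpois(1L, (cfg$background_rate / 1000) * delta * Lg)
    for (e in seq_len(n_gp)) {
      cod_i <- sample.int(Lg %/% 3L, 1L)
      p3 <- gp_s + 3L * (cod_i - 1L) + 2L
      codon <- paste(chain[(p3 - 2L):p3], collapse = "")
      alt <- setdiff(.BASES, chain[p3])
      syn <- alt[vapply(alt, function(b) {
        cod2 <- paste0(substr(codon, 1, 2), b)
        !is.na(code[cod2]) && !is.na(code[codon]) && code[cod2] == code[codon]
      }, logical(1))]
      if (length(syn)) {
        to <- sample(c(syn, syn), 1L)
        bg_ev[[length(bg_ev) + 1L]] <- data.frame(
          species = species, position = p3, from = chain[p3], to = to,
          stringsAsFactors = FALSE)
        chain[p3] <- to
      }
    }

    ident[species] <- mean(chain[tgt_s:tgt_e] == tgt)

    ## emit tip: private dead-end events, never inherited
    tip <- chain
    n_tip <- stats::rpois(1L, (cfg$background_rate / 100) *
                            cfg$dead_end_tip_my * length(mutable))
    if (n_tip > 0L) {
      pos <- sample(mutable, min(n_tip, length(mutable)))
      for (p in pos) {
        choices <- setdiff(.BASES, tip[p])
        if (in_target[p]) choices <- setdiff(choices, target_base[p])
        to <- sample(c(choices, choices), 1L)
        rnd_ev[[length(rnd_ev) + 1L]] <- data.frame(
          species = species, position = p, from = tip[p], to = to,
          stringsAsFactors = FALSE)
        tip[p] <- to
      }
    }
    tip_str <- paste(tip, collapse = "")
    if (stats::runif(1L) < cfg$dead_end_prob) {
      in_tg <- stats::runif(1L) < 0.7
      len <- sample(1:9, 1L)
      kind <- sample(c("insertion", "deletion"), 1L)
      pos <- if (in_tg) sample(tgt_s:(tgt_e - len), 1L)
             else sample(1:(gp_s - len - 1L), 1L)
      if (kind == "deletion") {
        removed <- substr(tip_str, pos, pos + len - 1L)
        tip_str <- paste0(substr(tip_str, 1L, pos - 1L),
                          substr(tip_str, pos + len, nchar(tip_str)))
        sq <- removed
      } else {
        sq <- paste(.random_bases(len, cfg$gc_content), collapse = "")
        tip_str <- paste0(substr(tip_str, 1L, pos), sq,
                          substr(tip_str, pos + 1L, nchar(tip_str)))
      }
      indel_ev[[length(indel_ev) + 1L]] <- data.frame(
        species = species, position = pos, kind = kind, seq = sq,
        length = len, slippage = FALSE, in_target = in_tg,
        stringsAsFactors = FALSE)
    }
    if (cfg$slippage_on_terminal && sp_i == nrow(cfg$panel)) {
      ## duplicate one unit of a tandem repeat in the 5' flank
      flank <- substr(tip_str, 1L, gp_s - 1L)
      runs <- tandem_repeats(flank, 4L, 2L)
      if (nrow(runs)) {
        r1 <- runs[1L, ]
        at <- r1$start + 4L * r1$copies - 1L
        tip_str <- paste0(substr(tip_str, 1L, at), r1$unit,
                          substr(tip_str, at + 1L, nchar(tip_str)))
        indel_ev[[length(indel_ev) + 1L]] <- data.frame(
          species = species, position = at, kind = "insertion",
          seq = r1$unit, length = 4L, slippage = TRUE, in_target = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    tips[[species]] <- seq_record(
      species, tip_str, "dna",
      sprintf("simulated inter-anchor region, age %s MYA",
              format(cfg$panel$age_mya[sp_i])))
  }

  bind <- function(x, cols) {
    if (length(x)) do.call(rbind, x) else
      stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  }
  truth <- list(
    root_species = root_species,
    ancestral = ancestral,
    seed_positions = as.integer(tgt_s - 1L + seeds_rel),
    loci = list(guidepost = c(gp_s, gp_e),
                silencer = c(sil_s, sil_e),
                silencer1 = c(sil_s, sil_s + s1len - 1L),
                silencer2 = if (s2_e >= s2_s) c(s2_s, s2_e) else NULL,
                target = c(tgt_s, tgt_e)),
    fixed_events = bind(fixed_ev, c("species", "position", "from", "to",
                                    "kind", "region")),
    background_events = bind(bg_ev, c("species", "position", "from", "to")),
    random_events = bind(rnd_ev, c("species", "position", "from", "to")),
    indel_events = bind(indel_ev, c("species", "position", "kind", "seq",
                                    "length", "slippage", "in_target")),
    per_species_target_identity = ident)
  structure(list(regions = tips, truth = truth, config = cfg),
            class = "genesis_sim")
}

#' Write a simulated panel to disk
#'
#' Writes one FASTA per species, a panel TSV (`name`, `age_mya`, `fasta`)
#' and the ground truth as JSON. Re-running with the same configuration
#' reproduces byte-identical outputs.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `panel_tsv`, `truth_json`, `fastas`, and
#'   the `genesis_sim` object as `sim`.
#' @export
emit_panel <- function(cfg, outdir) {
  sim <- simulate_genesis(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  fastas <- character()
  for (nm in names(sim$regions)) {
    f <- file.path(outdir, paste0(nm, ".fasta"))
    write_fasta(sim$regions[[nm]], f)
    fastas[nm] <- f
  }
  panel_tsv <- file.path(outdir, "panel.tsv")
  df <- data.frame(name = cfg$panel$name, age_mya = cfg$panel$age_mya,
                   fasta = paste0(cfg$panel$name, ".fasta"))
  utils::write.table(df, panel_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_json <- file.path(outdir, "truth.json")
  jsonlite::write_json(sim$truth, truth_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(panel_tsv = panel_tsv, truth_json = truth_json,
                 fastas = fastas, sim = sim))
}
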