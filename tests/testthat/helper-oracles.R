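## Independent oracles used across the suite. These deliberately take naive
## routes (path enumeration, quadratic scans, direct recursion) so that they
## share no code path with the package implementation.

## Exhaustive global alignment score by enumerating every alignment path
## (diagonal / up / left moves) with affine gap costs: a gap of length L
## costs open + (L - 1) * ext. Exponential; only for tiny strings.
enum_global_score <- function(a, b, match = 2, mismatch = -3,
                              open = 5, ext = 2) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  rec <- function(i, j, last) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "d"))
    }
    if (i <= length(av))   # gap in b
      best <- max(best,
                  -(if (last == "u") ext else open) + rec(i + 1L, j, "u"))
    if (j <= length(bv))   # gap in a
      best <- max(best,
                  -(if (last == "l") ext else open) + rec(i, j + 1L, "l"))
    best
  }
  rec(1L, 1L, "d")
}

## Local score oracle: best global score over all substring pairs, or 0.
enum_local_score <- function(a, b, ...) {
  best <- 0
  na <- nchar(a); nb <- nchar(b)
  for (i in seq_len(na)) for (j in i:na)
    for (k in seq_len(nb)) for (l in k:nb)
      best <- max(best, enum_global_score(substr(a, i, j), substr(b, k, l), ...))
  best
}

## Gotoh three-state DP, written independently of the package (which
## delegates to Biostrings). Validated against the enumerator on tiny
## inputs, then used as the oracle at larger sizes.
gotoh_score <- function(a, b, match = 2, mismatch = -3, open = 5, ext = 2,
                        local = FALSE) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)   # last pair aligned
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in b (consumes a)
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in seq_len(n) + 1L) {
    X[i, 1] <- -open - (i - 2L) * ext
    if (local) M[i, 1] <- 0
  }
  for (j in seq_len(m) + 1L) {
    Y[1, j] <- -open - (j - 2L) * ext
    if (local) M[1, j] <- 0
  }
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      s <- if (av[i - 1L] == bv[j - 1L]) match else mismatch
      M[i, j] <- s + max(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      if (local) M[i, j] <- max(M[i, j], 0)
      X[i, j] <- max(M[i - 1L, j] - open, X[i - 1L, j] - ext)
      Y[i, j] <- max(M[i, j - 1L] - open, Y[i, j - 1L] - ext)
      if (local) best <- max(best, M[i, j])
    }
  }
  if (local) best else max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

## Naive quadratic tandem-repeat scan mirroring the documented semantics:
## scan left to right, report a maximal run, resume past it.
brute_tandem <- function(s, unit_len, min_copies) {
  n <- nchar(s)
  out <- list()
  i <- 1L
  while (i + unit_len - 1L <= n) {
    unit <- substr(s, i, i + unit_len - 1L)
    if (grepl("[^acgt]", unit)) { i <- i + 1L; next }
    k <- 1L
    repeat {
      nxt <- substr(s, i + k * unit_len, i + (k + 1L) * unit_len - 1L)
      if (nchar(nxt) == unit_len && nxt == unit) k <- k + 1L else break
    }
    if (k >= min_copies) {
      out[[length(out) + 1L]] <- list(start = i, unit = unit, copies = k)
      i <- i + k * unit_len
    } else i <- i + 1L
  }
  out
}

## All strings of the given lengths over an alphabet.
all_strings <- function(alphabet, lengths) {
  unlist(lapply(lengths, function(L) {
    grid <- do.call(expand.grid, rep(list(alphabet), L))
    apply(grid, 1, paste, collapse = "")
  }), use.names = FALSE)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("a", "c", "g", "t"), n, replace = TRUE, prob = p),
        collapse = "")
}

## Replay a genesis_sim event log over the ancestral sequence, returning the
## inherited (chain) state of each species as a character vector of bases.
## Independent bookkeeping route used to validate simulator truth.
replay_chain <- function(sim) {
  cfg <- sim$config
  tr <- sim$truth
  chain <- strsplit(tr$ancestral, "", fixed = TRUE)[[1]]
  out <- list()
  for (sp in cfg$panel$name) {
    fe <- tr$fixed_events
    if (nrow(fe)) {
      fe <- fe[fe$species == sp, , drop = FALSE]
      for (r in seq_len(nrow(fe))) chain[fe$position[r]] <- fe$to[r]
    }
    be <- tr$background_events
    if (nrow(be)) {
      be <- be[be$species == sp, , drop = FALSE]
      for (r in seq_len(nrow(be))) chain[be$position[r]] <- be$to[r]
    }
    out[[sp]] <- chain
  }
  out
}

## Per-species observed (tip) state before indels: chain plus private subs.
replay_tip <- function(chains, truth, sp) {
  tip <- chains[[sp]]
  re <- truth$random_events
  if (nrow(re)) {
    re <- re[re$species == sp, , drop = FALSE]
    for (r in seq_len(nrow(re))) tip[re$position[r]] <- re$to[r]
  }
  tip
}

## Map a region coordinate to the emitted-sequence coordinate of a species,
## accounting for that species' logged indel events. NA if deleted.
map_to_emitted <- function(truth, sp, pos) {
  ev <- truth$indel_events
  ev <- ev[ev$species == sp, , drop = FALSE]
  p <- pos
  if (nrow(ev)) {
    ev <- ev[order(ev$position), , drop = FALSE]
    for (r in seq_len(nrow(ev))) {
      q <- ev$position[r]; L <- ev$length[r]
      if (ev$kind[r] == "insertion") {
        p <- ifelse(p > q, p + L, p)
      } else {
        p <- ifelse(is.na(p), NA,
             ifelse(p < q, p, ifelse(p <= q + L - 1L, NA, p - L)))
      }
    }
  }
  p
}

## Truth category of one (anc, mid, desc) base column - the five-way rule
## restated independently of the package.
truth_category <- function(a, m, d) {
  if (a == m && m == d) "conserved"
  else if (m == d && m != a) "fixed"
  else if (m != a && m != d) "random_mid"
  else "desc_specific"
}

default_scheme <- function() scoring_scheme()
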