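# Reference implementations used as independent oracles. The aligner
# oracle is a plain quadratic-space dynamic program over full matrices,
# written against the documented conventions (gap of length L costs
# open + (L-1)*extend; identity counts identical columns over all
# alignment columns; tie-breaks: first best cell in row-major order,
# diagonal > horizontal gap > vertical gap, gap opening preferred over
# extension on ties).

sw_oracle_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

sw_oracle <- function(a, b, gap_open = 11, gap_extend = 1) {
  S <- sw_oracle_matrix()
  ca <- chartr("UO", "XX", a); cb <- chartr("UO", "XX", b)
  av <- strsplit(ca, "")[[1]]; bv <- strsplit(cb, "")[[1]]
  m <- length(av); n <- length(bv)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0; bi <- NA; bj <- NA
  for (i in 1:m) for (j in 1:n) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - gap_open, E[i + 1, j] - gap_extend)
    F[i + 1, j + 1] <- max(H[i, j + 1] - gap_open, F[i, j + 1] - gap_extend)
    diag <- H[i, j] + S[av[i], bv[j]]
    h <- max(0, diag, E[i + 1, j + 1], F[i + 1, j + 1])
    H[i + 1, j + 1] <- h
    if (h > best) { best <- h; bi <- i; bj <- j }
  }
  if (best == 0)
    return(list(score = 0, identity = 0, coverage_query = 0,
                coverage_target = 0))
  i <- bi; j <- bj
  a_end <- i; b_end <- j; a_start <- i; b_start <- j
  ident <- 0; cols <- 0; state <- "H"
  while (i > 0 && j > 0) {
    if (state == "H") {
      h <- H[i + 1, j + 1]
      if (h == 0) break
      diag <- H[i, j] + S[av[i], bv[j]]
      if (h == diag) {
        cols <- cols + 1
        if (av[i] == bv[j]) ident <- ident + 1
        a_start <- i; b_start <- j
        i <- i - 1; j <- j - 1
      } else if (h == E[i + 1, j + 1]) state <- "E"
      else state <- "F"
    } else if (state == "E") {
      cols <- cols + 1
      b_start <- j
      open <- H[i + 1, j] - gap_open
      from_open <- E[i + 1, j + 1] == open
      j <- j - 1
      if (from_open) state <- "H"
    } else {
      cols <- cols + 1
      a_start <- i
      open <- H[i, j + 1] - gap_open
      from_open <- F[i + 1, j + 1] == open
      i <- i - 1
      if (from_open) state <- "H"
    }
  }
  list(score = best, identity = ident / cols,
       coverage_query = (a_end - a_start + 1) / m,
       coverage_target = (b_end - b_start + 1) / n)
}

# brute-force greedy clustering: full pairwise matrix first, then the same
# ordering and absorption rule as greedy_cluster()
brute_force_cluster <- function(proteins, min_identity, min_coverage) {
  ord <- order(-nchar(proteins$sequence), proteins$protein_id)
  ids <- proteins$protein_id[ord]; seqs <- proteins$sequence[ord]
  n <- length(ids)
  ok <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { ok[i, j] <- TRUE; next }
    al <- align_pair(seqs[j], seqs[i])
    ok[i, j] <- al$identity >= min_identity &&
      al$coverage_query >= min_coverage && al$coverage_target >= min_coverage
  }
  assigned <- integer(n); cl <- 0L
  for (i in seq_len(n)) {
    if (assigned[i] > 0) next
    cl <- cl + 1L
    assigned[i] <- cl
    for (j in seq_len(n))
      if (assigned[j] == 0 && ok[i, j]) assigned[j] <- cl
  }
  stats::setNames(assigned, ids)
}

random_seq <- function(len) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K",
                 "M","F","P","S","T","W","Y","V"), len, replace = TRUE),
        collapse = "")
}

# column identity of two equal-length, ungapped sequences
column_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  mean(av == bv)
}
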