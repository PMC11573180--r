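#' Existence-level proportions for HP and non-HP cohorts
#'
#' Counts UniProt protein-existence levels (1 = protein level, 2 =
#' transcript level, 3 = inferred from homology, 4 = predicted; the
#' "Uncertain" level 5 must already have been excluded on ingest) for the
#' HP cohort and its complement, and expresses each as a percentage of its
#' cohort.
#'
#' @param proteins Protein table with `protein_id` and `existence_level`.
#' @param hp_ids Character vector of HP protein ids.
#' @return A list with `hp_counts`, `nonhp_counts`, `hp_pct`, `nonhp_pct`,
#'   each a named numeric vector over levels `"1"`-`"4"`.
#' @export
existence_proportions <- function(proteins, hp_ids) {
  lv <- proteins$existence_level
  if (anyNA(lv)) stop("existence_level absent for some proteins")
  if (any(lv == 5)) stop("existence level 5 must be excluded at ingest")
  if (!all(lv %in% 1:4)) stop("existence_level outside 1-4")
  is_hp <- proteins$protein_id %in% hp_ids
  count4 <- function(x) {
    out <- tabulate(x, nbins = 4L)
    names(out) <- as.character(1:4)
    out
  }
  hp_counts <- count4(lv[is_hp])
  nonhp_counts <- count4(lv[!is_hp])
  pct <- function(cnt) if (sum(cnt) == 0) cnt * 0 else 100 * cnt / sum(cnt)
  list(hp_counts = hp_counts, nonhp_counts = nonhp_counts,
       hp_pct = pct(hp_counts), nonhp_pct = pct(nonhp_counts))
}

#' Fixed-size resampling of the non-HP cohort
#'
#' Draws `n_reps` samples of `sample_size` proteins without replacement
#' from the non-HP existence levels, counts each level per replicate, and
#' reports the per-level mean and standard deviation of those counts.
#' Deterministic for a fixed seed.
#'
#' @param nonhp_levels Integer vector of existence levels (1-4), one per
#'   non-HP protein.
#' @param sample_size Sample size per replicate (the HP cohort size in the
#'   survey design); must not exceed the population size.
#' @param n_reps Number of replicates (the survey uses 5, 10 and 100).
#' @param seed Integer seed.
#' @return A `data.frame` with `level`, `mean_count`, `sd_count`,
#'   `mean_pct`.
#' @export
resample_nonhp <- function(nonhp_levels, sample_size, n_reps, seed) {
  n <- length(nonhp_levels)
  if (sample_size > n)
    stop("sample_size (", sample_size, ") exceeds population size (", n, ")")
  stopifnot(n_reps >= 1)
  counts <- matrix(0L, nrow = n_reps, ncol = 4L)
  withr_seed(seed, {
    for (r in seq_len(n_reps)) {
      smp <- nonhp_levels[sample.int(n, sample_size)]
      counts[r, ] <- tabulate(smp, nbins = 4L)
    }
  })
  data.frame(level = 1:4,
             mean_count = colMeans(counts),
             sd_count = apply(counts, 2, stats::sd),
             mean_pct = 100 * colMeans(counts) / sample_size)
}

# run code under a locally-set RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Kruskal-Wallis and one-way ANOVA on existence levels
#'
#' Compares the HP and non-HP cohorts treating the existence level of each
#' protein as an ordinal score (1-4, smaller = stronger evidence), two
#' groups. The Kruskal-Wallis H uses the standard tie correction
#' `1 - sum(t^3 - t) / (N^3 - N)`; the F statistic is the textbook
#' between/within mean-square ratio. Both are computed natively (the test
#' suite checks them against the reference implementations in `stats`).
#'
#' @param hp_levels,nonhp_levels Integer vectors of per-protein existence
#'   levels; each cohort needs at least 2 proteins.
#' @return A list with `kruskal_h`, `kruskal_p` (chi-squared, 1 df),
#'   `anova_f`, `anova_p` (F with 1 and N-2 df).
#' @export
compare_distributions <- function(hp_levels, nonhp_levels) {
  n1 <- length(hp_levels); n2 <- length(nonhp_levels)
  if (n1 < 2 || n2 < 2)
    stop("each cohort needs at least 2 observations")
  x <- c(hp_levels, nonhp_levels)
  g <- rep(1:2, c(n1, n2))
  N <- n1 + n2
  # Kruskal-Wallis with tie correction
  r <- rank(x)
  R1 <- sum(r[g == 1]); R2 <- sum(r[g == 2])
  H <- 12 / (N * (N + 1)) * (R1^2 / n1 + R2^2 / n2) - 3 * (N + 1)
  ties <- table(x)
  denom <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- if (denom == 0) 0 else H / denom
  kruskal_p <- stats::pchisq(H, df = 1, lower.tail = FALSE)
  # one-way ANOVA on the same scores
  gm <- mean(x)
  m1 <- mean(hp_levels); m2 <- mean(nonhp_levels)
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- sum((hp_levels - m1)^2) + sum((nonhp_levels - m2)^2)
  Fstat <- (ssb / 1) / (ssw / (N - 2))
  anova_p <- stats::pf(Fstat, 1, N - 2, lower.tail = FALSE)
  list(kruskal_h = H, kruskal_p = kruskal_p,
       anova_f = Fstat, anova_p = anova_p)
}

#' Pearson correlations of BUSCO completeness with HP count and length
#'
#' For each superkingdom separately: the correlation between proteome
#' completeness and the proteome's HP count, and between completeness and
#' the length of each HP (each HP paired with its proteome's
#' completeness). Proteomes without a completeness score are excluded and
#' counted; groups with fewer than 3 points report `NA`.
#'
#' @param meta Kept proteome metadata.
#' @param hps An `hp_set`.
#' @return A `data.frame` with `superkingdom`, `metric`
#'   (`"hp_count"`/`"hp_length"`), `r`, `n_used`, `n_excluded`.
#' @export
quality_correlations <- function(meta, hps) {
  stopifnot(inherits(hps, "hp_set"))
  counts <- table(hps$hp$proteome_id)
  hp_count <- as.integer(counts[match(meta$proteome_id, names(counts))])
  hp_count[is.na(hp_count)] <- 0L
  midx <- match(hps$hp$proteome_id, meta$proteome_id)
  # Pearson r, NA (not a warning) for degenerate zero-variance inputs
  safe_cor <- function(x, y) {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    stats::cor(x, y)
  }
  rows <- list()
  for (sk in sort(unique(meta$superkingdom))) {
    ii <- meta$superkingdom == sk
    ok <- ii & !is.na(meta$busco_completeness)
    r_count <- safe_cor(meta$busco_completeness[ok], hp_count[ok])
    rows[[length(rows) + 1L]] <- data.frame(
      superkingdom = sk, metric = "hp_count", r = r_count,
      n_used = sum(ok), n_excluded = sum(ii) - sum(ok),
      stringsAsFactors = FALSE)
    jj <- !is.na(midx) & meta$superkingdom[midx] == sk
    bc <- meta$busco_completeness[midx[jj]]
    len <- hps$hp$length[jj]
    use <- !is.na(bc)
    r_len <- safe_cor(bc[use], len[use])
    rows[[length(rows) + 1L]] <- data.frame(
      superkingdom = sk, metric = "hp_length", r = r_len,
      n_used = sum(use), n_excluded = sum(jj) - sum(use),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' HP counts by genome assembly level
#'
#' Groups kept proteomes by superkingdom and the verbatim assembly-level
#' string and summarizes the distribution of per-proteome HP counts
#' (median and quartiles, type-7). Empty groups are absent from the
#' output.
#'
#' @inheritParams quality_correlations
#' @return A `data.frame` with `superkingdom`, `assembly_level`, `n`,
#'   `q1`, `median`, `q3`.
#' @export
assembly_level_summary <- function(meta, hps) {
  stopifnot(inherits(hps, "hp_set"))
  counts <- table(hps$hp$proteome_id)
  hp_count <- as.integer(counts[match(meta$proteome_id, names(counts))])
  hp_count[is.na(hp_count)] <- 0L
  grp <- split(hp_count, list(meta$superkingdom, meta$assembly_level),
               sep = "\t", drop = TRUE)
  out <- do.call(rbind, lapply(names(grp), function(k) {
    parts <- strsplit(k, "\t", fixed = TRUE)[[1L]]
    q <- stats::quantile(grp[[k]], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(superkingdom = parts[1], assembly_level = parts[2],
               n = length(grp[[k]]), q1 = q[1], median = q[2], q3 = q[3],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$superkingdom, out$assembly_level), , drop = FALSE]
  rownames(out) <- NULL
  out
}
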