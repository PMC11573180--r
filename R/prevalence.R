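#' Extract huge proteins from a protein table
#'
#' A protein is a huge protein (HP) iff its length is greater than or equal
#' to `min_length`; the boundary is inclusive, so a 5000-residue protein is
#' an HP and a 4999-residue one is not.
#'
#' @param proteins Protein table with `protein_id`, `proteome_id`,
#'   `length`.
#' @param min_length Length threshold in residues (default 5000).
#' @return An object of class `hp_set`: a list with `min_length` and `hp`,
#'   the HP subset of `proteins` (columns `protein_id`, `proteome_id`,
#'   `length`).
#' @export
extract_hps <- function(proteins, min_length = 5000) {
  stopifnot(min_length >= 1)
  keep <- proteins$length >= min_length
  hp <- proteins[keep, intersect(c("protein_id", "proteome_id", "length"),
                                 names(proteins)), drop = FALSE]
  rownames(hp) <- NULL
  structure(list(min_length = min_length, hp = hp), class = "hp_set")
}

#' @export
print.hp_set <- function(x, ...) {
  cat("hp_set:", nrow(x$hp), "proteins with length >=", x$min_length, "\n")
  invisible(x)
}

#' Filter proteomes before prevalence statistics
#'
#' Applies, in order: (1) drop every proteome in a phylum represented by
#' fewer than 5 proteomes; (2) within each surviving phylum, drop proteomes
#' whose size is strictly smaller than the phylum mean minus the phylum
#' sample standard deviation, both computed over the phylum *before* any
#' size-based removal (not iterated); (3) drop plasmid proteomes. Each
#' removal is logged with the rule that triggered it.
#'
#' @param meta Proteome metadata from [read_metadata()].
#' @param min_phylum_proteomes Minimum proteomes per phylum (default 5).
#' @return A list with `kept` (the surviving metadata rows) and `removed`
#'   (data.frame: `proteome_id`, `rule` in
#'   `c("small_phylum", "small_proteome", "plasmid")`).
#' @export
filter_proteomes <- function(meta, min_phylum_proteomes = 5) {
  removed <- data.frame(proteome_id = character(), rule = character(),
                        stringsAsFactors = FALSE)
  log_removed <- function(ids, rule) {
    if (length(ids))
      removed <<- rbind(removed, data.frame(proteome_id = ids, rule = rule,
                                            stringsAsFactors = FALSE))
  }
  # rule 1: phyla with too few proteomes
  counts <- table(meta$phylum)
  small <- names(counts)[counts < min_phylum_proteomes]
  drop1 <- meta$phylum %in% small
  log_removed(meta$proteome_id[drop1], "small_phylum")
  meta <- meta[!drop1, , drop = FALSE]
  # rule 2: undersized proteomes relative to their phylum (mean - sample SD
  # computed once, before removal; strict <, so zero-SD phyla lose nothing)
  drop2 <- logical(nrow(meta))
  for (ph in unique(meta$phylum)) {
    ii <- which(meta$phylum == ph)
    s <- meta$proteome_size[ii]
    cutoff <- mean(s) - stats::sd(s)
    if (is.na(cutoff)) next
    drop2[ii[s < cutoff]] <- TRUE
  }
  log_removed(meta$proteome_id[drop2], "small_proteome")
  meta <- meta[!drop2, , drop = FALSE]
  # rule 3: plasmids
  drop3 <- !is.na(meta$is_plasmid) & meta$is_plasmid
  log_removed(meta$proteome_id[drop3], "plasmid")
  meta <- meta[!drop3, , drop = FALSE]
  rownames(meta) <- NULL
  list(kept = meta, removed = removed)
}

#' Per-proteome and per-phylum HP likelihood
#'
#' The likelihood of a proteome to contain huge proteins is
#' `L = 100 * h / s` (h = HP count, s = proteome size, in percent). Phylum
#' summaries report the exact median of L over the phylum's kept proteomes
#' and are sorted by superkingdom, then median likelihood descending.
#'
#' @param hps An `hp_set` from [extract_hps()].
#' @param meta Kept proteome metadata (after [filter_proteomes()]).
#' @return A list with `per_proteome` (`proteome_id`, `superkingdom`,
#'   `phylum`, `proteome_size`, `hp_count`, `likelihood_pct`) and
#'   `per_phylum` (`superkingdom`, `phylum`, `n_proteomes`,
#'   `median_likelihood_pct`).
#' @export
phylum_likelihood <- function(hps, meta) {
  stopifnot(inherits(hps, "hp_set"))
  counts <- table(hps$hp$proteome_id)
  orphan <- setdiff(names(counts), meta$proteome_id)
  if (length(orphan))
    warning(length(orphan),
            " proteome(s) with HPs absent from kept metadata excluded")
  hp_count <- as.integer(counts[match(meta$proteome_id, names(counts))])
  hp_count[is.na(hp_count)] <- 0L
  per_proteome <- data.frame(
    proteome_id = meta$proteome_id, superkingdom = meta$superkingdom,
    phylum = meta$phylum, proteome_size = meta$proteome_size,
    hp_count = hp_count,
    likelihood_pct = 100 * hp_count / meta$proteome_size,
    stringsAsFactors = FALSE)
  per_phylum <- stats::aggregate(
    list(median_likelihood_pct = per_proteome$likelihood_pct),
    by = list(superkingdom = per_proteome$superkingdom,
              phylum = per_proteome$phylum),
    FUN = stats::median)
  nprot <- stats::aggregate(
    list(n_proteomes = per_proteome$likelihood_pct),
    by = list(superkingdom = per_proteome$superkingdom,
              phylum = per_proteome$phylum),
    FUN = length)
  per_phylum <- merge(per_phylum, nprot,
                      by = c("superkingdom", "phylum"))
  per_phylum <- per_phylum[order(per_phylum$superkingdom,
                                 -per_phylum$median_likelihood_pct,
                                 per_phylum$phylum),
                           c("superkingdom", "phylum", "n_proteomes",
                             "median_likelihood_pct")]
  rownames(per_phylum) <- NULL
  list(per_proteome = per_proteome, per_phylum = per_phylum)
}

#' Proteome size versus HP count table
#'
#' Plumbing for the size-vs-count scatter: one row per kept proteome with
#' the base-10 log of its size and its HP count.
#'
#' @inheritParams phylum_likelihood
#' @return A `data.frame` with `proteome_id`, `superkingdom`,
#'   `log10_size`, `hp_count`.
#' @export
proteome_size_vs_hp_table <- function(hps, meta) {
  stopifnot(inherits(hps, "hp_set"))
  counts <- table(hps$hp$proteome_id)
  hp_count <- as.integer(counts[match(meta$proteome_id, names(counts))])
  hp_count[is.na(hp_count)] <- 0L
  data.frame(proteome_id = meta$proteome_id,
             superkingdom = meta$superkingdom,
             log10_size = log10(meta$proteome_size),
             hp_count = hp_count, stringsAsFactors = FALSE)
}
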