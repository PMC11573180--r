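#' Filter Pfam domain hits by E-value
#'
#' Keeps hits with full-sequence E-value <= `seq_e` AND domain
#' (independent) E-value <= `dom_e`; the survey thresholds are 0.001 for
#' both. Raising either threshold never removes a previously kept hit.
#'
#' @param hits Hit table from [read_domtblout()].
#' @param seq_e,dom_e E-value thresholds (default 0.001 each).
#' @return The filtered hit table.
#' @export
filter_hits <- function(hits, seq_e = 0.001, dom_e = 0.001) {
  keep <- hits$seq_evalue <= seq_e & hits$dom_ievalue <= dom_e
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve overlapping domain hits within each protein
#'
#' Two hits conflict when their envelope overlap exceeds `max_overlap`
#' (default 50%) of the shorter envelope. Hits are admitted greedily in
#' descending bit-score order (ties: smaller domain E-value, then
#' lexicographic accession); a hit conflicting with an already-admitted
#' one is discarded. The retained hits are returned sorted by `env_from`.
#'
#' @param hits Filtered hit table (may span several proteins; resolution
#'   is per protein).
#' @param max_overlap Maximum tolerated overlap as a fraction of the
#'   shorter envelope (0 reproduces strict non-overlap).
#' @return The overlap-resolved hit table, sorted by protein then
#'   `env_from`.
#' @export
resolve_overlaps <- function(hits, max_overlap = 0.5) {
  if (nrow(hits) == 0L) return(hits)
  res <- lapply(split(hits, hits$protein_id), function(h) {
    ord <- order(-h$bitscore, h$dom_ievalue, h$pfam_accession)
    h <- h[ord, , drop = FALSE]
    kept <- integer(0)
    for (i in seq_len(nrow(h))) {
      ov <- FALSE
      for (k in kept) {
        olap <- min(h$env_to[i], h$env_to[k]) -
          max(h$env_from[i], h$env_from[k]) + 1L
        shorter <- min(h$env_to[i] - h$env_from[i],
                       h$env_to[k] - h$env_from[k]) + 1L
        if (olap > max_overlap * shorter) { ov <- TRUE; break }
      }
      if (!ov) kept <- c(kept, i)
    }
    h <- h[kept, , drop = FALSE]
    h[order(h$env_from, h$env_to, h$pfam_accession), , drop = FALSE]
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

strip_pfam_version <- function(acc) sub("\\.\\d+$", "", acc)

#' Deduce per-protein domain architectures
#'
#' Orders the overlap-resolved hits of each protein by envelope start,
#' strips Pfam version suffixes, and joins the accessions with `|` into
#' the canonical architecture pattern. Consecutive repeats are *not*
#' collapsed (repeat counts are meaningful); a secondary collapsed pattern
#' replaces each run of the same accession with `accession*`. Proteins in
#' `protein_ids` without any hit get an empty pattern (the no-domain set).
#'
#' @param hits Overlap-resolved hit table.
#' @param protein_ids Optional character vector of all protein ids to
#'   report (defaults to the proteins present in `hits`).
#' @return A `data.frame` with `protein_id`, `pattern`,
#'   `pattern_collapsed`, `n_domains`.
#' @export
deduce_architecture <- function(hits, protein_ids = NULL) {
  pats <- lapply(split(hits, hits$protein_id), function(h) {
    h <- h[order(h$env_from, h$env_to), , drop = FALSE]
    acc <- strip_pfam_version(h$pfam_accession)
    rl <- rle(acc)
    collapsed <- paste(ifelse(rl$lengths > 1L, paste0(rl$values, "*"),
                              rl$values), collapse = "|")
    c(pattern = paste(acc, collapse = "|"), collapsed = collapsed,
      n = as.character(length(acc)))
  })
  ids <- if (is.null(protein_ids)) names(pats) else unique(protein_ids)
  idx <- match(ids, names(pats))
  data.frame(
    protein_id = ids,
    pattern = ifelse(is.na(idx), "",
                     vapply(idx, function(i) if (is.na(i)) "" else pats[[i]][["pattern"]], character(1))),
    pattern_collapsed = ifelse(is.na(idx), "",
                               vapply(idx, function(i) if (is.na(i)) "" else pats[[i]][["collapsed"]], character(1))),
    n_domains = ifelse(is.na(idx), 0L,
                       as.integer(vapply(idx, function(i) if (is.na(i)) "0" else pats[[i]][["n"]], character(1)))),
    stringsAsFactors = FALSE)
}

# stable 6-character base-36 code from the FNV-1a 64-bit digest of a string
pattern_code <- function(pattern, hash_fun = NULL) {
  digest <- if (is.null(hash_fun)) .fnv1a64_cpp(pattern) else hash_fun(pattern)
  vapply(digest, function(h) {
    # fold the hex digest into a number and render 6 base-36 chars
    v <- strtoi(substring(h, seq(1, 15, by = 2), seq(2, 16, by = 2)), 16L)
    x <- 0
    for (b in v) x <- (x * 256 + b) %% (36^6)
    chars <- character(6)
    for (i in 6:1) {
      chars[i] <- substr("0123456789ABCDEFGHIJKLMNOPQRSTUVWXYZ",
                         x %% 36 + 1, x %% 36 + 1)
      x <- x %/% 36
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Group identical architectures and assign 6-character codes
#'
#' Exact pattern equality (order matters: `A|B` and `B|A` differ) defines
#' the groups. Each distinct pattern gets a stable 6-character code derived
#' from a fixed 64-bit hash of the pattern, rendered in upper-case base
#' 36. Truncated-hash collisions are resolved deterministically by
#' appending `#1`, `#2`, ... to the pattern and rehashing until unique;
#' patterns are processed in sorted order so the outcome does not depend on
#' input order.
#'
#' @param architectures Architecture table from [deduce_architecture()];
#'   empty patterns (no-domain proteins) are excluded from grouping.
#' @param hash_fun Optional replacement hash (character -> character hex
#'   digest of 16 hex digits); used to exercise collision handling.
#' @return A list with `groups` (data.frame: `pattern`, `group_code`,
#'   `n_proteins`) and `assignment` (data.frame: `protein_id`, `pattern`,
#'   `group_code`).
#' @export
group_architectures <- function(architectures, hash_fun = NULL) {
  nonempty <- architectures[nzchar(architectures$pattern), , drop = FALSE]
  pats <- sort(unique(nonempty$pattern))
  codes <- character(length(pats))
  used <- character(0)
  for (i in seq_along(pats)) {
    cand <- pattern_code(pats[i], hash_fun)
    k <- 0L
    while (cand %in% used) {
      k <- k + 1L
      cand <- pattern_code(paste0(pats[i], "#", k), hash_fun)
    }
    codes[i] <- cand
    used <- c(used, cand)
  }
  counts <- table(nonempty$pattern)
  groups <- data.frame(pattern = pats, group_code = codes,
                       n_proteins = as.integer(counts[pats]),
                       stringsAsFactors = FALSE)
  assignment <- data.frame(
    protein_id = nonempty$protein_id, pattern = nonempty$pattern,
    group_code = codes[match(nonempty$pattern, pats)],
    stringsAsFactors = FALSE)
  list(groups = groups, assignment = assignment)
}

#' Per-domain, per-phylum distribution
#'
#' Counts, for each Pfam domain, the proteins containing it, split by
#' phylum. To avoid a few heavily sequenced phyla dominating, each phylum
#' is first subsampled to at most `max_proteomes_per_phylum` proteomes
#' (deterministic under `seed`), and only the `top_phyla` phyla by total
#' contribution are retained per superkingdom. Both a presence table (a
#' domain counted once per protein) and an occurrence table (counted per
#' copy) are returned.
#'
#' @param hits Overlap-resolved hit table.
#' @param proteins Protein table (`protein_id`, `proteome_id`).
#' @param meta Proteome metadata (`proteome_id`, `phylum`,
#'   `superkingdom`).
#' @param max_proteomes_per_phylum Cap per phylum (default 50).
#' @param top_phyla Phyla retained per superkingdom (default 15).
#' @param seed Integer seed for the subsample.
#' @return A list with `presence` and `occurrence` data.frames
#'   (`superkingdom`, `phylum`, `domain_name`, `pfam_accession`, `n`) and
#'   `proteomes_used`.
#' @export
domain_distribution <- function(hits, proteins, meta,
                                max_proteomes_per_phylum = 50,
                                top_phyla = 15, seed = 1) {
  keep_ids <- unlist(lapply(split(meta$proteome_id, meta$phylum),
                            function(ids) {
    ids <- sort(ids)
    if (length(ids) <= max_proteomes_per_phylum) return(ids)
    withr_seed(seed, sort(sample(ids, max_proteomes_per_phylum)))
  }), use.names = FALSE)
  pidx <- match(hits$protein_id, proteins$protein_id)
  proteome <- proteins$proteome_id[pidx]
  midx <- match(proteome, meta$proteome_id)
  ok <- !is.na(midx) & proteome %in% keep_ids
  h <- hits[ok, , drop = FALSE]
  phylum <- meta$phylum[midx[ok]]
  sk <- meta$superkingdom[midx[ok]]
  acc <- strip_pfam_version(h$pfam_accession)
  tab <- function(dedup) {
    key <- data.frame(superkingdom = sk, phylum = phylum,
                      domain_name = h$domain_name, pfam_accession = acc,
                      protein_id = h$protein_id, stringsAsFactors = FALSE)
    if (dedup) key <- unique(key)
    if (nrow(key) == 0L)
      return(data.frame(superkingdom = character(), phylum = character(),
                        domain_name = character(),
                        pfam_accession = character(), n = integer(),
                        stringsAsFactors = FALSE))
    out <- stats::aggregate(list(n = rep(1L, nrow(key))),
                            by = key[c("superkingdom", "phylum",
                                       "domain_name", "pfam_accession")],
                            FUN = sum)
    # retain top phyla per superkingdom by total contribution
    tot <- stats::aggregate(list(total = out$n),
                            by = out[c("superkingdom", "phylum")], FUN = sum)
    keep_ph <- unlist(lapply(split(tot, tot$superkingdom), function(t2) {
      t2 <- t2[order(-t2$total, t2$phylum), , drop = FALSE]
      paste(t2$superkingdom, t2$phylum, sep = "\t")[seq_len(min(top_phyla, nrow(t2)))]
    }), use.names = FALSE)
    out <- out[paste(out$superkingdom, out$phylum, sep = "\t") %in% keep_ph, ,
               drop = FALSE]
    out <- out[order(out$superkingdom, -out$n, out$pfam_accession,
                     out$phylum), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(presence = tab(dedup = TRUE), occurrence = tab(dedup = FALSE),
       proteomes_used = keep_ids)
}

#' Census of proteins carrying repeat-class Pfam domains
#'
#' Counts proteins with at least one domain whose Pfam type is `Repeat`;
#' a protein counts once however many repeat copies it carries. Every
#' accession occurring in the architectures must be present in the
#' supplied accession-to-type mapping.
#'
#' @param hits Overlap-resolved hit table.
#' @param pfam_types A `data.frame` with `pfam_accession` (version-free)
#'   and `type` (e.g. `"Repeat"`, `"Domain"`, `"Family"`).
#' @return A list with `n_proteins` and `protein_ids`.
#' @export
repeat_census <- function(hits, pfam_types) {
  acc <- strip_pfam_version(hits$pfam_accession)
  unmapped <- setdiff(unique(acc), pfam_types$pfam_accession)
  if (length(unmapped))
    stop("accessions missing from the Pfam type mapping: ",
         paste(sort(unmapped), collapse = ", "))
  type <- pfam_types$type[match(acc, pfam_types$pfam_accession)]
  ids <- sort(unique(hits$protein_id[type == "Repeat"]))
  list(n_proteins = length(ids), protein_ids = ids)
}
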