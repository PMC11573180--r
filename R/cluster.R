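#' Greedy identity/coverage clustering of huge proteins
#'
#' Deterministic greedy set-cover clustering, the in-package equivalent of
#' cascaded sequence clustering at a minimum identity of 0.3 and a
#' bidirectional ("coverage mode 0") alignment coverage of 0.8. Candidates
#' are ordered by length descending, ties broken by protein id ascending.
#' The first unassigned sequence becomes a representative and absorbs every
#' unassigned sequence whose local alignment against it reaches BOTH
#' thresholds: identity >= `min_identity` and coverage >= `min_coverage`
#' for *both* sequences. Singletons are clusters of size one. The result is
#' independent of input order.
#'
#' @param proteins Protein table with `protein_id` and `sequence` columns
#'   (typically the huge-protein subset).
#' @param min_identity Minimum fractional identity (default 0.3).
#' @param min_coverage Minimum bidirectional coverage (default 0.8).
#' @param band Band specification passed to [align_pair()]; `"auto"`
#'   (default) uses the banded dynamic program for speed, `NULL` the full
#'   one.
#' @return A `data.frame` of memberships: `cluster_id` (1-based, in
#'   discovery order), `representative_id`, `member_id`,
#'   `identity_to_rep`, `cov_member`, `cov_rep`. The representative is
#'   listed as its own member with identity and coverages 1.
#' @export
greedy_cluster <- function(proteins, min_identity = 0.3, min_coverage = 0.8,
                           band = "auto") {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  empty <- data.frame(cluster_id = integer(), representative_id = character(),
                      member_id = character(), identity_to_rep = numeric(),
                      cov_member = numeric(), cov_rep = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(proteins) == 0L) return(empty)
  if (anyDuplicated(proteins$protein_id))
    stop("duplicate protein_id in clustering input")
  ord <- order(-nchar(proteins$sequence), proteins$protein_id)
  ids <- proteins$protein_id[ord]
  seqs <- proteins$sequence[ord]
  n <- length(ids)
  assigned <- logical(n)
  rows <- vector("list", n)
  nrow_out <- 0L
  cluster_id <- 0L
  for (i in seq_len(n)) {
    if (assigned[i]) next
    cluster_id <- cluster_id + 1L
    assigned[i] <- TRUE
    nrow_out <- nrow_out + 1L
    rows[[nrow_out]] <- data.frame(
      cluster_id = cluster_id, representative_id = ids[i],
      member_id = ids[i], identity_to_rep = 1, cov_member = 1, cov_rep = 1,
      stringsAsFactors = FALSE)
    for (j in seq_len(n)) {
      if (assigned[j]) next
      al <- align_pair(seqs[j], seqs[i], band = band)
      if (al$identity >= min_identity &&
          al$coverage_query >= min_coverage &&
          al$coverage_target >= min_coverage) {
        assigned[j] <- TRUE
        nrow_out <- nrow_out + 1L
        rows[[nrow_out]] <- data.frame(
          cluster_id = cluster_id, representative_id = ids[i],
          member_id = ids[j], identity_to_rep = al$identity,
          cov_member = al$coverage_query, cov_rep = al$coverage_target,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows[seq_len(nrow_out)])
}

#' Summarize cluster composition by taxonomy and function
#'
#' Produces the per-cluster phylum composition and the per-superkingdom
#' functional-category table (category label, protein count, sorted by
#' count descending within superkingdom), plus flags for clusters spanning
#' more than one superkingdom. Proteins without a functional category are
#' tallied under `"unassigned"` and excluded from the category rows.
#'
#' @param clusters Membership table from [greedy_cluster()].
#' @param proteins Protein table with `protein_id` and `proteome_id`.
#' @param meta Proteome metadata (`proteome_id`, `phylum`, `superkingdom`).
#' @param annotations Optional annotation table with `functional_category`.
#' @return A list with `per_cluster` (cluster_id, representative_id, size,
#'   n_phyla, phyla, superkingdoms, cross_superkingdom), `category_table`
#'   (superkingdom, functional_category, n_proteins, n_in_multi — proteins
#'   in clusters of size >= 2 counted separately from singletons) and
#'   `n_unassigned`.
#' @export
cluster_summary <- function(clusters, proteins, meta, annotations = NULL) {
  idx <- match(clusters$member_id, proteins$protein_id)
  prot_proteome <- proteins$proteome_id[idx]
  midx <- match(prot_proteome, meta$proteome_id)
  phylum <- meta$phylum[midx]
  superkingdom <- meta$superkingdom[midx]
  cat_lab <- rep(NA_character_, nrow(clusters))
  if (!is.null(annotations) && "functional_category" %in% names(annotations)) {
    aidx <- match(clusters$member_id, annotations$protein_id)
    cat_lab <- as.character(annotations$functional_category[aidx])
    cat_lab[!is.na(cat_lab) & !nzchar(cat_lab)] <- NA_character_
  }
  size <- ave(seq_len(nrow(clusters)), clusters$cluster_id, FUN = length)

  per_cluster <- do.call(rbind, lapply(split(seq_len(nrow(clusters)),
                                             clusters$cluster_id), function(ii) {
    ph <- sort(unique(stats::na.omit(phylum[ii])))
    sk <- sort(unique(stats::na.omit(superkingdom[ii])))
    data.frame(cluster_id = clusters$cluster_id[ii][1L],
               representative_id = clusters$representative_id[ii][1L],
               size = length(ii), n_phyla = length(ph),
               phyla = paste(ph, collapse = ";"),
               superkingdoms = paste(sk, collapse = ";"),
               cross_superkingdom = length(sk) > 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(per_cluster) <- NULL
  per_cluster <- per_cluster[order(per_cluster$cluster_id), , drop = FALSE]

  has_cat <- !is.na(cat_lab) & !is.na(superkingdom)
  n_unassigned <- sum(is.na(cat_lab))
  if (any(has_cat)) {
    tab <- stats::aggregate(
      list(n_proteins = rep(1L, sum(has_cat)),
           n_in_multi = as.integer(size[has_cat] >= 2L)),
      by = list(superkingdom = superkingdom[has_cat],
                functional_category = cat_lab[has_cat]),
      FUN = sum)
    tab <- tab[order(tab$superkingdom, -tab$n_proteins,
                     tab$functional_category), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(superkingdom = character(),
                      functional_category = character(),
                      n_proteins = integer(), n_in_multi = integer(),
                      stringsAsFactors = FALSE)
  }
  list(per_cluster = per_cluster, category_table = tab,
       n_unassigned = n_unassigned)
}
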