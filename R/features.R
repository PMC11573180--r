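#' Percentage of disordered residues
#'
#' Fraction of residues whose per-residue disorder score reaches the
#' threshold, times 100. The survey consumes only this percentage; the
#' residue threshold of 0.5 is the usual convention for IUPred-style
#' scores.
#'
#' @param scores Numeric vector of per-residue scores in \[0,1\].
#' @param threshold Residue-level disorder threshold (default 0.5).
#' @return The disorder percentage, in \[0,100\].
#' @export
disorder_percent <- function(scores, threshold = 0.5) {
  if (length(scores) == 0) stop("empty disorder score vector")
  if (any(scores < 0 | scores > 1)) stop("disorder scores must be in [0, 1]")
  100 * sum(scores >= threshold) / length(scores)
}

#' Flag potential annotation artifacts among HPs
#'
#' Four indications that an HP may be a gene-prediction artifact:
#' `no_domain` (empty Pfam architecture), `no_homology_no_cog` (singleton
#' cluster AND no COG category label), `disorder_ge_99` (at least 99%
#' predicted disorder) and `disorder_eq_100` (exactly 100%, which implies
#' `disorder_ge_99`). A flag whose inputs are absent is `NA` (unknown),
#' never silently unset.
#'
#' @param hp_ids Character vector of HP protein ids to flag.
#' @param architectures Architecture table from [deduce_architecture()],
#'   or `NULL`.
#' @param clusters Membership table from [greedy_cluster()], or `NULL`.
#' @param annotations Annotation table (for `functional_category`), or
#'   `NULL`.
#' @param disorder_pct Named numeric vector of disorder percentages (names
#'   are protein ids), or `NULL`.
#' @return A `data.frame` with `protein_id` and the four logical flag
#'   columns.
#' @export
flag_artifacts <- function(hp_ids, architectures = NULL, clusters = NULL,
                           annotations = NULL, disorder_pct = NULL) {
  n <- length(hp_ids)
  no_domain <- rep(NA, n)
  if (!is.null(architectures)) {
    idx <- match(hp_ids, architectures$protein_id)
    no_domain <- !is.na(idx) & !nzchar(architectures$pattern[idx])
    no_domain[is.na(idx)] <- NA
  }
  singleton <- rep(NA, n)
  if (!is.null(clusters)) {
    size <- table(clusters$cluster_id)
    csize <- as.integer(size[match(
      clusters$cluster_id[match(hp_ids, clusters$member_id)], names(size))])
    singleton <- csize == 1L
  }
  has_cog <- rep(NA, n)
  if (!is.null(annotations) && "functional_category" %in% names(annotations)) {
    aidx <- match(hp_ids, annotations$protein_id)
    lab <- as.character(annotations$functional_category[aidx])
    has_cog <- !is.na(lab) & nzchar(lab)
    has_cog[is.na(aidx)] <- NA
  }
  no_homology_no_cog <- singleton & !has_cog
  dpct <- rep(NA_real_, n)
  if (!is.null(disorder_pct))
    dpct <- unname(disorder_pct[match(hp_ids, names(disorder_pct))])
  data.frame(protein_id = hp_ids,
             no_domain = no_domain,
             no_homology_no_cog = no_homology_no_cog,
             disorder_ge_99 = dpct >= 99,
             disorder_eq_100 = dpct == 100,
             stringsAsFactors = FALSE)
}

#' Roll protein GO annotations up the ontology
#'
#' Propagates each protein's GO terms to all `is_a` ancestors within one
#' namespace and counts, per term (and per superkingdom when metadata is
#' supplied), the number of distinct proteins carrying the term — a
#' protein counts once per term regardless of how many of its leaf terms
#' reach it. The report can be restricted to a slim term list or to the
#' `top_n` terms by count. Terms absent from the ontology are skipped
#' with a warning. Propagation is idempotent: rolling up an
#' already-propagated set changes nothing.
#'
#' @param annotations Annotation table with `protein_id` and `go_terms`
#'   (semicolon-separated ids).
#' @param ontology A `go_ontology` from [read_obo()].
#' @param namespace One of `molecular_function`, `biological_process`,
#'   `cellular_component`.
#' @param proteins,meta Optional protein table and metadata for the
#'   per-superkingdom split.
#' @param slim Optional character vector restricting the reported terms.
#' @param top_n Terms reported per superkingdom when `slim` is `NULL`
#'   (default 20).
#' @return A `data.frame` with `superkingdom` (or `"all"`), `term`,
#'   `name`, `n_proteins`, sorted by count descending.
#' @export
go_rollup <- function(annotations, ontology, namespace,
                      proteins = NULL, meta = NULL, slim = NULL,
                      top_n = 20) {
  stopifnot(inherits(ontology, "go_ontology"),
            namespace %in% c("molecular_function", "biological_process",
                             "cellular_component"))
  ns_terms <- ontology$terms$id[ontology$terms$namespace == namespace]
  sk <- rep("all", nrow(annotations))
  if (!is.null(proteins) && !is.null(meta)) {
    pidx <- match(annotations$protein_id, proteins$protein_id)
    midx <- match(proteins$proteome_id[pidx], meta$proteome_id)
    sk <- meta$superkingdom[midx]
    sk[is.na(sk)] <- "all"
  }
  anc_cache <- new.env(parent = emptyenv())
  warned <- character(0)
  rows <- list()
  for (i in seq_len(nrow(annotations))) {
    gt <- annotations$go_terms[i]
    if (is.na(gt) || !nzchar(gt)) next
    terms <- strsplit(gt, ";", fixed = TRUE)[[1L]]
    terms <- trimws(terms)
    unknown <- setdiff(terms, ontology$terms$id)
    warned <- union(warned, unknown)
    terms <- setdiff(terms, unknown)
    anc <- unique(unlist(lapply(terms, function(t) {
      if (!exists(t, envir = anc_cache, inherits = FALSE))
        assign(t, go_ancestors(ontology, t)[[1L]], envir = anc_cache)
      get(t, envir = anc_cache, inherits = FALSE)
    })))
    anc <- intersect(anc, ns_terms)
    if (length(anc))
      rows[[length(rows) + 1L]] <- data.frame(
        superkingdom = sk[i], term = anc,
        protein_id = annotations$protein_id[i], stringsAsFactors = FALSE)
  }
  if (length(warned))
    warning(length(warned), " GO term(s) absent from the ontology skipped: ",
            paste(utils::head(sort(warned), 5), collapse = ", "))
  if (!length(rows))
    return(data.frame(superkingdom = character(), term = character(),
                      name = character(), n_proteins = integer(),
                      stringsAsFactors = FALSE))
  long <- unique(do.call(rbind, rows))
  out <- stats::aggregate(list(n_proteins = rep(1L, nrow(long))),
                          by = long[c("superkingdom", "term")], FUN = sum)
  out$name <- ontology$terms$name[match(out$term, ontology$terms$id)]
  if (!is.null(slim)) {
    out <- out[out$term %in% slim, , drop = FALSE]
  } else {
    out <- do.call(rbind, lapply(split(out, out$superkingdom), function(o) {
      o <- o[order(-o$n_proteins, o$term), , drop = FALSE]
      utils::head(o, top_n)
    }))
  }
  out <- out[order(out$superkingdom, -out$n_proteins, out$term),
             c("superkingdom", "term", "name", "n_proteins")]
  rownames(out) <- NULL
  out
}

#' Feature-versus-length profile for HPs and a matched non-HP sample
#'
#' Joins disorder percentage, signal-peptide presence and TMH count to
#' protein length for the HP cohort and for an equally sized non-HP cohort
#' sampled without replacement under a seed. Binning is left to the
#' report.
#'
#' @param proteins Protein table.
#' @param annotations Annotation table.
#' @param hps An `hp_set`.
#' @param seed Integer seed for the non-HP sample.
#' @param disorder_threshold Residue threshold passed to
#'   [disorder_percent()].
#' @return A `data.frame` with `protein_id`, `cohort` (`"HP"`/`"non-HP"`),
#'   `length`, `disorder_pct`, `has_signal_peptide`, `n_tmh`.
#' @export
feature_length_profile <- function(proteins, annotations, hps, seed = 1,
                                   disorder_threshold = 0.5) {
  stopifnot(inherits(hps, "hp_set"))
  hp_ids <- hps$hp$protein_id
  nonhp_ids <- setdiff(proteins$protein_id, hp_ids)
  if (length(hp_ids) > length(nonhp_ids))
    stop("non-HP population smaller than the HP cohort")
  smp <- withr_seed(seed, sample(sort(nonhp_ids), length(hp_ids)))
  ids <- c(hp_ids, smp)
  cohort <- rep(c("HP", "non-HP"), c(length(hp_ids), length(smp)))
  pidx <- match(ids, proteins$protein_id)
  aidx <- match(ids, annotations$protein_id)
  dpct <- vapply(seq_along(ids), function(i) {
    if (is.na(aidx[i])) return(NA_real_)
    ds <- annotations$disorder_scores[[aidx[i]]]
    if (is.null(ds) || length(ds) == 0) NA_real_
    else disorder_percent(ds, disorder_threshold)
  }, numeric(1))
  data.frame(protein_id = ids, cohort = cohort,
             length = proteins$length[pidx],
             disorder_pct = dpct,
             has_signal_peptide = annotations$has_signal_peptide[aidx],
             n_tmh = annotations$n_tmh[aidx],
             stringsAsFactors = FALSE)
}
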