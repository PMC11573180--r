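#' Read the proteome metadata table
#'
#' Tab-separated with a mandatory header. Required columns: `proteome_id`,
#' `taxid`, `superkingdom`, `phylum`, `proteome_size`, `assembly_level`,
#' `busco_completeness`, `is_plasmid`. Superkingdom must be one of
#' `archaea`, `bacteria`, `eukaryota` — viral (or any other) entries are
#' rejected, as the survey excludes them. Missing BUSCO completeness is
#' kept as `NA`, never imputed.
#'
#' @param path Path to a metadata TSV.
#' @return A `data.frame` of per-proteome metadata.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("proteome_id", "taxid", "superkingdom", "phylum", "proteome_size",
           "assembly_level", "busco_completeness", "is_plasmid")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(meta$proteome_id))
    stop("duplicate proteome_id in metadata: ",
         meta$proteome_id[duplicated(meta$proteome_id)][1L])
  bad <- !meta$superkingdom %in% c("archaea", "bacteria", "eukaryota")
  if (any(bad))
    stop("unknown superkingdom (viral and other entries are excluded): ",
         meta$superkingdom[which(bad)[1L]])
  if (any(meta$proteome_size < 1))
    stop("proteome_size must be >= 1")
  bc <- meta$busco_completeness
  if (any(!is.na(bc) & (bc < 0 | bc > 100)))
    stop("busco_completeness must be in [0, 100]")
  meta$is_plasmid <- as.logical(meta$is_plasmid)
  meta
}

#' Read the per-protein annotation table
#'
#' Package-defined TSV schema with one row per protein. Columns (all
#' optional except `protein_id`): `existence_level` (1-4; level 5
#' "Uncertain" rows are dropped with a warning), `has_signal_peptide`,
#' `n_tmh`, `go_terms` (semicolon-separated GO ids), `functional_category`
#' (one- or two-letter COG class), `disorder_scores` (comma-packed
#' per-residue scores in \[0,1\]). Absent values stay `NA` — nothing is
#' imputed.
#'
#' @param path Path to an annotation TSV.
#' @param proteins Optional protein table; when given, disorder vector
#'   lengths are validated against protein lengths and annotations for
#'   unknown proteins raise a warning (the rows are kept for later joins).
#' @return A `data.frame` with a list column `disorder_scores`.
#' @export
read_annotations <- function(path, proteins = NULL) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(ann)) stop("annotations missing protein_id")
  ann$protein_id <- as.character(ann$protein_id)
  if ("disorder_scores" %in% names(ann))
    ann$disorder_scores <- as.character(ann$disorder_scores)
  if ("existence_level" %in% names(ann)) {
    lvl5 <- !is.na(ann$existence_level) & ann$existence_level == 5L
    if (any(lvl5)) {
      warning(sum(lvl5), " protein(s) with existence level 5 (Uncertain) dropped")
      ann <- ann[!lvl5, , drop = FALSE]
    }
    bad <- !is.na(ann$existence_level) & !ann$existence_level %in% 1:4
    if (any(bad)) stop("existence_level outside 1-4")
  }
  if ("disorder_scores" %in% names(ann)) {
    ann$disorder_scores <- lapply(ann$disorder_scores, function(x) {
      if (is.na(x) || !nzchar(x)) return(NULL)
      v <- as.numeric(strsplit(x, ",", fixed = TRUE)[[1L]])
      if (anyNA(v) || any(v < 0 | v > 1))
        stop("disorder scores must be numeric in [0, 1]")
      v
    })
  }
  if ("has_signal_peptide" %in% names(ann))
    ann$has_signal_peptide <- as.logical(ann$has_signal_peptide)
  if (!is.null(proteins)) {
    unknown <- !ann$protein_id %in% proteins$protein_id
    if (any(unknown))
      warning(sum(unknown), " annotation(s) for unknown protein_id kept for later join")
    if ("disorder_scores" %in% names(ann)) {
      idx <- match(ann$protein_id, proteins$protein_id)
      for (i in seq_len(nrow(ann))) {
        ds <- ann$disorder_scores[[i]]
        if (!is.null(ds) && !is.na(idx[i]) &&
            length(ds) != proteins$length[idx[i]])
          stop("disorder vector length (", length(ds),
               ") does not match protein length (",
               proteins$length[idx[i]], ") for ", ann$protein_id[i])
      }
    }
  }
  ann
}

#' Attach existence levels from an annotation table to a protein table
#'
#' @param proteins Protein table from [read_fasta()].
#' @param annotations Annotation table from [read_annotations()].
#' @return `proteins` with an `existence_level` column joined on
#'   `protein_id`.
#' @export
attach_existence <- function(proteins, annotations) {
  idx <- match(proteins$protein_id, annotations$protein_id)
  proteins$existence_level <-
    if ("existence_level" %in% names(annotations))
      annotations$existence_level[idx] else NA_integer_
  proteins
}

#' @rdname read_metadata
#' @param meta A metadata `data.frame` to serialize.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_annotations
#' @param ann An annotation `data.frame` (list-column `disorder_scores`
#'   is comma-packed on write).
#' @export
write_annotations <- function(ann, path) {
  out <- ann
  if (is.list(out$disorder_scores))
    out$disorder_scores <- vapply(out$disorder_scores, function(v) {
      if (is.null(v)) "" else paste(format(v, trim = TRUE), collapse = ",")
    }, character(1))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
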