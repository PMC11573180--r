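#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly multi-line) amino-acid FASTA file into a protein
#' table. Headers may be either `proteome_id|protein_id` or a plain
#' `protein_id`; in the latter case `proteome_id` is `NA` and can be joined
#' on later from a mapping table. Sequences are upper-cased and a single
#' terminal `*` stop symbol is stripped. Records with an empty sequence are
#' dropped with a warning.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return A `data.frame` with columns `protein_id`, `proteome_id`,
#'   `sequence` and `length`, in file order. `length` always equals
#'   `nchar(sequence)`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  if (is.null(headers) || anyNA(headers) || any(headers == ""))
    stop("malformed FASTA header in ", path)
  # header token before first whitespace is the id field
  ids <- sub("\\s.*$", "", headers)
  has_pipe <- grepl("|", ids, fixed = TRUE)
  bad <- has_pipe & !grepl("^[^|]+\\|[^|]+$", ids)
  if (any(bad))
    stop("malformed FASTA header (expected 'proteome_id|protein_id'): ",
         ids[which(bad)[1L]])
  proteome_id <- ifelse(has_pipe, sub("\\|.*$", "", ids), NA_character_)
  protein_id <- ifelse(has_pipe, sub("^[^|]*\\|", "", ids), ids)
  sequence <- toupper(as.character(seqs))
  sequence <- sub("\\*$", "", sequence)
  empty <- !nzchar(sequence)
  if (any(empty)) {
    warning(sum(empty), " empty-sequence record(s) dropped from ", path)
    protein_id <- protein_id[!empty]
    proteome_id <- proteome_id[!empty]
    sequence <- sequence[!empty]
  }
  data.frame(protein_id = protein_id, proteome_id = proteome_id,
             sequence = sequence, length = nchar(sequence),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a protein table to FASTA
#'
#' Inverse of [read_fasta()]: emits `>proteome_id|protein_id` headers (or
#' plain `>protein_id` when `proteome_id` is `NA`), wrapping sequence lines
#' at `wrap` characters, UTF-8 with LF line endings.
#'
#' @param proteins A protein table with `protein_id`, `sequence` and
#'   optionally `proteome_id` columns.
#' @param path Output path.
#' @param wrap Line width for sequence wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, wrap = 60) {
  stopifnot(wrap >= 1)
  pid <- proteins$protein_id
  hdr <- if ("proteome_id" %in% names(proteins)) {
    ifelse(is.na(proteins$proteome_id), pid,
           paste0(proteins$proteome_id, "|", pid))
  } else pid
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(pid)) {
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = wrap)
    lines <- substring(s, starts, pmin(starts + wrap - 1L, nchar(s)))
    writeLines(c(paste0(">", hdr[i]), lines), con, sep = "\n")
  }
  invisible(path)
}

#' Read HMMER3 per-domain hits (domtblout)
#'
#' Parses the `--domtblout` tabular output of `hmmscan` (target = Pfam
#' model, query = protein). Comment lines starting with `#` are skipped.
#' Column mapping: 1 target name, 2 target accession, 4 query name,
#' 7 full-sequence E-value, 13 domain i-Evalue, 14 domain bit score,
#' 20/21 envelope from/to (1-based inclusive). Any HMMER3.x layout with at
#' least 23 whitespace-separated columns is accepted.
#'
#' @param path Path to a domtblout file.
#' @return A `data.frame` with columns `domain_name`, `pfam_accession`,
#'   `protein_id`, `seq_evalue`, `dom_ievalue`, `bitscore`, `env_from`,
#'   `env_to`.
#' @export
read_domtblout <- function(path) {
  if (!file.exists(path)) stop("domtblout file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(domain_name = character(), pfam_accession = character(),
                      protein_id = character(), seq_evalue = numeric(),
                      dom_ievalue = numeric(), bitscore = numeric(),
                      env_from = integer(), env_to = integer(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 23L))
    stop("domtblout line ", lineno[which(nf < 23L)[1L]],
         ": fewer than 23 columns")
  grab <- function(k) vapply(fields, `[[`, character(1), k)
  num <- function(k, what) {
    v <- suppressWarnings(as.numeric(grab(k)))
    if (anyNA(v))
      stop("domtblout line ", lineno[which(is.na(v))[1L]],
           ": non-numeric ", what)
    v
  }
  data.frame(domain_name = grab(1), pfam_accession = grab(2),
             protein_id = grab(4),
             seq_evalue = num(7, "sequence E-value"),
             dom_ievalue = num(13, "domain i-Evalue"),
             bitscore = num(14, "bit score"),
             env_from = as.integer(num(20, "envelope start")),
             env_to = as.integer(num(21, "envelope end")),
             stringsAsFactors = FALSE)
}
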