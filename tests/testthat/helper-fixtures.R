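# Small programmatic fixtures shared across test files.

make_meta <- function(phylum, size, superkingdom = "bacteria",
                      plasmid = FALSE, busco = NA_real_,
                      assembly = "Chromosome") {
  n <- max(length(phylum), length(size))
  data.frame(proteome_id = sprintf("UP%04d", seq_len(n)),
             taxid = seq_len(n), superkingdom = rep_len(superkingdom, n),
             phylum = rep_len(phylum, n), proteome_size = rep_len(size, n),
             assembly_level = rep_len(assembly, n),
             busco_completeness = rep_len(busco, n),
             is_plasmid = rep_len(plasmid, n), stringsAsFactors = FALSE)
}

make_proteins <- function(lengths, proteome_id = "UP0001",
                          prefix = "P") {
  n <- length(lengths)
  data.frame(protein_id = sprintf("%s%03d", prefix, seq_len(n)),
             proteome_id = rep_len(proteome_id, n),
             length = lengths, stringsAsFactors = FALSE)
}

write_tmp_obo <- function(lines) {
  path <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", lines), path)
  path
}

tiny_obo <- function() {
  write_tmp_obo(c(
    "[Term]", "id: GO:0000001", "name: root process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: child process",
    "namespace: biological_process", "is_a: GO:0000001 ! root process", "",
    "[Term]", "id: GO:0000003", "name: leaf process",
    "namespace: biological_process", "is_a: GO:0000002 ! child process", "",
    "[Term]", "id: GO:0000004", "name: old process",
    "namespace: biological_process", "is_a: GO:0000001",
    "is_obsolete: true", "",
    "[Term]", "id: GO:0000010", "name: root function",
    "namespace: molecular_function"))
}

make_hits <- function(protein_id, accession, from, to,
                      seq_e = 1e-6, dom_e = 1e-6, score = 100,
                      name = sub("\\.\\d+$", "", accession)) {
  n <- max(length(protein_id), length(accession), length(from))
  data.frame(domain_name = rep_len(name, n),
             pfam_accession = rep_len(accession, n),
             protein_id = rep_len(protein_id, n),
             seq_evalue = rep_len(seq_e, n),
             dom_ievalue = rep_len(dom_e, n),
             bitscore = rep_len(score, n),
             env_from = as.integer(rep_len(from, n)),
             env_to = as.integer(rep_len(to, n)), stringsAsFactors = FALSE)
}
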