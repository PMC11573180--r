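#' Build a pipeline run configuration
#'
#' Collects input paths and stage parameters for [run_pipeline()]. Every
#' threshold is validated here, before any stage runs, and the resolved
#' configuration is serialized next to the outputs so a run is
#' reproducible from its own directory.
#'
#' @param fasta,metadata,annotations Paths to the protein FASTA, proteome
#'   metadata TSV and annotation TSV.
#' @param domtblout Optional path to an hmmscan domtblout file; `NULL`
#'   disables the architecture stage.
#' @param obo Optional path to a GO OBO file; `NULL` disables the GO
#'   roll-up.
#' @param min_length HP length threshold (default 5000).
#' @param min_identity,min_coverage Clustering thresholds (defaults 0.3,
#'   0.8).
#' @param seq_e,dom_e Pfam E-value thresholds (defaults 0.001).
#' @param resample_reps Replicate counts for the existence resampling
#'   (default `c(5, 10, 100)`).
#' @param seed Root seed; every random stage derives its stream from it.
#' @return A `run_config` list.
#' @export
run_config <- function(fasta, metadata, annotations, domtblout = NULL,
                       obo = NULL, min_length = 5000, min_identity = 0.3,
                       min_coverage = 0.8, seq_e = 0.001, dom_e = 0.001,
                       resample_reps = c(5, 10, 100), seed = 1) {
  stopifnot(min_length >= 1, min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1, seq_e > 0, dom_e > 0,
            all(resample_reps >= 1))
  for (p in c(fasta, metadata, annotations, domtblout, obo))
    if (!file.exists(p)) stop("input not found: ", p)
  structure(list(fasta = fasta, metadata = metadata,
                 annotations = annotations, domtblout = domtblout,
                 obo = obo, min_length = min_length,
                 min_identity = min_identity, min_coverage = min_coverage,
                 seq_e = seq_e, dom_e = dom_e,
                 resample_reps = resample_reps, seed = seed),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

#' Run the full HP survey pipeline
#'
#' Executes the stages in dependency order — ingest, HP extraction,
#' proteome filtering, prevalence, existence statistics, clustering,
#' architectures (when a domtblout is configured), features/artifacts —
#' and writes one TSV per stage plus a JSON manifest (config hash, seed,
#' row counts) into `out_dir`. Re-running with the same config and inputs
#' is byte-identical.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "ingest"
  res <- tryCatch({
    proteins <- read_fasta(config$fasta)
    meta <- read_metadata(config$metadata)
    ann <- read_annotations(config$annotations, proteins)
    proteins <- attach_existence(proteins, ann)

    stage <- "extract"
    hps <- extract_hps(proteins, config$min_length)

    stage <- "prevalence"
    filt <- filter_proteomes(meta)
    lik <- phylum_likelihood(hps, filt$kept)
    write_tsv(filt$removed, file.path(out_dir, "removal_log.tsv"))
    write_tsv(lik$per_proteome, file.path(out_dir, "prevalence_per_proteome.tsv"))
    write_tsv(lik$per_phylum, file.path(out_dir, "prevalence_per_phylum.tsv"))
    write_tsv(proteome_size_vs_hp_table(hps, filt$kept),
              file.path(out_dir, "size_vs_hp.tsv"))

    stage <- "existence"
    prop <- existence_proportions(proteins, hps$hp$protein_id)
    lv <- proteins$existence_level
    is_hp <- proteins$protein_id %in% hps$hp$protein_id
    resamp <- do.call(rbind, lapply(config$resample_reps, function(nr) {
      r <- resample_nonhp(lv[!is_hp], min(sum(is_hp), sum(!is_hp)), nr,
                          config$seed + 11)
      r$n_reps <- nr
      r
    }))
    cmp <- compare_distributions(lv[is_hp], lv[!is_hp])
    write_tsv(data.frame(level = 1:4, hp_count = prop$hp_counts,
                         nonhp_count = prop$nonhp_counts,
                         hp_pct = prop$hp_pct, nonhp_pct = prop$nonhp_pct),
              file.path(out_dir, "existence_proportions.tsv"))
    write_tsv(resamp, file.path(out_dir, "existence_resampling.tsv"))
    write_tsv(data.frame(statistic = c("kruskal_h", "kruskal_p", "anova_f",
                                       "anova_p"),
                         value = unlist(cmp, use.names = FALSE)),
              file.path(out_dir, "existence_tests.tsv"))
    write_tsv(quality_correlations(filt$kept, hps),
              file.path(out_dir, "quality_correlations.tsv"))
    write_tsv(assembly_level_summary(filt$kept, hps),
              file.path(out_dir, "assembly_levels.tsv"))

    stage <- "cluster"
    hp_prot <- proteins[proteins$protein_id %in% hps$hp$protein_id, ,
                        drop = FALSE]
    clusters <- greedy_cluster(hp_prot, config$min_identity,
                               config$min_coverage)
    csum <- cluster_summary(clusters, proteins, meta, ann)
    write_tsv(clusters, file.path(out_dir, "clusters.tsv"))
    write_tsv(csum$per_cluster, file.path(out_dir, "cluster_composition.tsv"))
    write_tsv(csum$category_table, file.path(out_dir, "cluster_categories.tsv"))

    arch <- NULL
    if (!is.null(config$domtblout)) {
      stage <- "architect"
      hits <- read_domtblout(config$domtblout)
      hits <- filter_hits(hits, config$seq_e, config$dom_e)
      hits <- resolve_overlaps(hits)
      arch <- deduce_architecture(hits, hps$hp$protein_id)
      grp <- group_architectures(arch)
      dist <- domain_distribution(hits, proteins, meta,
                                  seed = config$seed + 21)
      write_tsv(arch, file.path(out_dir, "architectures.tsv"))
      write_tsv(grp$groups, file.path(out_dir, "architecture_groups.tsv"))
      write_tsv(dist$presence, file.path(out_dir, "domain_presence.tsv"))
      write_tsv(dist$occurrence, file.path(out_dir, "domain_occurrence.tsv"))
    }

    stage <- "features"
    dp <- vapply(hps$hp$protein_id, function(id) {
      i <- match(id, ann$protein_id)
      ds <- if (is.na(i)) NULL else ann$disorder_scores[[i]]
      if (is.null(ds) || length(ds) == 0) NA_real_ else disorder_percent(ds)
    }, numeric(1))
    flags <- flag_artifacts(hps$hp$protein_id, arch, clusters, ann, dp)
    write_tsv(flags, file.path(out_dir, "artifact_flags.tsv"))
    profile <- feature_length_profile(proteins, ann, hps,
                                      seed = config$seed + 31)
    write_tsv(profile, file.path(out_dir, "feature_length_profile.tsv"))
    if (!is.null(config$obo)) {
      ont <- read_obo(config$obo)
      hp_ann <- ann[ann$protein_id %in% hps$hp$protein_id, , drop = FALSE]
      for (ns in c("molecular_function", "biological_process",
                   "cellular_component")) {
        ro <- go_rollup(hp_ann, ont, ns, proteins, meta)
        write_tsv(ro, file.path(out_dir, paste0("go_", ns, ".tsv")))
      }
    }

    list(proteins = proteins, meta = meta, hps = hps, filt = filt,
         clusters = clusters, arch = arch)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  cfg_ser <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              null = "null")
  manifest <- list(
    config = unclass(config),
    config_hash = as.character(.fnv1a64_cpp(as.character(cfg_ser))),
    seed = config$seed,
    n_proteins = nrow(res$proteins),
    n_proteomes = nrow(res$meta),
    n_proteomes_kept = nrow(res$filt$kept),
    n_hps = nrow(res$hps$hp),
    n_clusters = length(unique(res$clusters$cluster_id)),
    n_architectures = if (is.null(res$arch)) 0L
      else sum(nzchar(res$arch$pattern)))
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                           null = "null", digits = NA)
  writeLines(json, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Render summary tables from a completed run directory
#'
#' Re-reads the stage TSVs of a [run_pipeline()] directory and assembles
#' the survey's summary tables: the per-phylum likelihood table (sorted by
#' superkingdom then median likelihood), the existence-level proportion
#' table, the functional-category table and, when present, the
#' architecture group table. Deterministic and idempotent; an empty
#' clustering stage yields an empty (but present) category table.
#'
#' @param run_dir A directory written by [run_pipeline()].
#' @return A named list of data.frames.
#' @export
render_report <- function(run_dir) {
  rd <- function(f) {
    p <- file.path(run_dir, f)
    if (!file.exists(p)) return(NULL)
    utils::read.delim(p, stringsAsFactors = FALSE)
  }
  list(likelihood = rd("prevalence_per_phylum.tsv"),
       existence = rd("existence_proportions.tsv"),
       existence_tests = rd("existence_tests.tsv"),
       categories = rd("cluster_categories.tsv"),
       architecture_groups = rd("architecture_groups.tsv"),
       assembly_levels = rd("assembly_levels.tsv"))
}
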