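AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K",
          "M","F","P","S","T","W","Y","V")

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# sample() without the length-1 surprise
resample <- function(x, n, replace = TRUE) {
  x[sample.int(length(x), n, replace = replace)]
}

#' Configuration for the synthetic proteome generator
#'
#' Defaults describe a desk-scale collection with the statistical structure
#' the survey assumes: bulk protein lengths log-normal (ln-scale mu 5.8,
#' sigma 0.9, capped at 4999 so that the planted set is exactly the ground
#' truth), per-proteome HP counts Poisson with mean
#' `hp_rate * proteome_size / 1000`, and per-phylum HP rates spanning the
#' reported range — around 4 per 1000 for HP-rich eukaryotic phyla such as
#' Apicomplexa down to well under 1 per 1000 for typical bacteria.
#' Existence levels for HPs default to the reported survey proportions
#' (0.8% protein level, 0.06% transcript level, ~22% inferred from
#' homology, ~77% predicted).
#'
#' @param phyla `data.frame` with `superkingdom`, `phylum`, `n_proteomes`,
#'   `hp_rate` (expected HPs per 1000 proteins).
#' @param proteome_size_range Integer interval for bulk proteome sizes.
#' @param length_lognormal_mu,length_lognormal_sigma Bulk length
#'   distribution on the natural-log scale.
#' @param n_hp_families,family_size Number K of planted homologous HP
#'   families and members m per family (0 disables planting).
#' @param within_family_target_identity Expected pairwise identity between
#'   family members, in (0, 1].
#' @param hp_length_range HP length interval; lower bound must be >= 5000.
#' @param architecture_library List of ordered Pfam accession vectors
#'   planted on HPs (recycled over the HP set).
#' @param existence_probs_hp,existence_probs_nonhp Probabilities over
#'   existence levels 1-4.
#' @param p_signal_peptide,tmh_lambda,disorder_beta Annotation
#'   distributions: signal-peptide probability, Poisson mean for TMH
#'   counts, Beta shape pair for per-protein disorder fractions.
#' @param n_disorder_99,n_disorder_100 Number of HPs planted with >= 99%
#'   and exactly 100% disorder (artifact ground truth).
#' @param category_probs Named probabilities over COG category labels
#'   assigned to HPs (`NA_character_` names allowed for unassigned).
#' @param seed Global integer seed; every stage derives its substream from
#'   it by a fixed offset.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(
    phyla = data.frame(
      superkingdom = c("eukaryota", "eukaryota", "bacteria", "bacteria",
                       "archaea"),
      phylum = c("Apicomplexa", "Chordata", "Planctomycetota",
                 "Proteobacteria", "Euryarchaeota"),
      n_proteomes = c(6, 6, 6, 6, 5),
      hp_rate = c(4.0, 0.4, 0.8, 0.1, 0.05),
      stringsAsFactors = FALSE),
    proteome_size_range = c(800, 1200),
    length_lognormal_mu = 5.8,
    length_lognormal_sigma = 0.9,
    n_hp_families = 0,
    family_size = 6,
    within_family_target_identity = 0.6,
    hp_length_range = c(5000, 6000),
    architecture_library = list(
      c("PF00501.30", "PF00550.28", "PF00668.23"),              # NRPS-like
      c("PF00109.29", "PF02801.25", "PF00550.28"),              # PKS-like
      c("PF00435.24", "PF00435.24", "PF00435.24", "PF00307.34"),# repeat block
      c("PF00632.28")),                                         # single HECT
    existence_probs_hp = c(0.008, 0.0006, 0.22, 0.7714),
    existence_probs_nonhp = c(0.003, 0.01, 0.27, 0.717),
    p_signal_peptide = 0.1,
    tmh_lambda = 0.5,
    disorder_beta = c(2, 6),
    n_disorder_99 = 0,
    n_disorder_100 = 0,
    category_probs = c(Q = 0.5, M = 0.3, S = 0.2),
    seed = 1) {
  cfg <- list(phyla = phyla, proteome_size_range = proteome_size_range,
              length_lognormal_mu = length_lognormal_mu,
              length_lognormal_sigma = length_lognormal_sigma,
              n_hp_families = n_hp_families, family_size = family_size,
              within_family_target_identity = within_family_target_identity,
              hp_length_range = hp_length_range,
              architecture_library = architecture_library,
              existence_probs_hp = existence_probs_hp,
              existence_probs_nonhp = existence_probs_nonhp,
              p_signal_peptide = p_signal_peptide, tmh_lambda = tmh_lambda,
              disorder_beta = disorder_beta,
              n_disorder_99 = n_disorder_99, n_disorder_100 = n_disorder_100,
              category_probs = category_probs, seed = seed)
  if (cfg$hp_length_range[1] < 5000)
    stop("hp_length_range lower bound must be >= 5000")
  if (any(cfg$phyla$hp_rate < 0)) stop("hp_rate must be >= 0")
  if (cfg$n_hp_families > 0 &&
      (cfg$within_family_target_identity <= 0 ||
       cfg$within_family_target_identity > 1))
    stop("within_family_target_identity must be in (0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

# substitution probability giving expected pairwise identity t between two
# descendants of a common ancestor under i.i.d. substitution to a uniform
# choice among the 19 alternatives: identity(p) = (1-p)^2 + p^2/19
family_substitution_prob <- function(target_identity) {
  a <- 20 / 19; b <- -2; c0 <- 1 - target_identity
  p <- (-b - sqrt(b^2 - 4 * a * c0)) / (2 * a)
  min(max(p, 0), 1)
}

#' Simulate one homologous HP family
#'
#' Draws a random ancestor and derives `m` members by independent per-site
#' substitution with the probability that makes the expected pairwise
#' identity between members approximately `target_identity` (closed form
#' `(1-p)^2 + p^2/19`). No indels, so bidirectional coverage between
#' members is 100% by construction.
#'
#' @param ancestor_length Length of the common ancestor (>= 5000 for HP
#'   families).
#' @param m Number of members (>= 2).
#' @param target_identity Expected pairwise identity in (0, 1].
#' @param seed Integer seed.
#' @return Character vector of `m` sequences.
#' @export
simulate_hp_family <- function(ancestor_length, m, target_identity, seed) {
  stopifnot(m >= 2, target_identity > 0, target_identity <= 1)
  p <- family_substitution_prob(target_identity)
  withr_seed(seed, {
    anc <- sample(AA20, ancestor_length, replace = TRUE)
    vapply(seq_len(m), function(i) {
      mut <- stats::runif(ancestor_length) < p
      s <- anc
      if (any(mut)) {
        # uniform over the 19 alternatives: shift by 1..19 in the alphabet
        shift <- sample.int(19L, sum(mut), replace = TRUE)
        s[mut] <- AA20[(match(anc[mut], AA20) - 1L + shift) %% 20L + 1L]
      }
      paste(s, collapse = "")
    }, character(1))
  })
}

#' Simulate a proteome collection with ground truth
#'
#' Generates proteomes per phylum with log-normal bulk lengths (capped at
#' 4999), Poisson-planted HP singletons, optional planted homologous HP
#' families, per-protein annotations (existence level, signal peptide,
#' TMH count, disorder scores for HPs, COG category for HPs) and planted
#' Pfam architectures drawn from the architecture library. Fully
#' deterministic for a fixed config.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return A list with `proteins` (protein table incl. `sequence`), `meta`
#'   (proteome metadata), `annotations` (annotation table) and
#'   `ground_truth`: `hp_ids`, `families` (named list of member id sets),
#'   `architectures` (named list hp_id -> accession vector),
#'   `disorder_99_ids`, `disorder_100_ids`, `category` (named vector).
#' @export
simulate_proteomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  ph <- config$phyla
  # stage 1: proteome skeletons and bulk lengths
  proteomes <- list(); prot <- list()
  withr_seed(seed + 101, {
    k <- 0L
    for (r in seq_len(nrow(ph))) {
      for (q in seq_len(ph$n_proteomes[r])) {
        k <- k + 1L
        pid <- sprintf("UP%04d", k)
        size <- resample(seq(config$proteome_size_range[1],
                             config$proteome_size_range[2]), 1)
        lens <- pmin(round(stats::rlnorm(size, config$length_lognormal_mu,
                                         config$length_lognormal_sigma)), 4999)
        lens <- pmax(lens, 30)
        n_hp <- stats::rpois(1, ph$hp_rate[r] * size / 1000)
        n_hp <- min(n_hp, size)
        if (n_hp > 0)
          lens[seq_len(n_hp)] <- resample(
            seq(config$hp_length_range[1], config$hp_length_range[2]), n_hp)
        proteomes[[k]] <- data.frame(
          proteome_id = pid, taxid = 100000L + k,
          superkingdom = ph$superkingdom[r], phylum = ph$phylum[r],
          assembly_level = sample(c("Chromosome", "Unassembled WGS",
                                    "Unplaced"), 1,
                                  prob = c(0.3, 0.5, 0.2)),
          busco_completeness = round(stats::runif(1, 70, 100), 1),
          is_plasmid = FALSE, stringsAsFactors = FALSE)
        prot[[k]] <- data.frame(
          protein_id = sprintf("%s_%05d", pid, seq_along(lens)),
          proteome_id = pid, length = lens, stringsAsFactors = FALSE)
      }
    }
  })
  meta <- do.call(rbind, proteomes)
  proteins <- do.call(rbind, prot)

  # stage 2: planted families appended to randomly chosen proteomes
  families <- list()
  if (config$n_hp_families > 0) {
    fam_lens <- withr_seed(seed + 202, resample(
      seq(config$hp_length_range[1], config$hp_length_range[2]),
      config$n_hp_families))
    home <- withr_seed(seed + 203, matrix(
      sample(meta$proteome_id, config$n_hp_families * config$family_size,
             replace = TRUE),
      nrow = config$n_hp_families))
    for (f in seq_len(config$n_hp_families)) {
      seqs <- simulate_hp_family(fam_lens[f], config$family_size,
                                 config$within_family_target_identity,
                                 seed + 300 + f)
      ids <- sprintf("FAM%02d_%02d", f, seq_len(config$family_size))
      families[[sprintf("FAM%02d", f)]] <- ids
      proteins <- rbind(proteins, data.frame(
        protein_id = ids, proteome_id = home[f, ],
        length = fam_lens[f], stringsAsFactors = FALSE))
      if (!exists("fam_seqs", inherits = FALSE)) fam_seqs <- character(0)
      fam_seqs[ids] <- seqs
    }
  }

  # stage 3: sequences for every protein (family members already drawn)
  seqs <- withr_seed(seed + 404, vapply(seq_len(nrow(proteins)), function(i) {
    id <- proteins$protein_id[i]
    if (config$n_hp_families > 0 && id %in% names(fam_seqs))
      fam_seqs[[id]]
    else random_protein(proteins$length[i])
  }, character(1)))
  proteins$sequence <- seqs
  proteins$length <- nchar(proteins$sequence)
  # proteome sizes include planted family members
  meta$proteome_size <- as.integer(table(proteins$proteome_id)[meta$proteome_id])

  hp_ids <- proteins$protein_id[proteins$length >= 5000]

  # stage 4: annotations
  is_hp <- proteins$protein_id %in% hp_ids
  ann <- withr_seed(seed + 505, {
    lvl <- integer(nrow(proteins))
    lvl[is_hp] <- sample(1:4, sum(is_hp), replace = TRUE,
                         prob = config$existence_probs_hp)
    lvl[!is_hp] <- sample(1:4, sum(!is_hp), replace = TRUE,
                          prob = config$existence_probs_nonhp)
    sp <- stats::runif(nrow(proteins)) < config$p_signal_peptide
    tmh <- stats::rpois(nrow(proteins), config$tmh_lambda)
    cat_lab <- rep(NA_character_, nrow(proteins))
    if (length(config$category_probs))
      cat_lab[is_hp] <- sample(names(config$category_probs), sum(is_hp),
                               replace = TRUE, prob = config$category_probs)
    # disorder scores for HPs only; residue scores split at 0.5
    frac <- stats::rbeta(sum(is_hp), config$disorder_beta[1],
                         config$disorder_beta[2])
    hp_rows <- which(is_hp)
    n99 <- min(config$n_disorder_99, length(hp_rows))
    n100 <- min(config$n_disorder_100, n99)
    frac[seq_len(n99)] <- 0.995
    disorder <- vector("list", nrow(proteins))
    for (j in seq_along(hp_rows)) {
      len <- proteins$length[hp_rows[j]]
      if (j <= n100) {
        sc <- stats::runif(len, 0.5, 1)
      } else if (j <= n99) {
        n_ord <- max(1L, min(len - ceiling(0.99 * len), len))
        sc <- c(stats::runif(len - n_ord, 0.5, 1),
                stats::runif(n_ord, 0, 0.499))
      } else {
        dis <- stats::runif(len) < frac[j]
        sc <- ifelse(dis, stats::runif(len, 0.5, 1),
                     stats::runif(len, 0, 0.499))
      }
      disorder[[hp_rows[j]]] <- round(sc, 4)
    }
    list(level = lvl, sp = sp, tmh = tmh, cat = cat_lab, disorder = disorder)
  })
  annotations <- data.frame(
    protein_id = proteins$protein_id,
    existence_level = ann$level,
    has_signal_peptide = ann$sp,
    n_tmh = ann$tmh,
    go_terms = NA_character_,
    functional_category = ann$cat,
    stringsAsFactors = FALSE)
  annotations$disorder_scores <- ann$disorder

  # stage 5: planted architectures, recycled over the HP set in id order
  archs <- list()
  if (length(config$architecture_library) && length(hp_ids)) {
    ord <- sort(hp_ids)
    for (i in seq_along(ord))
      archs[[ord[i]]] <-
        config$architecture_library[[(i - 1L) %% length(config$architecture_library) + 1L]]
  }

  hp_rows <- which(is_hp)
  gt <- list(hp_ids = hp_ids, families = families, architectures = archs,
             disorder_99_ids = proteins$protein_id[hp_rows[seq_len(
               min(config$n_disorder_99, length(hp_rows)))]],
             disorder_100_ids = proteins$protein_id[hp_rows[seq_len(
               min(config$n_disorder_100, min(config$n_disorder_99, length(hp_rows))))]],
             category = stats::setNames(ann$cat[is_hp],
                                        proteins$protein_id[is_hp]))
  list(proteins = proteins, meta = meta, annotations = annotations,
       ground_truth = gt)
}

#' Simulate an hmmscan domtblout file for planted architectures
#'
#' Writes one data line per planted domain, envelope coordinates laid out
#' in architecture order with at least 5 residues between consecutive
#' envelopes, true-hit E-values drawn below the 0.001/0.001 thresholds
#' and, optionally, one decoy hit per protein with E-values above the
#' threshold (removed later by [filter_hits()]).
#'
#' @param sim Output of [simulate_proteomes()].
#' @param path Output path for the domtblout file.
#' @param decoys Add one above-threshold decoy hit per architected protein.
#' @param seed Integer seed (defaults to the simulation's).
#' @return `path`, invisibly.
#' @export
simulate_domtblout <- function(sim, path, decoys = FALSE,
                               seed = sim$ground_truth$config_seed %||% 606) {
  archs <- sim$ground_truth$architectures
  lens <- stats::setNames(sim$proteins$length, sim$proteins$protein_id)
  lines <- character(0)
  withr_seed(seed, {
    for (pid in names(archs)) {
      acc <- archs[[pid]]
      plen <- lens[[pid]]
      dlen <- sample(80:300, length(acc), replace = TRUE)
      need <- sum(dlen) + 5L * (length(acc) - 1L)
      if (need > plen)
        stop("architecture does not fit protein ", pid,
             " (needs ", need, " residues, protein has ", plen, ")")
      gaps <- 5L + sample(0:20, length(acc), replace = TRUE)
      start <- 1L
      froms <- integer(length(acc)); tos <- integer(length(acc))
      for (d in seq_along(acc)) {
        froms[d] <- start
        tos[d] <- start + dlen[d] - 1L
        start <- tos[d] + gaps[d]
      }
      if (tos[length(acc)] > plen)
        stop("architecture does not fit protein ", pid)
      ev <- 10^stats::runif(length(acc), -10, -4)
      dom_names <- sub("\\.\\d+$", "", acc)
      for (d in seq_along(acc)) {
        lines <- c(lines, paste(
          dom_names[d], acc[d], dlen[d], pid, "-", plen,
          format(ev[d], digits = 3, scientific = TRUE), "120.0", "0.1",
          d, length(acc),
          format(ev[d], digits = 3, scientific = TRUE),
          format(ev[d], digits = 3, scientific = TRUE),
          "118.0", "0.1", 1, dlen[d], froms[d], tos[d], froms[d], tos[d],
          "0.95", "-", sep = " "))
      }
      if (decoys) {
        dev <- stats::runif(1, 0.01, 0.9)
        dfrom <- max(1L, plen - 400L)
        lines <- c(lines, paste(
          "DECOY", "PF99999.1", 150, pid, "-", plen,
          format(dev, digits = 3, scientific = TRUE), "8.0", "0.1",
          1, 1,
          format(dev, digits = 3, scientific = TRUE),
          format(dev, digits = 3, scientific = TRUE),
          "7.5", "0.1", 1, 150, dfrom, dfrom + 149L, dfrom, dfrom + 149L,
          "0.60", "-", sep = " "))
      }
    }
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("#                     --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
               "# target name  accession tlen query name accession qlen E-value score bias # of c-Evalue i-Evalue score bias from to from to from to acc description",
               lines), con, sep = "\n")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated collection to a directory
#'
#' Emits the package's on-disk schemas: `proteins.fasta`, `metadata.tsv`,
#' `annotations.tsv` and `hits.domtblout`. Byte-identical for a fixed
#' config.
#'
#' @param sim Output of [simulate_proteomes()].
#' @param dir Output directory (created if missing).
#' @param decoys Passed to [simulate_domtblout()].
#' @param seed Seed for the domtblout E-value stream.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, decoys = FALSE, seed = 606) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$proteins, file.path(dir, "proteins.fasta"))
  write_metadata(sim$meta, file.path(dir, "metadata.tsv"))
  write_annotations(sim$annotations, file.path(dir, "annotations.tsv"))
  simulate_domtblout(sim, file.path(dir, "hits.domtblout"),
                     decoys = decoys, seed = seed)
  invisible(dir)
}
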