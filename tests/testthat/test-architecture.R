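test_that("E-value filtering requires both thresholds and is monotone", {
  hits <- make_hits(c("P1", "P1", "P2"), c("PF00001.21", "PF00002.5", "PF00003.1"),
                    from = c(1, 200, 1), to = c(100, 300, 90),
                    seq_e = c(1e-5, 1e-5, 1e-2), dom_e = c(1e-4, 0.01, 1e-4))
  out <- filter_hits(hits)
  expect_equal(out$pfam_accession, "PF00001.21")  # 1e-5/0.01 and 1e-2/1e-4 dropped
  expect_equal(nrow(filter_hits(hits[0, ])), 0L)
  # monotone: raising either threshold never removes a kept hit
  set.seed(2)
  rnd <- make_hits(rep("P", 40), sprintf("PF%05d.1", 1:40),
                   from = seq(1, 40 * 30, by = 30),
                   to = seq(1, 40 * 30, by = 30) + 20,
                   seq_e = 10^runif(40, -8, 0), dom_e = 10^runif(40, -8, 0))
  base <- filter_hits(rnd, 1e-3, 1e-3)
  for (th in list(c(1e-2, 1e-3), c(1e-3, 1e-2), c(1, 1))) {
    wider <- filter_hits(rnd, th[1], th[2])
    expect_true(all(base$pfam_accession %in% wider$pfam_accession))
  }
})

test_that("overlap resolution keeps the better-scoring of conflicting hits", {
  # A(1-100, score 80) vs B(40-140, score 50): overlap 61 > 50% of 100 -> A
  h <- make_hits("P1", c("PF00001.1", "PF00002.1"), from = c(1, 40),
                 to = c(100, 140), score = c(80, 50))
  out <- resolve_overlaps(h)
  expect_equal(out$pfam_accession, "PF00001.1")
  # A(1-100), B(90-200): overlap 11 <= 50% of the shorter (101) -> both
  h <- make_hits("P1", c("PF00001.1", "PF00002.1"), from = c(1, 90),
                 to = c(100, 200), score = c(80, 50))
  out <- resolve_overlaps(h)
  expect_equal(nrow(out), 2L)
  expect_equal(out$env_from, c(1L, 90L))  # sorted by envelope start
  # single hit unchanged
  h1 <- make_hits("P1", "PF00001.1", from = 10, to = 50)
  expect_equal(resolve_overlaps(h1)$env_from, 10L)
  # property: every retained pair overlaps <= 50% of the shorter envelope
  set.seed(14)
  rnd <- make_hits(rep("PX", 30), sprintf("PF%05d.1", 1:30),
                   from = sample(1:900, 30), to = 0, score = runif(30, 10, 99))
  rnd$env_to <- rnd$env_from + sample(30:120, 30, replace = TRUE)
  out <- resolve_overlaps(rnd)
  for (i in seq_len(nrow(out))) for (j in seq_len(nrow(out))) {
    if (i >= j) next
    olap <- min(out$env_to[i], out$env_to[j]) -
      max(out$env_from[i], out$env_from[j]) + 1
    shorter <- min(out$env_to[i] - out$env_from[i],
                   out$env_to[j] - out$env_from[j]) + 1
    expect_lte(olap, 0.5 * shorter)
  }
})

test_that("architecture deduction orders, strips versions, keeps repeats", {
  h <- make_hits("P1", c("PF00001.21", "PF00002.5", "PF00001.23"),
                 from = c(10, 150, 350), to = c(100, 300, 500))
  arch <- deduce_architecture(h)
  expect_equal(arch$pattern, "PF00001|PF00002|PF00001")
  expect_equal(arch$pattern_collapsed, "PF00001|PF00002|PF00001")
  # a run of identical accessions collapses with '*' in the secondary view
  h2 <- make_hits("P2", rep("PF00435.24", 3), from = c(1, 200, 400),
                  to = c(100, 300, 500))
  arch2 <- deduce_architecture(h2)
  expect_equal(arch2$pattern, "PF00435|PF00435|PF00435")
  expect_equal(arch2$pattern_collapsed, "PF00435*")
  # proteins without hits get an empty pattern (the no-domain set)
  arch3 <- deduce_architecture(h, protein_ids = c("P1", "P9"))
  expect_equal(arch3$pattern[arch3$protein_id == "P9"], "")
  expect_equal(arch3$n_domains[arch3$protein_id == "P9"], 0L)
})

test_that("architecture grouping is an equivalence with stable unique codes", {
  arch <- data.frame(protein_id = c("A", "B", "C", "D"),
                     pattern = c("PF1|PF2", "PF1|PF2", "PF2|PF1", ""),
                     stringsAsFactors = FALSE)
  g <- group_architectures(arch)
  expect_equal(nrow(g$groups), 2L)  # empty pattern excluded, order matters
  codeAB <- g$assignment$group_code[g$assignment$protein_id %in% c("A", "B")]
  expect_equal(codeAB[1], codeAB[2])
  codeC <- g$assignment$group_code[g$assignment$protein_id == "C"]
  expect_false(codeC == codeAB[1])
  expect_true(all(nchar(g$groups$group_code) == 6))
  expect_true(all(grepl("^[0-9A-Z]{6}$", g$groups$group_code)))
  # codes stable across runs and input orders
  g2 <- group_architectures(arch[c(3, 1, 4, 2), ])
  expect_equal(sort(g2$groups$group_code), sort(g$groups$group_code))
  # n distinct patterns -> n distinct codes even under a colliding hash
  colliding <- function(p) {
    # same digest for every pattern until a '#' rehash suffix is appended
    ifelse(grepl("#", p, fixed = TRUE),
           as.character(hugeprot:::.fnv1a64_cpp(p)),
           "00000000000000ff")
  }
  g3 <- group_architectures(arch, hash_fun = colliding)
  expect_equal(anyDuplicated(g3$groups$group_code), 0L)
})

test_that("planted architectures round-trip through filter and deduction", {
  cfg <- simulation_config(
    phyla = data.frame(superkingdom = "bacteria", phylum = "Planctomycetota",
                       n_proteomes = 3, hp_rate = 25, stringsAsFactors = FALSE),
    proteome_size_range = c(150, 200),
    length_lognormal_mu = 4, length_lognormal_sigma = 0.4, seed = 77)
  sim <- simulate_proteomes(cfg)
  path <- tempfile(fileext = ".domtbl")
  simulate_domtblout(sim, path, decoys = TRUE, seed = 5)
  hits <- resolve_overlaps(filter_hits(read_domtblout(path)))
  arch <- deduce_architecture(hits, sim$ground_truth$hp_ids)
  gt <- sim$ground_truth$architectures
  for (i in seq_len(nrow(arch))) {
    want <- paste(sub("\\.\\d+$", "", gt[[arch$protein_id[i]]]), collapse = "|")
    expect_equal(arch$pattern[i], want)
  }
  expect_false(any(grepl("PF99999", arch$pattern)))  # decoys filtered out
})

test_that("domain distribution subsamples phyla deterministically", {
  prot <- do.call(rbind, lapply(1:80, function(i)
    make_proteins(5500, proteome_id = sprintf("UP%04d", i),
                  prefix = sprintf("P%02d_", i))))
  meta <- make_meta(rep("Big", 80), rep(1, 80))
  hits <- make_hits(prot$protein_id, "PF00001.1", from = 1, to = 100)
  hits <- rbind(hits, make_hits(prot$protein_id[1], "PF00001.1",
                                from = 300, to = 400))
  d1 <- domain_distribution(hits, prot, meta, max_proteomes_per_phylum = 50,
                            seed = 3)
  d2 <- domain_distribution(hits, prot, meta, max_proteomes_per_phylum = 50,
                            seed = 3)
  expect_equal(length(d1$proteomes_used), 50L)
  expect_identical(d1, d2)
  # presence counts once per protein, occurrence counts copies
  pres <- d1$presence$n[d1$presence$pfam_accession == "PF00001"]
  occ <- d1$occurrence$n[d1$occurrence$pfam_accession == "PF00001"]
  expect_equal(occ - pres,
               as.integer(prot$proteome_id[1] %in% d1$proteomes_used))
  # small phylum fully retained
  meta2 <- make_meta(rep("Small", 3), rep(1, 3))
  prot2 <- prot[1:3, ]; prot2$proteome_id <- meta2$proteome_id
  hits2 <- make_hits(prot2$protein_id, "PF00002.1", from = 1, to = 80)
  d3 <- domain_distribution(hits2, prot2, meta2)
  expect_equal(length(d3$proteomes_used), 3L)
})

test_that("repeat census counts proteins once and demands a full mapping", {
  hits <- rbind(
    make_hits("P1", rep("PF00435.24", 30),
              from = seq(1, 30 * 60, by = 60),
              to = seq(1, 30 * 60, by = 60) + 50),
    make_hits("P2", "PF00501.30", from = 1, to = 100),
    make_hits("P3", c("PF00435.24", "PF00501.30"), from = c(1, 200),
              to = c(100, 300)))
  types <- data.frame(pfam_accession = c("PF00435", "PF00501"),
                      type = c("Repeat", "Domain"), stringsAsFactors = FALSE)
  res <- repeat_census(hits, types)
  expect_equal(res$n_proteins, 2L)  # P1 once despite 30 copies, plus P3
  expect_setequal(res$protein_ids, c("P1", "P3"))
  expect_equal(repeat_census(hits[0, ], types)$n_proteins, 0L)
  expect_error(repeat_census(hits, types[1, ]), "PF00501")
})
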