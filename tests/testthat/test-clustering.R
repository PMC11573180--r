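test_that("self- and prefix-alignment behave by construction", {
  s <- random_seq(120)
  al <- align_pair(s, s)
  expect_equal(al$identity, 1)
  expect_equal(al$coverage_query, 1)
  expect_equal(al$coverage_target, 1)

  half <- substr(s, 1, 60)
  al <- align_pair(half, s)
  expect_equal(al$identity, 1)
  expect_equal(al$coverage_query, 1)
  expect_equal(al$coverage_target, 0.5)

  # symmetry: identity preserved, coverages swapped
  fwd <- align_pair(half, s)
  rev <- align_pair(s, half)
  expect_equal(fwd$identity, rev$identity)
  expect_equal(fwd$score, rev$score)
  expect_equal(fwd$coverage_query, rev$coverage_target)
  expect_equal(fwd$coverage_target, rev$coverage_query)
})

test_that("aligner rejects characters outside the amino-acid alphabet", {
  expect_error(align_pair("MKV1", "MKV"), "outside")
  # U and O are accepted (scored as X)
  expect_silent(align_pair("MKUOV", "MKXXV"))
})

test_that("aligner matches the quadratic-space reference DP exactly", {
  set.seed(42)
  for (rep in 1:50) {
    a <- random_seq(sample(10:60, 1))
    b <- random_seq(sample(10:60, 1))
    got <- align_pair(a, b)
    ref <- sw_oracle(a, b)
    expect_equal(got$score, ref$score)
    expect_identical(got$identity, ref$identity)
    expect_identical(got$coverage_query, ref$coverage_query)
    expect_identical(got$coverage_target, ref$coverage_target)
  }
})

test_that("banded alignment agrees with the full DP on related pairs", {
  set.seed(7)
  fam <- simulate_hp_family(400, 2, 0.7, seed = 99)
  full <- align_pair(fam[1], fam[2], band = NULL)
  banded <- align_pair(fam[1], fam[2], band = "auto")
  expect_equal(banded$score, full$score)
  expect_equal(banded$identity, full$identity)
})

test_that("greedy clustering handles trivial and maximal-stringency cases", {
  expect_equal(nrow(greedy_cluster(data.frame(protein_id = character(),
                                              sequence = character()))), 0L)
  s <- random_seq(100)
  two <- data.frame(protein_id = c("A", "B"), sequence = c(s, s),
                    stringsAsFactors = FALSE)
  cl <- greedy_cluster(two)
  expect_equal(length(unique(cl$cluster_id)), 1L)
  expect_equal(nrow(cl), 2L)

  set.seed(11)
  distinct <- data.frame(protein_id = paste0("S", 1:4),
                         sequence = vapply(1:4, function(i) random_seq(80),
                                           character(1)),
                         stringsAsFactors = FALSE)
  cl <- greedy_cluster(distinct, min_identity = 1, min_coverage = 1)
  expect_equal(length(unique(cl$cluster_id)), 4L)
})

test_that("clustering is a partition, order-invariant, and matches the brute-force oracle", {
  set.seed(5)
  # families of related short sequences plus noise; n <= 30
  base1 <- random_seq(60); base2 <- random_seq(60)
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    pos <- sample(length(v), k)
    v[pos] <- sample(c("A","R","N","D","C","Q","E","G","H","I"), k,
                     replace = TRUE)
    paste(v, collapse = "")
  }
  seqs <- c(vapply(1:5, function(i) mutate(base1, 8), character(1)),
            vapply(1:5, function(i) mutate(base2, 8), character(1)),
            vapply(1:6, function(i) random_seq(sample(40:70, 1)),
                   character(1)))
  prot <- data.frame(protein_id = sprintf("P%02d", seq_along(seqs)),
                     sequence = seqs, stringsAsFactors = FALSE)
  cl <- greedy_cluster(prot, 0.5, 0.8, band = NULL)
  # partition over the input ids
  expect_setequal(cl$member_id, prot$protein_id)
  expect_equal(anyDuplicated(cl$member_id), 0L)
  # member thresholds hold against the representative
  nonrep <- cl[cl$member_id != cl$representative_id, ]
  expect_true(all(nonrep$identity_to_rep >= 0.5))
  expect_true(all(nonrep$cov_member >= 0.8 & nonrep$cov_rep >= 0.8))
  # representatives pairwise fail the joint criterion
  reps <- unique(cl$representative_id)
  rep_seq <- prot$sequence[match(reps, prot$protein_id)]
  for (i in seq_along(reps)) for (j in seq_along(reps)) {
    if (i >= j) next
    al <- align_pair(rep_seq[i], rep_seq[j])
    expect_false(al$identity >= 0.5 && al$coverage_query >= 0.8 &&
                   al$coverage_target >= 0.8)
  }
  # brute-force equivalence
  oracle <- brute_force_cluster(prot, 0.5, 0.8)
  got <- stats::setNames(cl$cluster_id, cl$member_id)[names(oracle)]
  expect_equal(as.integer(got), as.integer(oracle))
  # input order does not matter
  cl2 <- greedy_cluster(prot[rev(seq_len(nrow(prot))), ], 0.5, 0.8,
                        band = NULL)
  expect_equal(cl2, cl)
})

test_that("cluster composition and category tables recover planted labels", {
  s <- random_seq(90)
  prot <- data.frame(protein_id = sprintf("P%02d", 1:10),
                     proteome_id = rep(c("UP0001", "UP0002"), each = 5),
                     sequence = c(rep(s, 6),
                                  vapply(1:4, function(i) random_seq(90),
                                         character(1))),
                     stringsAsFactors = FALSE)
  meta <- make_meta(c("Planctomycetota", "Apicomplexa"), c(5, 5),
                    superkingdom = c("bacteria", "eukaryota"))
  cat_lab <- c(rep("Q", 5), rep("M", 3), rep("S", 2))
  ann <- data.frame(protein_id = prot$protein_id,
                    functional_category = cat_lab, stringsAsFactors = FALSE)
  cl <- greedy_cluster(prot, 0.3, 0.8, band = NULL)
  cs <- cluster_summary(cl, prot, meta, ann)
  # 6 identical sequences cluster together across both proteomes
  expect_equal(max(cs$per_cluster$size), 6L)
  expect_true(any(cs$per_cluster$cross_superkingdom))
  # planted 0.5/0.3/0.2 proportions recovered exactly
  tab <- cs$category_table
  expect_equal(sum(tab$n_proteins[tab$functional_category == "Q"]), 5L)
  expect_equal(sum(tab$n_proteins[tab$functional_category == "M"]), 3L)
  expect_equal(sum(tab$n_proteins[tab$functional_category == "S"]), 2L)
  # counts sorted descending within superkingdom
  for (sk in unique(tab$superkingdom)) {
    v <- tab$n_proteins[tab$superkingdom == sk]
    expect_true(all(diff(v) <= 0))
  }
  # unassigned convention
  ann$functional_category[1] <- NA
  cs2 <- cluster_summary(cl, prot, meta, ann)
  expect_equal(cs2$n_unassigned, 1L)
})
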