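test_that("existence proportions count per cohort and reject level 5", {
  prot <- data.frame(protein_id = sprintf("P%02d", 1:8),
                     existence_level = c(4L, 4L, 4L, 1L, 4L, 4L, 4L, 1L),
                     stringsAsFactors = FALSE)
  # HP cohort all level 4
  res <- existence_proportions(prot, c("P01", "P02", "P03"))
  expect_equal(unname(res$hp_pct), c(0, 0, 0, 100))
  # cohort of 4 with levels [1,4,4,4]
  res <- existence_proportions(prot, c("P04", "P05", "P06", "P07"))
  expect_equal(unname(res$hp_pct), c(25, 0, 0, 75))
  expect_equal(sum(res$hp_pct), 100)
  expect_equal(sum(res$nonhp_pct), 100)
  prot$existence_level[1] <- 5L
  expect_error(existence_proportions(prot, "P04"), "level 5")
})

test_that("proportions recover the generator's planted level distribution", {
  probs <- c(0.008, 0.0006, 0.22, 0.7714)
  cfg <- simulation_config(
    phyla = data.frame(superkingdom = "eukaryota", phylum = "Apicomplexa",
                       n_proteomes = 5, hp_rate = 30,
                       stringsAsFactors = FALSE),
    proteome_size_range = c(2000, 2000),
    length_lognormal_mu = 4, length_lognormal_sigma = 0.4,
    existence_probs_hp = probs, seed = 21)
  sim <- simulate_proteomes(cfg)
  hp_ids <- sim$ground_truth$hp_ids
  prot <- attach_existence(sim$proteins, sim$annotations)
  res <- existence_proportions(prot, hp_ids)
  n <- length(hp_ids)
  for (l in 1:4) {
    se <- sqrt(probs[l] * (1 - probs[l]) / n)
    expect_lt(abs(res$hp_pct[l] / 100 - probs[l]), max(4 * se, 1e-9) + 1e-12)
  }
})

test_that("resampling is exact for exhaustive samples and calibrated otherwise", {
  pop <- rep(1:4, c(10, 20, 30, 40))
  ex <- resample_nonhp(pop, length(pop), n_reps = 5, seed = 1)
  expect_equal(ex$mean_count, c(10, 20, 30, 40))
  expect_equal(ex$sd_count, rep(0, 4))
  expect_error(resample_nonhp(pop, 101, 5, 1), "exceeds population")

  # hypergeometric calibration: population 50% level 4
  pop <- rep(c(1L, 4L), c(500, 500))
  rs <- resample_nonhp(pop, 200, n_reps = 100, seed = 9)
  p <- 0.5; N <- 1000; k <- 200
  se_rep <- sqrt(k * p * (1 - p) * (N - k) / (N - 1))
  expect_lt(abs(rs$mean_count[4] - k * p), 3 * se_rep / sqrt(100))
  # determinism under seed
  rs2 <- resample_nonhp(pop, 200, n_reps = 100, seed = 9)
  expect_identical(rs, rs2)
})

test_that("Kruskal-Wallis H and ANOVA F match hand computation on toys", {
  # complete separation with ties: hand rank computation gives H = 5
  res <- compare_distributions(c(1, 1, 1), c(4, 4, 4))
  expect_equal(res$kruskal_h, 5)
  # identical multisets: no group effect
  res <- compare_distributions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$kruskal_h, 0)
  expect_equal(res$kruskal_p, 1)
  expect_equal(res$anova_f, 0)
  # textbook mean-square ratio on a 6-value toy:
  # hp=[1,2,1], nonhp=[4,3,4]: SSB=49/6, SSW=4/3, F=(49/6)/(1/3)=24.5
  res <- compare_distributions(c(1, 2, 1), c(4, 3, 4))
  expect_equal(res$anova_f, 24.5)
  expect_error(compare_distributions(1, c(1, 2)), "at least 2")
})

test_that("H and F agree with the stats reference to 1e-9 on random cohorts", {
  set.seed(31)
  for (rep in 1:50) {
    a <- sample(1:4, sample(5:40, 1), replace = TRUE)
    b <- sample(1:4, sample(5:40, 1), replace = TRUE)
    if (length(unique(c(a, b))) < 2) next
    res <- compare_distributions(a, b)
    x <- c(a, b); g <- factor(rep(1:2, c(length(a), length(b))))
    kw <- stats::kruskal.test(x, g)
    expect_equal(res$kruskal_h, unname(kw$statistic), tolerance = 1e-9)
    expect_equal(res$kruskal_p, kw$p.value, tolerance = 1e-9)
    av <- stats::anova(stats::lm(x ~ g))
    expect_equal(res$anova_f, av$`F value`[1], tolerance = 1e-9)
    expect_equal(res$anova_p, av$`Pr(>F)`[1], tolerance = 1e-9)
  }
})

test_that("quality correlations handle collinear and hand-computed cases", {
  meta <- make_meta(rep("B", 5), rep(100, 5), busco = c(70, 80, 90, 95, 100))
  # HP counts exactly collinear with completeness: 0,1,2,2.5,3 impossible
  # for counts; use 0,2,4,5,6 via planted HPs
  counts <- c(0, 2, 4, 5, 6)
  prot <- do.call(rbind, lapply(seq_len(5), function(i) {
    if (counts[i] == 0) return(NULL)
    make_proteins(rep(5500, counts[i]), proteome_id = meta$proteome_id[i],
                  prefix = paste0("H", i, "_"))
  }))
  hps <- extract_hps(prot)
  qc <- quality_correlations(meta, hps)
  r_count <- qc$r[qc$metric == "hp_count"]
  # independent hand computation by the covariance/sd ratio
  x <- meta$busco_completeness; y <- counts
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r_count, r_hand)
  # anti-collinear lengths: make HP length decrease with completeness
  meta2 <- make_meta(rep("B", 3), rep(100, 3), busco = c(80, 90, 100))
  prot2 <- do.call(rbind, lapply(1:3, function(i)
    make_proteins(9000 - 1000 * i, proteome_id = meta2$proteome_id[i],
                  prefix = paste0("L", i, "_"))))
  qc2 <- quality_correlations(meta2, extract_hps(prot2))
  expect_equal(qc2$r[qc2$metric == "hp_length"], -1)
  # fewer than 3 points -> NA, missing completeness excluded and counted
  meta3 <- make_meta(rep("B", 3), rep(100, 3), busco = c(80, NA, NA))
  qc3 <- quality_correlations(meta3, extract_hps(prot2))
  expect_true(is.na(qc3$r[qc3$metric == "hp_count"]))
  expect_equal(qc3$n_excluded[qc3$metric == "hp_count"], 2L)
})

test_that("assembly-level summary gives exact medians per group", {
  meta <- make_meta(rep("B", 5), rep(100, 5),
                    assembly = c("Chromosome", "Chromosome", "Chromosome",
                                 "Unplaced", "Linkage Group"))
  counts <- c(1, 2, 31, 4, 0)
  prot <- do.call(rbind, lapply(seq_len(5), function(i) {
    if (counts[i] == 0) return(NULL)
    make_proteins(rep(5100, counts[i]), proteome_id = meta$proteome_id[i],
                  prefix = paste0("A", i, "_"))
  }))
  res <- assembly_level_summary(meta, extract_hps(prot))
  expect_equal(res$median[res$assembly_level == "Chromosome"], 2)
  expect_equal(res$median[res$assembly_level == "Unplaced"], 4)
  expect_equal(res$median[res$assembly_level == "Linkage Group"], 0)
  expect_false("Unassembled WGS" %in% res$assembly_level)
})
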