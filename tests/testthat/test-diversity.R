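test_that("segregating sites count polymorphic resolved columns", {
  expect_equal(segregating_sites(make_aln(c("ACGT", "ACGA", "ACGT"))), 1L)
  expect_equal(segregating_sites(make_aln(c("ACGT", "ACGT"))), 0L)
  # a column variable only through an N is not segregating
  expect_equal(segregating_sites(make_aln(c("ANGT", "AAGT"))), 0L)
  for (seed in 1:3) {
    aln <- random_aln(5, 60, seed = seed, missing_rate = 0.1)
    expect_identical(segregating_sites(aln), oracle_segregating_sites(aln))
  }
})

test_that("nucleotide diversity equals the mean pairwise p-distance", {
  expect_equal(nucleotide_diversity(make_aln(c("AAAA", "AAAT"))), 0.25)
  expect_equal(nucleotide_diversity(make_aln(c("AAAA", "AAAA", "AAAA"))), 0)
  aln <- random_aln(6, 80, seed = 7, missing_rate = 0.05)
  expect_equal(nucleotide_diversity(aln), oracle_pi(aln))
})

test_that("simulated diversity matches the configured theta", {
  # panmictic pool at theta = 0.005: mean realized pi within 2 SE over reps
  pis <- vapply(1:40, function(r) {
    ds <- simulate_dataset(sim_config(seed = 3000 + r, loci = c(mt = 1000L),
      clades = data.frame(clade_id = 1, locality_code = 1, n = 10L),
      d = 0, theta = 0.005, scenario = "panmixia"))
    nucleotide_diversity(ds$alignments$mt)
  }, numeric(1))
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - 0.005), 2 * se + 1e-4)
})

test_that("haplotype counting uses complete deletion and the corrected Hd", {
  hp <- haplotypes(make_aln(c("ACGT", "ACGA")))
  expect_equal(hp$h, 2L)
  expect_equal(hp$Hd, 1.0)
  # {X, X, Y}: Hd = (3/2)(1 - (4/9 + 1/9)) = 2/3
  hp2 <- haplotypes(make_aln(c("ACGT", "ACGT", "ACGA")))
  expect_equal(hp2$h, 2L)
  expect_equal(hp2$Hd, 2 / 3)
  # a column with any unresolved symbol is dropped for haplotype identity:
  # s1/s2 differ only at the N-carrying column, so they collapse
  hp3 <- haplotypes(make_aln(c("ACGT", "ACNT", "TCGT")))
  expect_equal(hp3$h, 2L)
  expect_equal(hp3$sites_used, 3L)

  # invariance under row order; Hd = 0 iff h = 1
  aln <- random_aln(6, 30, seed = 13)
  hp4 <- haplotypes(aln)
  perm <- locus_alignment(aln$seqs[sample(6), ], locus = "p")
  hp5 <- haplotypes(perm)
  expect_equal(hp5$h, hp4$h)
  expect_equal(hp5$Hd, hp4$Hd)
  mono <- haplotypes(make_aln(c("AAAA", "AAAA", "AAAA")))
  expect_equal(mono$h, 1L)
  expect_equal(mono$Hd, 0)
})

test_that("standardized diversity equals raw when s = N", {
  aln <- random_aln(5, 40, seed = 17)
  std <- standardized_diversity(list(g = aln), seed = 4)
  expect_equal(std$S_std, std$S)
  expect_equal(std$h_std, std$h)
  expect_equal(std$Hd_std, std$Hd)
  expect_equal(std$pi_std, std$pi)
  expect_equal(std$s, 5)
})

test_that("exhaustive rarefaction equals the enumerated subset average", {
  aln <- random_aln(4, 50, seed = 23, missing_rate = 0.05)
  std <- standardized_diversity(list(g = aln), s = 2, exhaustive = TRUE)
  # independent enumeration with the primitive statistics
  subs <- combn(aln$ids, 2, simplify = FALSE)
  expect_length(subs, 6)
  vals <- t(vapply(subs, function(ss) {
    sub <- subset_alignment(aln, ids = ss)
    hp <- haplotypes(sub)
    c(S = segregating_sites(sub), h = hp$h, Hd = hp$Hd,
      pi = suppressWarnings(nucleotide_diversity(sub)))
  }, numeric(4)))
  expect_equal(std$S_std, mean(vals[, "S"]))
  expect_equal(std$h_std, mean(vals[, "h"]))
  expect_equal(std$Hd_std, mean(vals[, "Hd"]))
  expect_equal(std$pi_std, mean(vals[, "pi"]))
  # rarefaction can only lose segregating sites
  expect_lte(std$S_std, std$S)
})

test_that("resampling is seed-reproducible and per-group independent", {
  a <- random_aln(8, 60, seed = 31)
  b <- random_aln(4, 60, seed = 32)
  r1 <- standardized_diversity(list(big = a, small = b), n_resamples = 25, seed = 5)
  r2 <- standardized_diversity(list(big = a, small = b), n_resamples = 25, seed = 5)
  expect_identical(r1, r2)
  # adding a group does not disturb an existing group's draws
  c3 <- random_aln(6, 60, seed = 33)
  r3 <- standardized_diversity(list(big = a, small = b, extra = c3),
                               n_resamples = 25, seed = 5, s = 4)
  expect_equal(r3[r3$group == "big", c("S_std", "h_std", "Hd_std", "pi_std")],
               r1[r1$group == "big", c("S_std", "h_std", "Hd_std", "pi_std")],
               ignore_attr = TRUE)
  # different seed, different draws (with overwhelming probability)
  r4 <- standardized_diversity(list(big = a, small = b), n_resamples = 25, seed = 6)
  expect_false(isTRUE(all.equal(r4$pi_std[1], r1$pi_std[1], tolerance = 1e-12)))
})

test_that("groups below two sequences are excluded from standardization", {
  a <- random_aln(4, 30, seed = 41)
  single <- subset_alignment(a, ids = "s1")
  std <- standardized_diversity(list(g = a, lone = single), seed = 1)
  expect_equal(std$s[1], 4)            # s ignores the size-1 group
  expect_true(is.na(std$pi_std[std$group == "lone"]))
  expect_error(standardized_diversity(list(lone = single)), class = "data_error")
})

test_that("the diversity report carries raw and standardized rows per locus", {
  ds <- simulate_dataset(structured_config(seed = 77, n = 4L, L = 300L))
  grouping <- setNames(ds$samples$clade_id, ds$samples$specimen_id)
  rep <- diversity_report(ds$alignments, grouping, n_resamples = 10, seed = 2)
  expect_equal(nrow(rep), 4 * 2)       # 4 clades x {raw, standardized}
  expect_setequal(unique(rep$type), c("raw", "standardized"))
  expect_equal(rep$pi_e3, rep$pi * 1e3)
  # equal group sizes: standardized rows equal raw rows
  raw <- rep[rep$type == "raw", ]
  std <- rep[rep$type == "standardized", ]
  expect_equal(std$pi, raw$pi)
  # cells agree with direct per-group calls
  for (g in unique(raw$group)) {
    sub <- subset_alignment(ds$alignments$mt,
                            ids = names(grouping)[grouping == g])
    expect_equal(raw$pi[raw$group == g], nucleotide_diversity(sub))
    expect_equal(raw$S[raw$group == g], segregating_sites(sub))
  }
})
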