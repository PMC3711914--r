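test_that("Phi-ST is 1 for fixed between-group differences and drops tiny groups", {
  aln <- make_aln(c("AAAA", "AAAA", "TTTT", "TTTT"))
  D <- distance_matrix(aln)
  fit <- amova_phist(D, c(s1 = "g1", s2 = "g1", s3 = "g2", s4 = "g2"))
  expect_equal(fit$phi, 1.0)

  # a singleton group is dropped with a warning
  aln5 <- make_aln(c("AAAA", "AAAA", "TTTT", "TTTT", "GGGG"))
  D5 <- distance_matrix(aln5)
  expect_warning(fit5 <- amova_phist(D5, c(s1 = "a", s2 = "a", s3 = "b",
                                           s4 = "b", s5 = "c")),
                 "dropping")
  expect_equal(fit5$n, 4)

  # all-zero distances: undefined
  same <- distance_matrix(make_aln(c("AAAA", "AAAA", "AAAA", "AAAA")))
  expect_true(is.na(amova_phist(same, c(s1 = "a", s2 = "a", s3 = "b", s4 = "b"))$phi))
})

test_that("Phi-ST is centred near zero under panmixia", {
  phis <- vapply(1:40, function(r) {
    ds <- simulate_dataset(sim_config(seed = 5000 + r, loci = c(mt = 600L),
      clades = data.frame(clade_id = 1:4, locality_code = 1:4, n = 5L),
      d = 0, theta = 0.01, scenario = "panmixia"))
    D <- distance_matrix(ds$alignments$mt)
    amova_phist(D, setNames(ds$samples$clade_id, ds$samples$specimen_id))$phi
  }, numeric(1))
  expect_lt(abs(mean(phis, na.rm = TRUE)), 0.05)
})

test_that("Phi-ST permutation p-values honour the +1 convention and enumeration", {
  # strong structure at realistic size: no permuted arrangement matches the
  # true partition, so the p-value hits the +1 floor
  ds <- simulate_dataset(structured_config(seed = 71, n = 6L, d = 0.08, L = 500L))
  D <- distance_matrix(ds$alignments$mt)
  grp <- setNames(ds$samples$clade_id, ds$samples$specimen_id)
  fit <- fst_permutation_test(D, grp, n_perm = 999, seed = 3)
  expect_equal(fit$p_value, 1 / 1000)
  expect_error(fst_permutation_test(D, grp, n_perm = 0), class = "config_error")

  # tiny asymmetric case: Monte-Carlo p within binomial error of enumeration
  aln2 <- random_aln(4, 60, seed = 19)
  D2 <- distance_matrix(aln2)
  grp2 <- c(s1 = "a", s2 = "a", s3 = "b", s4 = "b")
  p_mc <- fst_permutation_test(D2, grp2, n_perm = 4000, seed = 7,
                               plus_one = FALSE)$p_value
  p_exact <- exact_phist_p(D2$d^2, unname(grp2))
  expect_lt(abs(p_mc - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 4000) + 1e-9)
})

test_that("pooled between/within-clade means match the pair-loop oracle", {
  D <- distance_matrix(make_aln(c("AAAA", "AAAA", "TTTT", "TTTT")))
  st <- bc_wc_statistics(D, list(c1 = c("s1", "s2"), c2 = c("s3", "s4")))
  expect_equal(st$D_bc, 1.0)
  expect_equal(st$D_wc, 0.0)
  # one clade only: D_bc undefined
  st1 <- bc_wc_statistics(D, list(c1 = paste0("s", 1:4)))
  expect_true(is.na(st1$D_bc))

  aln <- random_aln(9, 70, seed = 29)
  D2 <- distance_matrix(aln)
  lab <- setNames(rep(c("a", "b", "c"), each = 3), aln$ids)
  st2 <- bc_wc_statistics(D2, lab)
  orc <- oracle_bcwc(D2$d, unname(lab))
  expect_equal(st2$D_bc, unname(orc["D_bc"]))
  expect_equal(st2$D_wc, unname(orc["D_wc"]))
  # singleton clades contribute to D_bc but not D_wc
  lab3 <- setNames(c("a", "a", "a", "b", "b", "b", "c", "d", "e"), aln$ids)
  st3 <- bc_wc_statistics(D2, lab3)
  expect_equal(st3$n_wc_pairs, 2 * choose(3, 2))
})

test_that("the between- vs within-clade test matches exhaustive enumeration", {
  # strong structure: no permutation can reach the observed statistic
  ds <- simulate_dataset(structured_config(seed = 99, n = 3L, L = 500L, d = 0.08))
  D <- distance_matrix(ds$alignments$mt)
  lab <- setNames(ds$samples$clade_id, ds$samples$specimen_id)
  res <- test_bc_vs_wc(D, lab, n_perm = 1000, seed = 1)
  expect_equal(res$p_value, 1 / 1001)

  # 5 individuals in clades (3, 2): all C(5,3) = 10 assignments
  aln <- random_aln(5, 80, seed = 37)
  D2 <- distance_matrix(aln)
  lab2 <- setNames(c("x", "x", "x", "y", "y"), aln$ids)
  p_exact <- exact_bcwc_p(D2$d, unname(lab2))
  p_mc <- test_bc_vs_wc(D2, lab2, n_perm = 4000, seed = 11,
                        plus_one = FALSE)$p_value
  expect_lt(abs(p_mc - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 4000) + 1e-9)

  # degenerate clade structures are rejected
  expect_error(test_bc_vs_wc(D2, setNames(rep("x", 5), aln$ids)),
               class = "data_error")
  expect_error(test_bc_vs_wc(D2, setNames(c("a", "b", "c", "d", "e"), aln$ids)),
               class = "data_error")
})

test_that("permutation results are bit-reproducible under a fixed seed", {
  ds <- simulate_dataset(structured_config(seed = 55, n = 4L, L = 400L))
  D <- distance_matrix(ds$alignments$mt)
  lab <- setNames(ds$samples$clade_id, ds$samples$specimen_id)
  r1 <- test_bc_vs_wc(D, lab, n_perm = 300, seed = 42)
  r2 <- test_bc_vs_wc(D, lab, n_perm = 300, seed = 42)
  expect_identical(r1, r2)
  f1 <- fst_permutation_test(D, lab, n_perm = 300, seed = 42)
  f2 <- fst_permutation_test(D, lab, n_perm = 300, seed = 42)
  expect_identical(f1, f2)
  sch <- sim_scheme(simulate_dataset(northern_config(88, "northern_in_situ")))
  ds2 <- simulate_dataset(northern_config(88, "northern_in_situ"))
  D2 <- distance_matrix(ds2$alignments$mt)
  o1 <- northern_origin_test(D2, sim_scheme(ds2), 99L, n_perm = 200, seed = 9)
  o2 <- northern_origin_test(D2, sim_scheme(ds2), 99L, n_perm = 200, seed = 9)
  expect_identical(o1, o2)
})

test_that("observed statistics are independent of the permutation stream", {
  ds <- simulate_dataset(structured_config(seed = 61, n = 4L, L = 400L))
  D <- distance_matrix(ds$alignments$mt)
  lab <- setNames(ds$samples$clade_id, ds$samples$specimen_id)
  r1 <- test_bc_vs_wc(D, lab, n_perm = 100, seed = 1)
  r2 <- test_bc_vs_wc(D, lab, n_perm = 500, seed = 999)
  expect_equal(r1$observed, r2$observed)
  st <- bc_wc_statistics(D, lab)
  expect_equal(r1$D_bc, st$D_bc)
  expect_equal(r1$D_wc, st$D_wc)
})

test_that("phased rows of one individual travel together in permutations", {
  lab <- c("a", "a", "b", "b", "c", "c")
  ind <- c("i1", "i1", "i2", "i2", "i3", "i3")
  set.seed(1)
  for (k in 1:20) {
    pl <- divpart:::permute_labels(lab, ind)
    expect_equal(pl[1], pl[2])
    expect_equal(pl[3], pl[4])
    expect_equal(pl[5], pl[6])
    expect_equal(sort(pl), sort(lab))
  }
})

test_that("partition schemes validate their locality sets", {
  expect_error(partition_scheme(c(a = 1), c(`1` = 1), northern = 1, southern = 1),
               class = "metadata_error")
  expect_error(partition_scheme(c(a = 1), c(`1` = 1), northern = 1, southern = 2,
                                contiguous = list(bad = list(northern = 1, southern = 3))),
               class = "metadata_error")
  samples <- load_sample_table(
    system.file("extdata", "podarcis_samples.tsv", package = "divpart"))
  sch <- study_scheme(samples)
  expect_setequal(sch$northern, c(1, 20:23, 25:26, 35:36, 37:39))
  expect_length(sch$contiguous, 5)
  expect_equal(sch$contiguous$pyrenees$southern, c(2:16, 18L))
  # the Slovenian block is compared against both adjacent refugia
  expect_equal(sum(vapply(sch$contiguous, function(b) 35 %in% b$northern, logical(1))), 2)
})

test_that("origin tests distinguish the two demographic scenarios", {
  ds_in <- simulate_dataset(northern_config(101, "northern_in_situ"))
  D_in <- distance_matrix(ds_in$alignments$mt)
  sch_in <- sim_scheme(ds_in)
  res_in <- northern_origin_test(D_in, sch_in, 99L,
                                 southern_set = sch_in$contiguous$source_region$southern,
                                 n_perm = 500, seed = 2)
  expect_lte(res_in$p_wc, 0.05)
  expect_equal(classify_origin(res_in), "in_situ")

  ds_re <- simulate_dataset(northern_config(101, "northern_recent_expansion"))
  D_re <- distance_matrix(ds_re$alignments$mt)
  sch_re <- sim_scheme(ds_re)
  res_re <- northern_origin_test(D_re, sch_re, 99L,
                                 southern_set = sch_re$contiguous$source_region$southern,
                                 n_perm = 500, seed = 2)
  expect_gt(res_re$p_wc, 0.05)
  expect_equal(classify_origin(res_re), "recent_expansion")
  # the colonist locality sits near its source pool
  expect_lt(res_re$D_i, res_re$D_bc / 2)

  expect_error(northern_origin_test(D_re, sch_re, 12345L), class = "data_error")
})

test_that("the origin battery enumerates (locality x reference set) rows", {
  ds <- simulate_dataset(northern_config(31, "northern_in_situ"))
  D <- distance_matrix(ds$alignments$mt)
  sch <- sim_scheme(ds)
  bat <- run_origin_battery(D, sch, n_perm = 200, seed = 4)
  # one northern locality, all-southern + source-region comparisons
  expect_equal(nrow(bat), 2)
  expect_setequal(bat$comparison, c("all_southern", "source_region"))
  # with no contiguous block: a single row
  sch0 <- partition_scheme(sch$locality_of, sch$clade_of_locality,
                           northern = sch$northern, southern = sch$southern)
  expect_equal(nrow(run_origin_battery(D, sch0, n_perm = 100, seed = 4)), 1)
  # rows recompute the same observed quantities as direct calls
  direct <- northern_origin_test(D, sch, 99L, n_perm = 10, seed = 1)
  expect_equal(bat$D_i[bat$comparison == "all_southern"], direct$D_i)
})
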