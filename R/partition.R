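# Distance-based variance partitioning (AMOVA Phi-ST) and the permutation
# framework: between- vs within-clade mean distances, and the tests that
# classify a peripheral locality as an in-situ lineage versus a recent
# colonist from a southern source pool.

# normalise a grouping (named vector id -> label, factor, or list
# label -> ids) into a character vector aligned with `ids`; NA = unassigned
labels_for <- function(grouping, ids) {
  if (inherits(grouping, "clade_map")) {
    grouping <- grouping$members
  }
  if (is.list(grouping)) {
    grouping <- stats::setNames(rep(names(grouping), lengths(grouping)),
                                unlist(grouping))
  }
  lab <- as.character(grouping)[match(ids, names(grouping))]
  lab
}

# Phi-ST point computation on a squared-distance matrix given labels.
# Two-level AMOVA: SS_total = (1/N) sum_{i<j} d2; SS_within = sum_g (1/n_g)
# sum_{i<j in g} d2; sigma2_w = SS_w/(N-G); sigma2_a from the expected mean
# square with the unequal-size coefficient n_bar.
phist_stat <- function(d2, lab) {
  N <- length(lab)
  groups <- split(seq_len(N), lab)
  G <- length(groups)
  ss_total <- sum(d2[upper.tri(d2)], na.rm = TRUE) / N
  ss_within <- 0
  for (idx in groups) {
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)], na.rm = TRUE) / length(idx)
    }
  }
  ss_among <- ss_total - ss_within
  s2w <- ss_within / (N - G)
  nbar <- (N - sum(lengths(groups)^2) / N) / (G - 1)
  s2a <- (ss_among / (G - 1) - s2w) / nbar
  denom <- s2a + s2w
  phi <- if (denom <= 0) NA_real_ else s2a / denom
  list(phi = phi, sigma_among = s2a, sigma_within = s2w,
       ss_among = ss_among, ss_within = ss_within, n_groups = G, n = N)
}

#' AMOVA-based Phi-ST from a p-distance matrix
#'
#' Partitions molecular variance among and within groups using squared
#' pairwise p-distances (the distance-based analysis of molecular variance).
#' Groups with fewer than two members are dropped with a warning. With all
#' pairwise distances zero the statistic is undefined and returned as `NA`.
#'
#' @param D a `pdist` object.
#' @param groups grouping of sequences: named vector id -> group, a list
#'   group -> ids, or a `clade_map`.
#' @return object of class `amova_phist` with the Phi-ST estimate, variance
#'   components and sums of squares.
#' @export
amova_phist <- function(D, groups) {
  stopifnot(inherits(D, "pdist"))
  lab <- labels_for(groups, D$ids)
  keep <- !is.na(lab)
  lab <- lab[keep]
  tab <- table(lab)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    warning(sprintf("dropping group(s) with < 2 members: %s", paste(small, collapse = ", ")))
    keep2 <- !(lab %in% small)
    lab <- lab[keep2]
    keep[keep] <- keep2
  }
  if (length(unique(lab)) < 2) data_error("Phi-ST needs >= 2 groups with >= 2 members")
  d2 <- D$d[keep, keep, drop = FALSE]^2
  st <- phist_stat(d2, lab)
  structure(c(st, list(ids = D$ids[keep], labels = lab, dropped = small)),
            class = "amova_phist")
}

#' @export
print.amova_phist <- function(x, ...) {
  cat(sprintf("<amova_phist> Phi_ST = %.4f (%d groups, %d sequences)\n",
              x$phi, x$n_groups, x$n))
  cat(sprintf("  variance among %.6g, within %.6g\n", x$sigma_among, x$sigma_within))
  if (!is.null(x$p_value)) {
    cat(sprintf("  p = %.4g (%d permutations, seed %s)\n", x$p_value, x$n_perm, x$seed))
  }
  invisible(x)
}

#' Permutation significance of Phi-ST
#'
#' Builds the null distribution of Phi-ST by shuffling individuals among
#' groups while holding group sizes fixed; the p-value is
#' `(# permuted Phi >= observed + 1) / (n_perm + 1)` (ties count as
#' exceedances).
#'
#' @inheritParams amova_phist
#' @param n_perm number of permutations (default 1000).
#' @param seed integer RNG seed.
#' @param plus_one use the `+1` convention (default); otherwise the raw
#'   proportion of exceedances is reported.
#' @return an `amova_phist` object with `p_value`, `n_perm`, `seed`, and
#'   `null_phi` summary statistics added.
#' @export
fst_permutation_test <- function(D, groups, n_perm = 1000, seed = 1,
                                 plus_one = TRUE) {
  if (n_perm < 1) config_error("n_perm must be >= 1")
  obs <- amova_phist(D, groups)
  d2 <- D$d[match(obs$ids, D$ids), match(obs$ids, D$ids), drop = FALSE]^2
  lab <- obs$labels
  set.seed(seed)
  null_phi <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    null_phi[b] <- phist_stat(d2, sample(lab))$phi
  }
  exceed <- sum(null_phi >= obs$phi, na.rm = TRUE)
  obs$p_value <- if (plus_one) (exceed + 1) / (n_perm + 1) else exceed / n_perm
  obs$n_perm <- n_perm
  obs$seed <- seed
  obs$null_summary <- summary(null_phi)
  obs
}

#' Pooled between- and within-clade mean distances
#'
#' `D_bc` is the mean p-distance over all sequence pairs belonging to
#' different clades, `D_wc` the mean over all pairs within the same clade
#' (pooled over clades). Clades with a single member contribute no within
#' pair and so are automatically excluded from `D_wc` while still entering
#' `D_bc`. With fewer than two clades `D_bc` is undefined (`NA`); with no
#' within pair `D_wc` is undefined (`NA`).
#'
#' @param D a `pdist` object.
#' @param clades clade grouping (named vector, list, or `clade_map`).
#' @return list with `D_bc`, `D_wc`, `n_bc_pairs`, `n_wc_pairs`.
#' @export
bc_wc_statistics <- function(D, clades) {
  lab <- labels_for(clades, D$ids)
  keep <- !is.na(lab)
  d <- D$d[keep, keep, drop = FALSE]
  bcwc_from(d, lab[keep])
}

bcwc_from <- function(d, lab) {
  eq <- outer(lab, lab, "==")
  ok <- !is.na(eq)  # pairs where both sequences carry a clade label
  ut <- upper.tri(d)
  same <- ut & ok & eq
  diff <- ut & ok & !eq
  n_wc <- sum(same)
  n_bc <- sum(diff)
  list(D_bc = if (n_bc == 0) NA_real_ else mean(d[diff], na.rm = TRUE),
       D_wc = if (n_wc == 0) NA_real_ else mean(d[same], na.rm = TRUE),
       n_bc_pairs = n_bc, n_wc_pairs = n_wc)
}

# expand a row-level permutation that keeps rows of the same individual
# together: permute labels among individuals, then map back to rows
permute_labels <- function(lab, individuals = NULL) {
  if (is.null(individuals)) return(sample(lab))
  ind <- unique(individuals)
  ind_lab <- lab[match(ind, individuals)]
  new_ind_lab <- sample(ind_lab)
  new_ind_lab[match(individuals, ind)]
}

#' Permutation test of between- vs within-clade divergence
#'
#' Tests whether the pooled between-clade mean p-distance exceeds the pooled
#' within-clade mean: the statistic is `T = D_bc - D_wc`, and the null
#' distribution is built by randomly shuffling individuals among clades
#' (clade sizes held fixed). The one-sided p-value is
#' `(#{T_perm >= T_obs} + 1) / (n_perm + 1)`, so the smallest reportable p at
#' 1000 permutations is 0.001.
#'
#' For phased nuclear data where each individual contributes two sequence
#' rows, pass `individuals` so both rows travel together during permutation
#' (the individual, not the haplotype, is the exchangeable unit).
#'
#' @inheritParams bc_wc_statistics
#' @param n_perm number of permutations.
#' @param seed integer RNG seed.
#' @param individuals optional vector (aligned with the retained sequence
#'   rows, named by sequence id) giving the individual each row belongs to.
#' @param plus_one use the `(x+1)/(n+1)` convention (default).
#' @return object of class `perm_test` with observed `D_bc`, `D_wc`,
#'   `statistic`, `p_value`, `n_perm`, `seed` and a null summary.
#' @export
test_bc_vs_wc <- function(D, clades, n_perm = 1000, seed = 1,
                          individuals = NULL, plus_one = TRUE) {
  if (n_perm < 1) config_error("n_perm must be >= 1")
  lab <- labels_for(clades, D$ids)
  keep <- !is.na(lab)
  if (sum(keep) < 3) data_error("too few clade-assigned sequences")
  d <- D$d[keep, keep, drop = FALSE]
  lab <- lab[keep]
  if (length(unique(lab)) < 2) data_error("need >= 2 clades")
  if (!any(table(lab) >= 2)) data_error("no clade has >= 2 members (D_wc undefined)")
  ind <- NULL
  if (!is.null(individuals)) {
    ind <- if (!is.null(names(individuals))) individuals[D$ids[keep]] else individuals[keep]
  }
  obs <- bcwc_from(d, lab)
  t_obs <- obs$D_bc - obs$D_wc
  set.seed(seed)
  t_null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pl <- permute_labels(lab, ind)
    st <- bcwc_from(d, pl)
    t_null[b] <- st$D_bc - st$D_wc
  }
  exceed <- sum(t_null >= t_obs, na.rm = TRUE)
  structure(list(statistic = "D_bc - D_wc",
                 D_bc = obs$D_bc, D_wc = obs$D_wc, observed = t_obs,
                 p_value = if (plus_one) (exceed + 1) / (n_perm + 1) else exceed / n_perm,
                 n_perm = n_perm, seed = seed,
                 null_summary = stats::quantile(t_null, c(.025, .5, .975), na.rm = TRUE)),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> %s: observed %.4f (D_bc %.4f, D_wc %.4f)\n",
              x$statistic, x$observed, x$D_bc, x$D_wc))
  cat(sprintf("  p = %.4g over %d permutations (seed %s)\n",
              x$p_value, x$n_perm, x$seed))
  invisible(x)
}

#' Partition scheme for the origin tests
#'
#' Packages the maps the northern-origin tests need: sequence id to locality,
#' locality to clade, the northern locality set, the all-southern reference
#' set, and optional contiguous-southern blocks (each a named list with
#' `northern` and `southern` locality vectors, for comparisons restricted to
#' adjacent refugia).
#'
#' @param locality_of named vector: sequence id -> locality code.
#' @param clade_of_locality named vector: locality code -> clade id.
#' @param northern,southern locality-code vectors (must be disjoint).
#' @param contiguous named list of blocks `list(northern=, southern=)`; every
#'   contiguous southern set must be a subset of `southern`.
#' @param individuals optional named vector sequence id -> individual for
#'   phased data.
#' @return object of class `partition_scheme`.
#' @export
partition_scheme <- function(locality_of, clade_of_locality, northern, southern,
                             contiguous = list(), individuals = NULL) {
  if (length(intersect(northern, southern)) > 0) {
    metadata_error("northern and southern locality sets must be disjoint")
  }
  for (nm in names(contiguous)) {
    blk <- contiguous[[nm]]
    if (length(setdiff(blk$southern, southern)) > 0) {
      metadata_error(sprintf("contiguous block '%s' has southern localities outside the all-southern set", nm))
    }
  }
  structure(list(locality_of = locality_of,
                 clade_of_locality = clade_of_locality,
                 northern = northern, southern = southern,
                 contiguous = contiguous, individuals = individuals),
            class = "partition_scheme")
}

#' Default partition scheme from a sample table
#'
#' Builds the [partition_scheme] encoding the study design: northern and
#' southern locality lists from [default_regions()] (or the table's `region`
#' column) and the contiguous-southern comparisons — locality 1 against the
#' Iberian localities (2-16, 18); the localities west of the Alps (20-23,
#' 25-26) against peninsular Italy (27-34); the Slovenian localities (35-36)
#' against either peninsular Italy or the southern Balkans (40-46); and the
#' central-Balkan localities (37-39) against the southern Balkans.
#'
#' @param samples a sample table with clade assignments.
#' @return a `partition_scheme`.
#' @export
study_scheme <- function(samples) {
  loc_of <- stats::setNames(samples$locality_code, samples$specimen_id)
  cl <- samples[!is.na(samples$clade_id), ]
  clade_of_loc <- tapply(cl$clade_id, cl$locality_code, function(x) unique(x)[1])
  clade_of_loc <- stats::setNames(as.integer(clade_of_loc), names(clade_of_loc))
  northern <- sort(unique(samples$locality_code[samples$region == "northern"]))
  southern <- sort(unique(samples$locality_code[samples$region == "southern"]))
  contiguous <- list(
    pyrenees = list(northern = 1L, southern = c(2:16, 18L)),
    west_alps = list(northern = c(20:23, 25:26), southern = 27:34),
    east_alps_vs_italy = list(northern = 35:36, southern = 27:34),
    east_alps_vs_balkans = list(northern = 35:36, southern = 40:46),
    balkans = list(northern = 37:39, southern = 40:46))
  # restrict blocks to localities present in the data and drop empty ones
  contiguous <- lapply(contiguous, function(b)
    list(northern = intersect(b$northern, northern),
         southern = intersect(b$southern, southern)))
  contiguous <- Filter(function(b) length(b$northern) > 0 && length(b$southern) > 0,
                       contiguous)
  partition_scheme(loc_of, clade_of_loc, northern, southern, contiguous)
}

#' Origin test for one northern locality
#'
#' Tests whether the mean p-distance `D_i` between a northern locality and a
#' southern reference set sits at the between-clade or the within-clade level
#' of divergence. Individuals are shuffled among locality slots (locality
#' sizes fixed; clade labels follow localities through the scheme's
#' locality-to-clade map) and `D_i`, `D_bc`, `D_wc` are recomputed each
#' cycle. Two one-sided p-values result:
#' \itemize{
#' \item `p_bc`: proportion of permutations with `(D_bc - D_i)` at least the
#'   observed value — small when `D_i` is significantly *below* the
#'   between-clade level;
#' \item `p_wc`: proportion with `(D_i - D_wc)` at least the observed value —
#'   small when `D_i` is significantly *above* the within-clade level.
#' }
#' A locality whose divergence from the south is at the between-clade level
#' (`p_wc` significant, `p_bc` not) behaves as an independent lineage — the
#' in-situ refugium signature; a locality not significantly above the
#' within-clade level behaves as a recent colonist of southern origin.
#'
#' @param D a `pdist` object.
#' @param scheme a [partition_scheme].
#' @param northern_locality locality code of the northern locality tested.
#' @param southern_set locality codes of the southern reference set; default
#'   the scheme's full southern set.
#' @param n_perm,seed,plus_one as in [test_bc_vs_wc()].
#' @return object of class `origin_test` with observed `D_i`, `D_bc`,
#'   `D_wc`, the two p-values, and permutation metadata.
#' @export
northern_origin_test <- function(D, scheme, northern_locality,
                                 southern_set = scheme$southern,
                                 n_perm = 1000, seed = 1, plus_one = TRUE) {
  stopifnot(inherits(scheme, "partition_scheme"))
  if (n_perm < 1) config_error("n_perm must be >= 1")
  loc <- scheme$locality_of[D$ids]
  known <- !is.na(loc) & as.character(loc) %in% names(scheme$clade_of_locality)
  if (any(!known)) {
    loc <- loc[known]
  }
  ids <- D$ids[known]
  d <- D$d[known, known, drop = FALSE]
  is_north <- loc == northern_locality
  in_south <- loc %in% southern_set
  if (sum(is_north) < 1) data_error(sprintf("northern locality %s has no individuals", northern_locality))
  if (sum(in_south) < 2) data_error("southern reference set has fewer than 2 individuals")
  clade_of <- scheme$clade_of_locality
  lab <- as.character(clade_of[as.character(loc)])
  ind <- if (!is.null(scheme$individuals)) scheme$individuals[ids] else NULL

  observe <- function(loc_vec, lab_vec) {
    st <- bcwc_from(d, lab_vec)
    di <- mean_pairs(d, loc_vec == northern_locality, loc_vec %in% southern_set)
    c(D_i = di, D_bc = st$D_bc, D_wc = st$D_wc)
  }
  obs <- observe(loc, lab)
  obs_bc_minus_i <- obs["D_bc"] - obs["D_i"]
  obs_i_minus_wc <- obs["D_i"] - obs["D_wc"]

  set.seed(seed)
  loc_chr <- as.character(loc)
  exc_bc <- 0L; exc_wc <- 0L
  null_di <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pl <- permute_labels(loc_chr, ind)
    pstats <- observe(pl, as.character(clade_of[pl]))
    null_di[b] <- pstats["D_i"]
    if (!is.na(pstats["D_bc"] - pstats["D_i"]) &&
        pstats["D_bc"] - pstats["D_i"] >= obs_bc_minus_i) exc_bc <- exc_bc + 1L
    if (!is.na(pstats["D_i"] - pstats["D_wc"]) &&
        pstats["D_i"] - pstats["D_wc"] >= obs_i_minus_wc) exc_wc <- exc_wc + 1L
  }
  pv <- function(x) if (plus_one) (x + 1) / (n_perm + 1) else x / n_perm
  structure(list(northern_locality = northern_locality,
                 southern_set = southern_set,
                 D_i = unname(obs["D_i"]), D_bc = unname(obs["D_bc"]),
                 D_wc = unname(obs["D_wc"]),
                 p_bc = pv(exc_bc), p_wc = pv(exc_wc),
                 n_perm = n_perm, seed = seed,
                 n_north = sum(is_north), n_south = sum(in_south),
                 null_D_i = stats::quantile(null_di, c(.025, .5, .975), na.rm = TRUE)),
            class = "origin_test")
}

#' @export
print.origin_test <- function(x, ...) {
  cat(sprintf("<origin_test> locality %s vs %d southern localities\n",
              x$northern_locality, length(x$southern_set)))
  cat(sprintf("  D_i = %.4f (D_bc %.4f, D_wc %.4f)\n", x$D_i, x$D_bc, x$D_wc))
  cat(sprintf("  p_bc = %.4g, p_wc = %.4g (%d permutations)\n  -> %s\n",
              x$p_bc, x$p_wc, x$n_perm, classify_origin(x)))
  invisible(x)
}

#' Classify the outcome of an origin test
#'
#' `in_situ` when `D_i` is significantly above the within-clade level but
#' not significantly below the between-clade level (the locality diverges
#' like an independent clade); `recent_expansion` when `D_i` is not
#' significantly above the within-clade level (the locality looks like part
#' of a southern pool); `ambiguous` when both p-values are significant
#' (intermediate divergence).
#'
#' @param x an `origin_test`.
#' @param alpha significance level (default 0.05).
#' @return one of `"in_situ"`, `"recent_expansion"`, `"ambiguous"`.
#' @export
classify_origin <- function(x, alpha = 0.05) {
  if (x$p_wc > alpha) return("recent_expansion")
  if (x$p_bc > alpha) return("in_situ")
  "ambiguous"
}

#' Run the full battery of origin tests
#'
#' One test per (northern locality x reference set): every northern locality
#' with data is compared against the all-southern set, and additionally
#' against each contiguous-southern block it belongs to (localities in two
#' blocks are tested against both).
#'
#' @param D a `pdist` object.
#' @param scheme a [partition_scheme].
#' @param n_perm,seed passed to [northern_origin_test()]; each row draws a
#'   deterministic sub-seed so rows are independent of battery order.
#' @param alpha significance level for the classification column.
#' @return `data.frame` with columns `locality`, `comparison`, `n_north`,
#'   `D_i`, `D_bc`, `D_wc`, `p_bc`, `p_wc`, `classification`, `n_perm`,
#'   `seed`; the full `origin_test` objects are attached as the `tests`
#'   attribute.
#' @export
run_origin_battery <- function(D, scheme, n_perm = 1000, seed = 1, alpha = 0.05) {
  loc_present <- unique(scheme$locality_of[D$ids])
  norths <- intersect(scheme$northern, loc_present)
  if (length(norths) == 0) data_error("no northern locality has data")
  rows <- list(); tests <- list()
  for (nl in norths) {
    comps <- list(all_southern = scheme$southern)
    for (nm in names(scheme$contiguous)) {
      blk <- scheme$contiguous[[nm]]
      if (nl %in% blk$northern) comps[[nm]] <- blk$southern
    }
    for (cn in names(comps)) {
      sset <- intersect(comps[[cn]], loc_present)
      if (length(sset) == 0) next
      res <- northern_origin_test(D, scheme, nl, southern_set = sset,
                                  n_perm = n_perm,
                                  seed = substream_seed(seed, paste(nl, cn)))
      tests[[paste(nl, cn, sep = ":")]] <- res
      rows[[length(rows) + 1]] <- data.frame(
        locality = nl, comparison = cn, n_north = res$n_north,
        D_i = res$D_i, D_bc = res$D_bc, D_wc = res$D_wc,
        p_bc = res$p_bc, p_wc = res$p_wc,
        classification = classify_origin(res, alpha),
        n_perm = n_perm, seed = res$seed)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "tests") <- tests
  out
}
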