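# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (per-pair / per-column loops, full enumeration) so they
# share no code path with the implementation they check.

make_aln <- function(seqs, ids = NULL, locus = "test") {
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  locus_alignment(stats::setNames(seqs, ids), locus = locus)
}

# random alignment with optional missing data and ambiguity codes
random_aln <- function(n, L, seed, missing_rate = 0, ambig_rate = 0) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  if (missing_rate > 0) m[runif(n * L) < missing_rate] <- "N"
  if (ambig_rate > 0) {
    idx <- runif(n * L) < ambig_rate
    m[idx] <- sample(c("R", "Y", "-", "W"), sum(idx), replace = TRUE)
  }
  rownames(m) <- paste0("s", seq_len(n))
  locus_alignment(m, locus = "rand")
}

# oracle: per-pair p-distance by explicit site loop
oracle_pdist_pair <- function(a, b) {
  bases <- c("A", "C", "G", "T")
  mism <- 0L; valid <- 0L
  for (k in seq_along(a)) {
    if (a[k] %in% bases && b[k] %in% bases) {
      valid <- valid + 1L
      if (a[k] != b[k]) mism <- mism + 1L
    }
  }
  if (valid == 0) return(c(NA_real_, 0))
  c(mism / valid, valid)
}

oracle_distance_matrix <- function(aln) {
  n <- nrow(aln$seqs)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  v <- matrix(ncol(aln$seqs), n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      r <- oracle_pdist_pair(aln$seqs[i, ], aln$seqs[j, ])
      d[i, j] <- r[1]; v[i, j] <- r[2]
    }
  }
  list(d = d, valid = v)
}

oracle_segregating_sites <- function(aln) {
  bases <- c("A", "C", "G", "T")
  s <- 0L
  for (col in seq_len(ncol(aln$seqs))) {
    x <- aln$seqs[, col]
    x <- x[x %in% bases]
    if (length(unique(x)) >= 2) s <- s + 1L
  }
  s
}

oracle_pi <- function(aln) {
  n <- nrow(aln$seqs)
  acc <- c();
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    acc <- c(acc, oracle_pdist_pair(aln$seqs[i, ], aln$seqs[j, ])[1])
  }
  mean(acc, na.rm = TRUE)
}

# oracle: pooled between/within-clade means by explicit pair loop
oracle_bcwc <- function(d, lab) {
  n <- length(lab)
  bc <- c(); wc <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (is.na(lab[i]) || is.na(lab[j])) next
    if (lab[i] == lab[j]) wc <- c(wc, d[i, j]) else bc <- c(bc, d[i, j])
  }
  c(D_bc = if (length(bc)) mean(bc, na.rm = TRUE) else NA_real_,
    D_wc = if (length(wc)) mean(wc, na.rm = TRUE) else NA_real_)
}

# exact p-value of the D_bc - D_wc test by enumerating every distinct
# assignment of individuals to clade slots (multiset permutations)
exact_bcwc_p <- function(d, lab) {
  obs <- oracle_bcwc(d, lab)
  t_obs <- obs["D_bc"] - obs["D_wc"]
  n <- length(lab)
  perms <- all_label_permutations(lab)
  t_all <- apply(perms, 1, function(pl) {
    st <- oracle_bcwc(d, pl)
    st["D_bc"] - st["D_wc"]
  })
  mean(t_all >= t_obs)
}

# every distinct arrangement of a label multiset (rows of a matrix)
all_label_permutations <- function(lab) {
  n <- length(lab)
  out <- unique(t(apply(permutations_of(seq_len(n)), 1, function(ix) lab[ix])))
  out
}

permutations_of <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- permutations_of(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# exact Phi-ST permutation p-value by enumeration (small n only)
exact_phist_p <- function(d2, lab) {
  phi <- function(l) divpart:::phist_stat(d2, l)$phi
  obs <- phi(lab)
  perms <- all_label_permutations(lab)
  p_all <- apply(perms, 1, phi)
  mean(p_all >= obs)
}

# standard 4-clade structured config used across tests
structured_config <- function(seed, n = 6L, d = 0.03, theta = 0.005, L = 1284L) {
  sim_config(seed = seed, loci = c(mt = as.integer(L)),
             clades = data.frame(clade_id = 1:4, locality_code = 1:4, n = n),
             d = d, theta = theta)
}

northern_config <- function(seed, scenario, d = 0.03, theta = 0.005, L = 1284L) {
  sim_config(seed = seed, loci = c(mt = as.integer(L)),
             clades = data.frame(clade_id = c(1:4, 5L),
                                 locality_code = c(1:4, 99L), n = 6L),
             d = d, theta = theta, scenario = scenario, northern_locality = 99L,
             source_clade = if (scenario == "northern_recent_expansion") 1L else NULL)
}
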