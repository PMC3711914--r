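# Per-group diversity statistics (S, pi, h, Hd) and the resampling
# standardization that makes groups of unequal sample size comparable.

#' Number of segregating sites
#'
#' Counts alignment columns at which at least two distinct unambiguous bases
#' occur among the sequences resolved at that column.
#'
#' @param aln a [locus_alignment] with N >= 2.
#' @return integer count.
#' @export
segregating_sites <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (nrow(aln$seqs) < 2) data_error("S needs >= 2 sequences")
  code <- encode_bases(aln)
  seg <- apply(code, 2, function(col) {
    u <- unique(col[!is.na(col)])
    length(u) >= 2
  })
  sum(seg)
}

#' Nucleotide diversity (pi)
#'
#' Mean pairwise uncorrected p-distance (pairwise deletion) among the
#' sequences of a group, per site:
#' \deqn{\pi = \frac{2}{N(N-1)} \sum_{i<j} d_{ij}.}
#' Undefined pairs are excluded from the mean with a warning.
#'
#' @param aln a [locus_alignment] with N >= 2, or a `pdist` object.
#' @return per-site proportion.
#' @export
nucleotide_diversity <- function(aln) {
  D <- if (inherits(aln, "pdist")) aln else distance_matrix(aln)
  v <- D$d[upper.tri(D$d)]
  if (all(is.na(v))) return(NA_real_)
  if (anyNA(v)) warning("undefined pairs excluded from pi")
  mean(v, na.rm = TRUE)
}

#' Haplotype count and diversity
#'
#' Haplotypes are equivalence classes of exact sequence identity over the
#' columns fully resolved (unambiguous base) in every sequence of the group —
#' complete deletion within the group, which keeps the equivalence relation
#' well defined in the presence of missing data. Haplotype diversity uses the
#' small-sample correction
#' \deqn{Hd = \frac{N}{N-1}\left(1 - \sum_k p_k^2\right).}
#'
#' @param aln a [locus_alignment] with N >= 2.
#' @return list with `h` (count), `Hd` (in `[0,1]`), `assignment` (integer
#'   haplotype index named by sequence id), and `sites_used`. When every
#'   column carries missing data the result is flagged with `h = NA`.
#' @export
haplotypes <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  n <- nrow(aln$seqs)
  if (n < 2) data_error("haplotypes needs >= 2 sequences")
  code <- encode_bases(aln)
  complete <- colSums(is.na(code)) == 0
  if (!any(complete)) {
    return(list(h = NA_integer_, Hd = NA_real_, assignment = NULL, sites_used = 0L))
  }
  key <- apply(code[, complete, drop = FALSE], 1, paste, collapse = ",")
  assignment <- as.integer(factor(key, levels = unique(key)))
  names(assignment) <- aln$ids
  p <- table(assignment) / n
  Hd <- n / (n - 1) * (1 - sum(p^2))
  list(h = length(p), Hd = Hd, assignment = assignment,
       sites_used = as.integer(sum(complete)))
}

# raw summary for one group; sites_used = columns fully resolved in-group
diversity_raw <- function(aln) {
  hp <- haplotypes(aln)
  data.frame(N = nrow(aln$seqs),
             sites_used = hp$sites_used,
             S = segregating_sites(aln),
             h = as.numeric(hp$h),
             Hd = hp$Hd,
             pi = nucleotide_diversity(aln))
}

#' Sample-size-standardized diversity statistics
#'
#' Groups of unequal size are made comparable by rarefaction: with `s` the
#' smallest group size among the groups compared (sizes 0 and 1 ignored),
#' each group larger than `s` is summarised as the average of S, h, Hd and
#' pi over `n_resamples` random subsets of `s` sequences drawn without
#' replacement; groups of exactly `s` sequences keep their raw values.
#' Resampling is reproducible: each group's draws come from a substream
#' derived from `seed` and a hash of the group id, so adding or removing a
#' group leaves the other groups' draws unchanged.
#'
#' @param groups named list of [locus_alignment] objects (one per group).
#' @param n_resamples number of subsets per group (default 100).
#' @param seed integer seed for the resampling.
#' @param s resample size; defaults to the smallest group size >= 2.
#' @param replace draw subsets with replacement (bootstrap) instead of the
#'   default subsampling without replacement.
#' @param exhaustive average over *all* `choose(N, s)` subsets instead of
#'   random draws (small groups only); `n_resamples` and `seed` are ignored
#'   for groups handled exhaustively.
#' @return `data.frame` with one row per group: raw columns (`N`,
#'   `sites_used`, `S`, `h`, `Hd`, `pi`) plus standardized means (`S_std`,
#'   `h_std`, `Hd_std`, `pi_std`; `h_std` may be fractional), `s`,
#'   `n_resamples`, `seed`.
#' @export
standardized_diversity <- function(groups, n_resamples = 100, seed = 1,
                                   s = NULL, replace = FALSE,
                                   exhaustive = FALSE) {
  if (exhaustive && replace) config_error("exhaustive mode enumerates subsets without replacement")
  sizes <- vapply(groups, function(a) nrow(a$seqs), integer(1))
  usable <- sizes >= 2
  if (!any(usable)) data_error("no group has >= 2 sequences")
  if (is.null(s)) s <- min(sizes[usable])
  if (s < 2) config_error("resample size s must be >= 2")
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    gid <- names(groups)[g]
    aln <- groups[[g]]
    if (sizes[g] < 2) {
      row <- data.frame(N = sizes[g], sites_used = NA, S = NA, h = NA,
                        Hd = NA, pi = NA)
      row[c("S_std", "h_std", "Hd_std", "pi_std")] <- NA
    } else {
      row <- diversity_raw(aln)
      if (sizes[g] <= s && !replace) {
        row$S_std <- row$S; row$h_std <- row$h
        row$Hd_std <- row$Hd; row$pi_std <- row$pi
      } else {
        if (exhaustive) {
          subsets <- utils::combn(aln$ids, s, simplify = FALSE)
        } else {
          set.seed(substream_seed(seed, gid))
          subsets <- NULL
        }
        n_draws <- if (exhaustive) length(subsets) else n_resamples
        acc <- matrix(0, n_draws, 4)
        for (r in seq_len(n_draws)) {
          if (exhaustive) {
            sub <- subset_alignment(aln, ids = subsets[[r]])
          } else if (replace) {
            take <- sample(seq_len(nrow(aln$seqs)), s, replace = TRUE)
            mm <- aln$seqs[take, , drop = FALSE]
            rownames(mm) <- paste0("r", seq_len(s))
            sub <- locus_alignment(mm, locus = aln$locus)
          } else {
            sub <- subset_alignment(aln, ids = sample(aln$ids, s))
          }
          dr <- suppressWarnings(diversity_raw(sub))
          acc[r, ] <- c(dr$S, dr$h, dr$Hd, dr$pi)
        }
        mu <- colMeans(acc)
        row$S_std <- mu[1]; row$h_std <- mu[2]
        row$Hd_std <- mu[3]; row$pi_std <- mu[4]
      }
    }
    row$group <- gid
    out[[g]] <- row
  }
  res <- do.call(rbind, out)
  res$s <- s
  res$n_resamples <- n_resamples
  res$seed <- seed
  res[, c("group", setdiff(names(res), "group"))]
}

#' Diversity report across loci and groups
#'
#' Builds the standard two-rows-per-group report (raw and standardized) for
#' each locus: N, sites used, S, h, Hd and pi (also scaled by 10^3 as
#' `pi_e3`, the conventional reporting scale for intraspecific mtDNA). The
#' rarefaction size `s` is computed per locus across the groups compared.
#'
#' @param alignments named list of [locus_alignment] objects, one per locus.
#' @param grouping named character vector: sequence id -> group label, or a
#'   `clade_map` (groups are clades).
#' @param n_resamples,seed passed to [standardized_diversity()].
#' @return long-format `data.frame` with columns `locus`, `group`, `type`
#'   (`raw`/`standardized`), `N`, `s`, `sites_used`, `S`, `h`, `Hd`, `pi`,
#'   `pi_e3`. Undefined cells carry `NA` (rendered as `-` on output).
#' @export
diversity_report <- function(alignments, grouping, n_resamples = 100, seed = 1) {
  if (inherits(grouping, "clade_map")) {
    grouping <- stats::setNames(
      rep(names(grouping$members), lengths(grouping$members)),
      unlist(grouping$members))
  }
  rows <- list()
  for (locus in names(alignments)) {
    aln <- alignments[[locus]]
    ids <- intersect(names(grouping), aln$ids)
    groups <- split(ids, grouping[ids])
    groups <- groups[lengths(groups) > 0]
    alns <- lapply(groups, function(g)
      if (length(g) >= 1) subset_alignment(aln, ids = g))
    std <- suppressWarnings(
      standardized_diversity(alns, n_resamples = n_resamples, seed = seed))
    for (i in seq_len(nrow(std))) {
      raw <- data.frame(locus = locus, group = std$group[i], type = "raw",
                        N = std$N[i], s = std$s[i], sites_used = std$sites_used[i],
                        S = std$S[i], h = std$h[i], Hd = std$Hd[i], pi = std$pi[i])
      st <- raw
      st$type <- "standardized"
      st$S <- std$S_std[i]; st$h <- std$h_std[i]
      st$Hd <- std$Hd_std[i]; st$pi <- std$pi_std[i]
      rows[[length(rows) + 1]] <- raw
      rows[[length(rows) + 1]] <- st
    }
  }
  out <- do.call(rbind, rows)
  out$pi_e3 <- out$pi * 1e3
  out
}
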