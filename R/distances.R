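# Uncorrected p-distances with pairwise deletion. A site contributes to a
# pair only when both sequences carry an unambiguous base (A/C/G/T); gaps,
# N and IUPAC ambiguity codes are treated as unresolved and dropped per pair.

BASES <- c("A", "C", "G", "T")

# integer-coded alignment: 1..4 for A,C,G,T; NA for anything unresolved
encode_bases <- function(aln) {
  m <- matrix(match(aln$seqs, BASES), nrow = nrow(aln$seqs),
              dimnames = dimnames(aln$seqs))
  m
}

#' Uncorrected p-distance between two sequences
#'
#' Proportion of mismatching sites among the jointly resolved sites of two
#' equal-length sequences (pairwise deletion). When no site is jointly
#' resolved the distance is undefined and returned as `NA` with
#' `valid_sites = 0` (a flag, not an error).
#'
#' @param seq_a,seq_b sequences as single strings or character vectors of
#'   symbols; equal lengths required.
#' @return list with `distance` (proportion, `NA` if undefined) and
#'   `valid_sites` (integer count of jointly resolved sites).
#' @export
p_distance <- function(seq_a, seq_b) {
  a <- if (length(seq_a) == 1) strsplit(seq_a, "", fixed = TRUE)[[1]] else seq_a
  b <- if (length(seq_b) == 1) strsplit(seq_b, "", fixed = TRUE)[[1]] else seq_b
  if (length(a) != length(b)) alignment_error("sequences differ in length")
  ia <- match(toupper(a), BASES)
  ib <- match(toupper(b), BASES)
  ok <- !is.na(ia) & !is.na(ib)
  n <- sum(ok)
  if (n == 0) return(list(distance = NA_real_, valid_sites = 0L))
  list(distance = sum(ia[ok] != ib[ok]) / n, valid_sites = as.integer(n))
}

#' All-pairs p-distance matrix
#'
#' Computes the symmetric matrix of uncorrected p-distances with pairwise
#' deletion for an alignment, together with the per-pair counts of jointly
#' resolved sites. Pairs with no jointly resolved site are flagged in
#' `undefined_pairs` and carry `NA` distances.
#'
#' Mismatch counts are obtained by indicator-matrix products (one per base),
#' so the result is exact integer arithmetic, not a floating approximation.
#'
#' @param aln a [locus_alignment] with at least two sequences.
#' @return object of class `pdist` with fields `ids`, `d` (distance matrix),
#'   `valid_sites`, and `undefined_pairs` (two-column matrix of ids, possibly
#'   empty).
#' @export
distance_matrix <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (nrow(aln$seqs) < 2) data_error("distance matrix needs at least 2 sequences")
  code <- encode_bases(aln)
  resolved <- !is.na(code)
  storage.mode(resolved) <- "double"
  valid <- resolved %*% t(resolved)
  matches <- matrix(0, nrow(code), nrow(code))
  for (b in seq_along(BASES)) {
    ind <- (!is.na(code)) & code == b
    storage.mode(ind) <- "double"
    matches <- matches + ind %*% t(ind)
  }
  mism <- round(valid - matches)
  valid <- round(valid)
  d <- ifelse(valid > 0, mism / valid, NA_real_)
  diag(d) <- 0
  dimnames(d) <- list(aln$ids, aln$ids)
  dimnames(valid) <- dimnames(d)
  und <- which(upper.tri(valid) & valid == 0, arr.ind = TRUE)
  undefined_pairs <- cbind(aln$ids[und[, 1]], aln$ids[und[, 2]])
  if (nrow(undefined_pairs) > 0) {
    warning(sprintf("%d sequence pair(s) share no resolved site; their distances are undefined",
                    nrow(undefined_pairs)))
  }
  structure(list(ids = aln$ids, d = d, valid_sites = matrix(as.integer(valid),
                 nrow(valid), dimnames = dimnames(valid)),
                 undefined_pairs = undefined_pairs),
            class = "pdist")
}

#' @export
print.pdist <- function(x, ...) {
  cat(sprintf("<pdist> %d sequences; mean defined distance %.4f; %d undefined pair(s)\n",
              length(x$ids), mean(x$d[upper.tri(x$d)], na.rm = TRUE),
              nrow(x$undefined_pairs)))
  invisible(x)
}

# mean over defined distances of a set of index pairs; NA if none defined
mean_pairs <- function(d, rows, cols) {
  v <- d[rows, cols, drop = FALSE]
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Mean p-distance between (or within) groups
#'
#' Arithmetic mean of pairwise distances over all cross pairs of two disjoint
#' groups, or over all within pairs (`i < j`) when the same group is given
#' twice. Undefined pairs are excluded from the mean with a warning.
#'
#' @param D a `pdist` object.
#' @param group_a,group_b character vectors of sequence ids.
#' @return mean distance (proportion), `NA` if no pair is defined.
#' @export
group_mean_distance <- function(D, group_a, group_b = group_a) {
  stopifnot(inherits(D, "pdist"))
  miss <- setdiff(c(group_a, group_b), D$ids)
  if (length(miss) > 0) key_error(sprintf("ids not in distance matrix: %s", paste(miss, collapse = ", ")))
  within <- identical(sort(group_a), sort(group_b))
  if (within) {
    if (length(group_a) < 2) data_error("within-group mean needs >= 2 members")
    sub <- D$d[group_a, group_a, drop = FALSE]
    v <- sub[upper.tri(sub)]
  } else {
    if (length(intersect(group_a, group_b)) > 0) data_error("groups must be disjoint")
    if (length(group_a) == 0 || length(group_b) == 0) data_error("empty group")
    v <- as.vector(D$d[group_a, group_b, drop = FALSE])
  }
  if (anyNA(v)) {
    if (all(is.na(v))) return(NA_real_)
    warning("undefined pairs excluded from group mean")
  }
  mean(v, na.rm = TRUE)
}

#' Between-clade mean distance table
#'
#' Matrix of mean between-clade p-distances (within-clade means on the
#' diagonal where a clade has two or more members), plus the unweighted
#' summary over clade pairs — the convention used by MEGA's between-group
#' mean distances. Note this differs from the pooled individual-pair mean
#' used by [bc_wc_statistics()]; both are exposed.
#'
#' @param D a `pdist` object.
#' @param clades a `clade_map`, or a named list clade -> member ids.
#' @return list of class `clade_distances`: `between` (K x K matrix),
#'   `mean`, `min`, `max` over off-diagonal clade pairs.
#' @export
clade_distance_table <- function(D, clades) {
  members <- clade_members(clades, D$ids)
  k <- length(members)
  if (k < 2) data_error("need at least 2 clades")
  nm <- names(members)
  between <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    if (length(members[[i]]) >= 2) {
      between[i, i] <- group_mean_distance(D, members[[i]])
    }
    if (i < k) for (j in (i + 1):k) {
      between[i, j] <- between[j, i] <-
        group_mean_distance(D, members[[i]], members[[j]])
    }
  }
  off <- between[upper.tri(between)]
  structure(list(between = between,
                 mean = mean(off, na.rm = TRUE),
                 min = min(off, na.rm = TRUE),
                 max = max(off, na.rm = TRUE)),
            class = "clade_distances")
}

#' @export
print.clade_distances <- function(x, ...) {
  cat(sprintf("<clade_distances> %d clades; between-clade mean %.4f (range %.4f-%.4f)\n",
              nrow(x$between), x$mean, x$min, x$max))
  invisible(x)
}

#' Check clade divergence against the delimitation threshold
#'
#' For each clade, the mean p-distance to its nearest other clade and whether
#' that distance exceeds the delimitation threshold (clades are expected to
#' be more than 1% divergent from their closest relative).
#'
#' @param D a `pdist` object.
#' @param clades a `clade_map` or named list clade -> member ids.
#' @param threshold divergence threshold as a proportion (default 0.01).
#' @return `data.frame` with columns `clade`, `nearest_clade`, `distance`,
#'   `passes`.
#' @export
validate_clade_divergence <- function(D, clades, threshold = 0.01) {
  tab <- clade_distance_table(D, clades)$between
  diag(tab) <- NA
  nm <- rownames(tab)
  nearest <- apply(tab, 1, function(r) if (all(is.na(r))) NA_integer_ else which.min(r))
  dist <- vapply(seq_along(nm), function(i)
    if (is.na(nearest[i])) NA_real_ else tab[i, nearest[i]], numeric(1))
  data.frame(clade = nm,
             nearest_clade = nm[nearest],
             distance = dist,
             passes = !is.na(dist) & dist > threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

# normalise clade input to a named list of member ids present in `ids`
clade_members <- function(clades, ids) {
  members <- if (inherits(clades, "clade_map")) clades$members else clades
  if (is.factor(clades) || (is.atomic(clades) && !is.null(names(clades)))) {
    members <- split(names(clades), as.character(clades))
  }
  members <- lapply(members, function(m) intersect(m, ids))
  members <- members[vapply(members, length, integer(1)) > 0]
  if (length(members) == 0) data_error("no clade members present in distance matrix")
  members
}

#' Write / read a distance matrix
#'
#' PHYLIP square-matrix format (`write_pdist_phylip`) or long-format TSV with
#' columns `id_a`, `id_b`, `distance`, `valid_sites` (`write_pdist_tsv`).
#'
#' @param D a `pdist` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdist_phylip <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(D$ids)), con)
  for (i in seq_along(D$ids)) {
    writeLines(paste(c(format(D$ids[i], width = 10),
                       sprintf("%.6f", D$d[i, ])), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_pdist_phylip
#' @export
write_pdist_tsv <- function(D, path) {
  idx <- which(upper.tri(D$d), arr.ind = TRUE)
  df <- data.frame(id_a = D$ids[idx[, 1]], id_b = D$ids[idx[, 2]],
                   distance = D$d[idx], valid_sites = D$valid_sites[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
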