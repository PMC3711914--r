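#' Aligned sequences for one locus
#'
#' A `locus_alignment` holds equal-length nucleotide sequences keyed by a
#' unique sequence identifier. Symbols are upper-case IUPAC nucleotide codes
#' (including ambiguity codes and `N`) or the gap character `-`; `U` is mapped
#' to `T` on construction. Internally the alignment is a character matrix with
#' one row per sequence and one column per site, which makes column-wise
#' operations (segregating sites, haplotype collapsing) direct.
#'
#' @param seqs named character vector of sequence strings, or a character
#'   matrix of single symbols with row names.
#' @param locus locus name carried along for reporting.
#' @return an object of class `locus_alignment`.
#' @export
locus_alignment <- function(seqs, locus = "locus") {
  if (is.matrix(seqs)) {
    m <- seqs
    if (is.null(rownames(m))) metadata_error("alignment matrix must have row names (sequence ids)")
  } else {
    if (is.null(names(seqs))) metadata_error("sequences must be named")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1) {
      alignment_error(sprintf(
        "ragged alignment: sequence lengths %s", paste(sort(unique(lens)), collapse = "/")))
    }
    if (length(seqs) == 0 || lens[1] == 0) alignment_error("empty alignment")
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(m) <- names(seqs)
  }
  ids <- rownames(m)
  if (anyDuplicated(ids)) {
    metadata_error(sprintf("duplicate sequence id: %s",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- toupper(m)
  m[m == "U"] <- "T"
  bad <- matrix(!(m %in% IUPAC_SYMBOLS), nrow(m))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    parse_error(sprintf("illegal symbol '%s' in sequence '%s' at column %d",
                        m[idx[1], idx[2]], ids[idx[1]], idx[2]))
  }
  structure(list(locus = locus, ids = ids, seqs = m, length = ncol(m)),
            class = "locus_alignment")
}

IUPAC_SYMBOLS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N", "-")

#' Read a FASTA alignment
#'
#' Reads one locus from a FASTA file and validates it as an alignment: all
#' records must have the same length, ids (the header token up to the first
#' whitespace) must be unique, and every symbol must be a valid IUPAC
#' nucleotide code, `N`, or `-`. Parsing is case-insensitive and `U` is read
#' as `T`.
#'
#' @param path path to a FASTA file.
#' @param locus_name name recorded on the returned alignment.
#' @return a [locus_alignment].
#' @export
read_fasta <- function(path, locus_name = basename(path)) {
  if (!file.exists(path)) parse_error(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) alignment_error(sprintf("no FASTA records in %s", path))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  names(seqs) <- ids
  locus_alignment(seqs, locus = locus_name)
}

#' Write an alignment to FASTA
#'
#' @param aln a [locus_alignment].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "locus_alignment"))
  seqs <- apply(aln$seqs, 1, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s: %d sequences x %d bp\n",
              x$locus, length(x$ids), x$length))
  invisible(x)
}

#' @export
dim.locus_alignment <- function(x) dim(x$seqs)

#' @export
as.matrix.locus_alignment <- function(x, ...) x$seqs

#' Concatenate loci over the shared specimens
#'
#' Builds a combined alignment from several per-locus alignments using
#' intersection semantics: only specimens present in every input locus are
#' kept (no padding with missing data). Per-locus column ranges are recorded
#' as 0-based half-open intervals in the `ranges` attribute.
#'
#' @param alignments list of [locus_alignment] objects sharing an id namespace.
#' @param locus name for the combined alignment.
#' @return a [locus_alignment] with `length` equal to the summed input lengths.
#' @export
concat_loci <- function(alignments, locus = "combined") {
  if (length(alignments) < 2) data_error("concat_loci needs at least two alignments")
  ids <- Reduce(intersect, lapply(alignments, function(a) a$ids))
  if (length(ids) == 0) data_error("no specimen is present in all loci")
  mats <- lapply(alignments, function(a) a$seqs[ids, , drop = FALSE])
  out <- locus_alignment(do.call(cbind, mats), locus = locus)
  lens <- vapply(alignments, function(a) a$length, integer(1))
  ends <- cumsum(lens)
  ranges <- data.frame(
    locus = vapply(alignments, function(a) a$locus, character(1)),
    start = c(0L, ends[-length(ends)]), end = ends)
  attr(out, "ranges") <- ranges
  out
}

#' Row-subset an alignment
#'
#' Selects sequences by id, by locality, or by clade (the latter two require
#' a sample table). Column count is unchanged.
#'
#' @param aln a [locus_alignment].
#' @param ids sequence ids to keep.
#' @param localities,clades locality codes / clade ids to keep; resolved to
#'   specimen ids through `samples`.
#' @param samples a sample table as returned by [load_sample_table()].
#' @return a [locus_alignment].
#' @export
subset_alignment <- function(aln, ids = NULL, localities = NULL, clades = NULL,
                             samples = NULL) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (is.null(ids)) {
    if (is.null(samples)) key_error("subsetting by locality/clade needs a sample table")
    keep <- rep(FALSE, nrow(samples))
    if (!is.null(localities)) keep <- keep | samples$locality_code %in% localities
    if (!is.null(clades)) keep <- keep | (!is.na(samples$clade_id) & samples$clade_id %in% clades)
    ids <- intersect(samples$specimen_id[keep], aln$ids)
  } else {
    missing_ids <- setdiff(ids, aln$ids)
    if (length(missing_ids) > 0) {
      key_error(sprintf("unknown sequence id(s): %s", paste(missing_ids, collapse = ", ")))
    }
  }
  if (length(ids) == 0) data_error("subset selects no sequences")
  locus_alignment(aln$seqs[ids, , drop = FALSE], locus = aln$locus)
}

#' Default northern/southern locality classification
#'
#' The default regional partition used by the origin tests: localities north
#' or east of the major biogeographic barriers separating central Europe from
#' the Mediterranean refugial peninsulas are "northern"; localities within the
#' Iberian, Italian and Balkan peninsulas are "southern"; every other locality
#' code is unassigned and excluded from origin tests. Shipped as data so a
#' different classification can be supplied.
#'
#' @return list with integer vectors `northern` and `southern`.
#' @export
default_regions <- function() {
  list(northern = c(1L, 20:23, 25:26, 35:36, 37:39),
       southern = c(2:16, 18L, 27:34, 40:46))
}

#' Load a sample metadata table
#'
#' Reads a tab-separated table with columns `specimen_id`, `locality_code`,
#' `locality_name`, `lat`, `lon`, `clade_id` (empty or `-` for unassigned)
#' and optionally one column per locus holding an accession or `-` when the
#' specimen lacks that fragment. A `region` column is accepted; when absent,
#' regions are assigned from `regions` (northern / southern / unassigned).
#'
#' @param path path to the TSV file.
#' @param regions list with `northern` and `southern` locality-code vectors;
#'   defaults to [default_regions()].
#' @param locus_columns names of per-locus presence columns; by default every
#'   column not otherwise recognised.
#' @return a `data.frame` of class `sample_table`.
#' @export
load_sample_table <- function(path, regions = default_regions(),
                              locus_columns = NULL) {
  if (!file.exists(path)) parse_error(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  required <- c("specimen_id", "locality_code")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) metadata_error(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  if (nrow(df) == 0) {
    df$region <- character(0)
    class(df) <- c("sample_table", class(df))
    return(df)
  }
  if (anyDuplicated(df$specimen_id)) {
    metadata_error(sprintf("duplicate specimen_id: %s",
                           paste(unique(df$specimen_id[duplicated(df$specimen_id)]), collapse = ", ")))
  }
  df$locality_code <- as.integer(df$locality_code)
  if (!"clade_id" %in% names(df)) df$clade_id <- NA_integer_
  df$clade_id[df$clade_id %in% "-"] <- NA
  df$clade_id <- suppressWarnings(as.integer(df$clade_id))
  # every locality must map to exactly one clade
  by_loc <- split(df$clade_id, df$locality_code)
  conflict <- names(by_loc)[vapply(by_loc, function(x) length(unique(x[!is.na(x)])) > 1, logical(1))]
  if (length(conflict) > 0) {
    metadata_error(sprintf("locality assigned to more than one clade: %s",
                           paste(conflict, collapse = ", ")))
  }
  if (!"region" %in% names(df)) {
    df$region <- ifelse(df$locality_code %in% regions$northern, "northern",
                 ifelse(df$locality_code %in% regions$southern, "southern", "unassigned"))
  }
  bad_region <- setdiff(unique(df$region), c("northern", "southern", "unassigned"))
  if (length(bad_region) > 0) metadata_error(sprintf("unknown region label: %s", paste(bad_region, collapse = ", ")))
  reg_by_loc <- split(df$region, df$locality_code)
  if (any(vapply(reg_by_loc, function(x) length(unique(x)) > 1, logical(1)))) {
    metadata_error("a locality carries more than one region label")
  }
  known <- c("specimen_id", "locality_code", "locality_name", "lat", "lon",
             "clade_id", "region")
  if (is.null(locus_columns)) locus_columns <- setdiff(names(df), known)
  attr(df, "loci") <- locus_columns
  class(df) <- c("sample_table", class(df))
  df
}

#' Ids of specimens carrying a given locus
#'
#' @param samples a sample table.
#' @param locus name of a per-locus presence column.
#' @return character vector of specimen ids.
#' @export
specimens_with_locus <- function(samples, locus) {
  if (!locus %in% names(samples)) key_error(sprintf("no locus column '%s'", locus))
  v <- samples[[locus]]
  samples$specimen_id[!is.na(v) & v != "-"]
}

#' Clade membership map
#'
#' Builds the clade structure from a sample table: which localities belong to
#' each clade and which specimens are members. Clades with fewer than two
#' members are flagged (they are excluded from variance-partition analyses).
#'
#' @param samples a sample table.
#' @param ids restrict membership to these sequence ids (e.g. the rows of one
#'   locus alignment); default all specimens.
#' @return list of class `clade_map` with `localities`, `members`, and
#'   `too_small` (logical per clade).
#' @export
clade_map <- function(samples, ids = NULL) {
  df <- samples[!is.na(samples$clade_id), , drop = FALSE]
  if (!is.null(ids)) df <- df[df$specimen_id %in% ids, , drop = FALSE]
  if (nrow(df) == 0) data_error("no clade-assigned specimens")
  members <- split(df$specimen_id, df$clade_id)
  localities <- lapply(split(df$locality_code, df$clade_id), function(x) sort(unique(x)))
  structure(list(localities = localities, members = members,
                 too_small = vapply(members, length, integer(1)) < 2),
            class = "clade_map")
}
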