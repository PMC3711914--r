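# End-to-end pipeline driver: reads a YAML configuration (input files or a
# simulation block), runs the requested stages in dependency order, writes
# TSV reports, and records a manifest sufficient to reproduce every output.

#' Run the analysis pipeline
#'
#' Stages (run in dependency order, subset selectable via the config's
#' `stages` field): `simulate` or input loading, `diversity`, `distances`,
#' `fst`, `permtest` (between- vs within-clade), and `origin` (the northern
#' locality battery). Every output TSV is accompanied by `manifest.json`
#' recording the config hash, input digests, seeds and package version.
#'
#' Configuration fields: either `simulate:` (arguments of [sim_config()])
#' or `inputs:` with `fasta:` (named locus -> path) and `samples:` (TSV
#' path); optional `concat: true` to analyse the concatenated loci;
#' `seed`, `n_perm`, `n_resamples`; `stages` (default all applicable).
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results (`samples`,
#'   `alignments`, `distance`, `diversity`, `fst`, `permtest`, `origin`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    if (!file.exists(config)) config_error(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  n_perm <- as.integer(config$n_perm %||% 1000L)
  n_resamples <- as.integer(config$n_resamples %||% 100L)
  inputs <- character(0)

  stage <- function(name, expr) {
    tryCatch(expr, divpart_error = function(e) {
      dp_abort(class(e)[1], sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- as.integer(sim_args$seed %||% seed)
    if (!is.null(sim_args$clades)) {
      cl <- sim_args$clades
      # YAML 1.1 reads a bare `n:` key as boolean FALSE; map it back
      names(cl)[names(cl) %in% c("FALSE", "F")] <- "n"
      sim_args$clades <- as.data.frame(cl)
    }
    if (!is.null(sim_args$loci)) sim_args$loci <- unlist(sim_args$loci)
    ds <- stage("simulate", do.call(sim_config, sim_args))
    ds <- stage("simulate", simulate_dataset(ds))
    alignments <- ds$alignments
    samples <- ds$samples
    scheme <- stage("simulate", sim_scheme(ds))
  } else if (!is.null(config$inputs)) {
    fasta <- config$inputs$fasta
    if (is.null(fasta) || is.null(config$inputs$samples)) {
      config_error("[stage load] inputs need 'fasta' (named locus -> path) and 'samples'")
    }
    inputs <- c(unlist(fasta), config$inputs$samples)
    missing_in <- inputs[!file.exists(inputs)]
    if (length(missing_in) > 0) {
      config_error(sprintf("[stage load] missing input file(s): %s",
                           paste(missing_in, collapse = ", ")))
    }
    alignments <- stage("load", mapply(read_fasta, unlist(fasta), names(fasta),
                                       SIMPLIFY = FALSE))
    samples <- stage("load", load_sample_table(config$inputs$samples))
    scheme <- stage("load", study_scheme(samples))
  } else {
    config_error("[stage load] config needs either a 'simulate' or an 'inputs' block")
  }

  if (isTRUE(config$concat) && length(alignments) > 1) {
    alignments$combined <- stage("load", concat_loci(alignments))
  }
  stages <- config$stages %||% c("diversity", "distances", "fst", "permtest", "origin")
  results <- list(samples = samples, alignments = alignments, scheme = scheme)

  grouping <- stats::setNames(samples$clade_id, samples$specimen_id)
  grouping <- grouping[!is.na(grouping)]

  primary <- alignments[[if ("combined" %in% names(alignments)) "combined"
                         else names(alignments)[1]]]
  D <- stage("distances", suppressWarnings(distance_matrix(primary)))
  results$distance <- D

  if ("distances" %in% stages) {
    stage("distances", {
      write_pdist_tsv(D, file.path(out_dir, "distances.tsv"))
      cm <- clade_map(samples, ids = primary$ids)
      ct <- suppressWarnings(clade_distance_table(D, cm))
      utils::write.table(
        data.frame(clade = rownames(ct$between), ct$between, check.names = FALSE),
        file.path(out_dir, "clade_distances.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      results$clade_distances <- ct
    })
  }
  if ("diversity" %in% stages) {
    stage("diversity", {
      rep <- diversity_report(alignments, grouping,
                              n_resamples = n_resamples, seed = seed)
      render_table2(rep, file.path(out_dir, "diversity.tsv"))
      results$diversity <- rep
    })
  }
  if ("fst" %in% stages) {
    stage("fst", {
      results$fst <- suppressWarnings(
        fst_permutation_test(D, grouping, n_perm = n_perm, seed = seed))
    })
  }
  if ("permtest" %in% stages) {
    stage("permtest", {
      results$permtest <- test_bc_vs_wc(D, grouping, n_perm = n_perm, seed = seed)
    })
  }
  if ("origin" %in% stages && length(intersect(scheme$northern,
                                               scheme$locality_of[primary$ids])) > 0) {
    stage("origin", {
      bat <- run_origin_battery(D, scheme, n_perm = n_perm, seed = seed)
      utils::write.table(bat, file.path(out_dir, "origin_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$origin <- bat
    })
  }

  manifest <- list(
    command = "run_pipeline",
    package_version = as.character(utils::packageVersion("divpart")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, n_perm = n_perm, n_resamples = n_resamples,
    config_hash = manifest_hash(config),
    config_file = cfg_path,
    input_digests = if (length(inputs)) as.list(tools::md5sum(inputs)) else list(),
    stages = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

manifest_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Render a diversity report as a summary-table TSV
#'
#' Writes the long-format output of [diversity_report()] in the
#' two-rows-per-group layout (raw then standardized) with columns `locus`,
#' `group`, `type`, `N`, `s`, `sites_used`, `S`, `h`, `Hd`, `pi_e3`.
#' Undefined cells are rendered as `-`.
#'
#' @param report output of [diversity_report()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
render_table2 <- function(report, path) {
  cols <- c("locus", "group", "type", "N", "s", "sites_used", "S", "h", "Hd", "pi_e3")
  miss <- setdiff(cols, names(report))
  if (length(miss) > 0) config_error(sprintf("report lacks column(s): %s",
                                             paste(miss, collapse = ", ")))
  out <- report[, cols]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) ifelse(is.na(x), "-", format(round(x, 3))))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
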