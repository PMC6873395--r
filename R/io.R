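## Readers and writers: count tables (TSV/CSV), parameter sets (JSON),
## simulation outputs and evaluation reports.

sep_for_path <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a grouped count table from disk
#'
#' The count file is TSV (or CSV by extension): features on rows, samples
#' on columns, first column feature ids, header row sample ids.  The
#' metadata file must have columns `sample_id` and `group`.  Every sample
#' in the count table must appear in the metadata; non-integer, negative
#' or missing cells and duplicate ids are rejected with the offending
#' coordinates in the message.
#'
#' @param path count table file.
#' @param metadata_path sample metadata file.
#' @return a [grouped_count_table()].
#' @export
read_count_table <- function(path, metadata_path) {
  for (p in c(path, metadata_path)) {
    if (!file.exists(p)) abort_data("file not found: ", p)
  }
  raw <- read.table(path, header = TRUE, sep = sep_for_path(path),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "\"")
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    abort_data("count table '", path, "' is empty or has no sample columns")
  }
  feature_ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(mat, 2, as.numeric))),
                 arr.ind = TRUE)
    coord <- if (nrow(bad) > 0) {
      sprintf(" (first at feature '%s', sample '%s')",
              feature_ids[bad[1, 1]], colnames(mat)[bad[1, 2]])
    } else ""
    abort_data("count table '", path, "' has non-numeric cells", coord)
  }
  bad <- which(!is_wholenumber(mat) | mat < 0 | is.na(mat), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort_data(sprintf(
      "count table '%s': invalid count %s at feature '%s', sample '%s' (counts must be non-negative integers)",
      path, format(mat[bad[1, 1], bad[1, 2]]),
      feature_ids[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  }
  rownames(mat) <- feature_ids

  meta <- read.table(metadata_path, header = TRUE,
                     sep = sep_for_path(metadata_path),
                     check.names = FALSE, stringsAsFactors = FALSE,
                     comment.char = "", quote = "\"")
  if (!all(c("sample_id", "group") %in% colnames(meta))) {
    abort_data("metadata '", metadata_path,
               "' must have columns 'sample_id' and 'group'")
  }
  if (anyDuplicated(meta$sample_id)) {
    abort_data("metadata '", metadata_path, "' has duplicate sample ids")
  }
  missing_meta <- setdiff(colnames(mat), meta$sample_id)
  if (length(missing_meta) > 0L) {
    abort_data("samples missing from metadata: ",
               paste(missing_meta, collapse = ", "))
  }
  group_of <- stats::setNames(as.character(meta$group), meta$sample_id)
  grouped_count_table(mat, group_of[colnames(mat)])
}

write_matrix_tsv <- function(mat, path, id_column = "feature_id",
                             digits = NULL) {
  vals <- if (is.null(digits)) {
    format(mat, trim = TRUE, scientific = FALSE)
  } else {
    formatC(mat, digits = digits, format = "g")
  }
  df <- data.frame(rownames(mat), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(mat))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a parameter set to a versioned JSON file
#'
#' @param params a [sim_params()] object.
#' @param path output file.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  obj <- list(schema = "mhgsim/sim_params/1",
              feature_ids = params$feature_ids,
              groups = params$groups)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a parameter set written by [write_params()]
#'
#' @param path JSON file.
#' @return a [sim_params()] object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) abort_data("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || !startsWith(obj$schema, "mhgsim/sim_params/")) {
    abort_data("'", path, "' is not a mhgsim parameter file")
  }
  groups <- lapply(obj$groups, function(g) {
    list(mu = as.numeric(g$mu), phi = as.numeric(g$phi),
         lib_sizes = as.numeric(g$lib_sizes))
  })
  sim_params(obj$feature_ids, groups)
}

#' Write simulation outputs to a directory
#'
#' Writes `counts.tsv` (the simulated count table), `relative_abundances.tsv`
#' (the gamma-step ground-truth composition of every sample, before
#' sequencing), `params.json` (the parameters used) and `manifest.json`
#' (seed, population scale, package version, timestamp, sample-to-group
#' map) so the run is fully reproducible from its own output.
#'
#' @param result a `sim_result` from [simulate_counts()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_simulation <- function(result, outdir) {
  stopifnot(inherits(result, "sim_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) abort_data("cannot create directory: ", outdir)
  paths <- c(
    counts = file.path(outdir, "counts.tsv"),
    rel = file.path(outdir, "relative_abundances.tsv"),
    params = file.path(outdir, "params.json"),
    manifest = file.path(outdir, "manifest.json"))
  write_matrix_tsv(result$counts, paths["counts"])
  write_matrix_tsv(result$rel_abundance, paths["rel"], digits = 15)
  write_params(result$params_used, paths["params"])
  manifest <- list(
    tool = "mhgsim",
    version = as.character(packageVersion("mhgsim")),
    seed = result$seed,
    population_scale = result$population_scale,
    n_features = nrow(result$counts),
    n_samples = ncol(result$counts),
    group_of = as.list(result$group_of),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE)
  ## metadata TSV so the simulated table round-trips through
  ## read_count_table directly
  meta <- data.frame(sample_id = names(result$group_of),
                     group = unname(result$group_of))
  meta_path <- file.path(outdir, "metadata.tsv")
  write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, metadata = meta_path))
}

#' Write an evaluation report as tidy TSV tables
#'
#' Writes `report_tests.tsv` (one row per group x metric with p-value,
#' effect size and bootstrap significant fraction), `report_sparsity.tsv`
#' (total and per-group sparsity of both tables) and `report_rsquared.tsv`.
#'
#' @param report an `eval_report` from [compare_tables()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_eval_report <- function(report, outdir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(tests = file.path(outdir, "report_tests.tsv"),
             sparsity = file.path(outdir, "report_sparsity.tsv"),
             rsquared = file.path(outdir, "report_rsquared.tsv"))
  write.table(report$tests, paths["tests"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  groups <- names(report$sparsity$real$per_group)
  sp <- data.frame(
    scope = c("total", groups),
    real_sparsity_pct = c(report$sparsity$real$total,
                          unname(report$sparsity$real$per_group)),
    sim_sparsity_pct = c(report$sparsity$sim$total,
                         unname(report$sparsity$sim$per_group[groups])))
  write.table(sp, paths["sparsity"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  r2 <- data.frame(comparison = names(report$r_squared),
                   r_squared = unlist(report$r_squared, use.names = FALSE))
  write.table(r2, paths["rsquared"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
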