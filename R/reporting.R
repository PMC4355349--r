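#' Collapse duplicate probe sequences
#'
#' Exact duplicate sequences are collapsed to their first occurrence (stable
#' order); the survivor's `clusters` column records the sorted unique cluster
#' ids of every collapsed copy so no target group silently loses its probe.
#'
#' @param probes Probe data frame (as produced by the design stages).
#' @return The deduplicated probe data frame with an added `clusters` column.
#' @export
nonredundant <- function(probes) {
  if (nrow(probes) == 0L) {
    probes$clusters <- character(0)
    return(probes)
  }
  first <- !duplicated(probes$seq)
  cl_by_seq <- vapply(split(probes$cluster_id, probes$seq), function(x)
    paste(sort(unique(x)), collapse = ","), character(1))
  out <- probes[first, , drop = FALSE]
  out$clusters <- unname(cl_by_seq[out$seq])
  rownames(out) <- NULL
  out
}

#' Summarize a probe-design stage
#'
#' @param stage `"run1"` (primary design only) or `"run2"` (after rescue).
#' @param clusters A `capture_clusters` object (for the cluster universe).
#' @param probes Probe data frame for the stage; every `cluster_id` must
#'   refer to an existing cluster.
#' @param rejections Optional named integer vector of filter-rejection
#'   counts (reason -> count).
#' @return An object of class `probe_run_summary`: per-stage cluster and
#'   probe counts plus a probes-per-cluster histogram whose mass equals the
#'   number of clusters.
#' @export
summarize_run <- function(stage, clusters, probes, rejections = NULL) {
  all_cids <- as.character(sort(unique(clusters$assignments$cluster_id)))
  if (nrow(probes) > 0L && !all(probes$cluster_id %in% all_cids))
    stop("probes reference unknown cluster ids: ",
         paste(setdiff(unique(probes$cluster_id), all_cids), collapse = ", "))
  per_cluster <- table(factor(probes$cluster_id, levels = all_cids))
  hist <- table(as.integer(per_cluster))
  structure(list(
    stage = stage,
    clusters_total = length(all_cids),
    clusters_with_probes = sum(per_cluster > 0L),
    probes_emitted = nrow(probes),
    probes_per_cluster_histogram = setNames(as.integer(hist), names(hist)),
    filter_rejections = rejections),
    class = "probe_run_summary")
}

#' @export
print.probe_run_summary <- function(x, ...) {
  cat(sprintf("%s: %d/%d clusters with probes, %d probes\n",
              x$stage, x$clusters_with_probes, x$clusters_total,
              x$probes_emitted))
  invisible(x)
}

write_summary_tsv <- function(summary, path) {
  kv <- c(stage = summary$stage,
          clusters_total = summary$clusters_total,
          clusters_with_probes = summary$clusters_with_probes,
          probes_emitted = summary$probes_emitted)
  h <- summary$probes_per_cluster_histogram
  if (length(h) > 0L)
    kv <- c(kv, setNames(h, paste0("clusters_with_", names(h), "_probes")))
  r <- summary$filter_rejections
  if (length(r) > 0L)
    kv <- c(kv, setNames(r, paste0("rejected_", names(r))))
  con <- file(path, "wt"); on.exit(close(con))
  writeLines("key\tvalue", con)
  writeLines(paste(names(kv), unname(kv), sep = "\t"), con)
  invisible(path)
}

write_probe_tsv <- function(probes, path) {
  cols <- c("probe_id", "cluster_id", "stage", "source_record", "offset",
            "seq", "gc", "tm", "coverage", "cycles")
  extra <- setdiff(names(probes), cols)
  df <- probes[, c(cols, extra), drop = FALSE]
  df$gc <- sprintf("%.4f", df$gc)
  df$tm <- sprintf("%.4f", df$tm)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write the six output files of a completed run
#'
#' Emits, into `directory`: `probe_run1_summary` and `probe_run2_summary`
#' (key/value TSV), `probe_file1` (primary probes, TSV) and `probe_file2`
#' (all probes from both generations, TSV), `core_cluster.txt` (.clstr-style
#' clustering of the submitted sequences) and `probe_non_redundant.txt`
#' (deduplicated probe set, TSV). A machine-readable `run_manifest.txt`
#' (key: value lines) is written alongside but is not part of the six.
#'
#' @param run A `capture_run` object from [run_pipeline()].
#' @param directory Output directory (created if missing).
#' @param zip Also zip the six files into `<directory>.zip` (requires a
#'   `zip` binary on the PATH); default off.
#' @return Named character vector of the six file paths, invisibly.
#' @export
write_outputs <- function(run, directory, zip = FALSE) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  p <- function(f) file.path(directory, f)
  files <- c(probe_run1_summary = p("probe_run1_summary"),
             probe_run2_summary = p("probe_run2_summary"),
             probe_file1 = p("probe_file1"),
             probe_file2 = p("probe_file2"),
             core_cluster = p("core_cluster.txt"),
             probe_non_redundant = p("probe_non_redundant.txt"))
  try_write <- function(fun, path, ...) {
    tryCatch(fun(..., path), error = function(e)
      stop(sprintf("failed writing %s: %s", path, conditionMessage(e))))
  }
  try_write(function(x, path) write_summary_tsv(x, path),
            files[["probe_run1_summary"]], run$summary_run1)
  try_write(function(x, path) write_summary_tsv(x, path),
            files[["probe_run2_summary"]], run$summary_run2)
  try_write(function(x, path) write_probe_tsv(x, path),
            files[["probe_file1"]], run$probes_run1)
  try_write(function(x, path) write_probe_tsv(x, path),
            files[["probe_file2"]], run$probes_run2)
  try_write(function(x, path) write_clstr(x, path),
            files[["core_cluster"]], run$clusters)
  try_write(function(x, path) write_probe_tsv(x, path),
            files[["probe_non_redundant"]], run$probes_nonredundant)
  manifest_path <- p("run_manifest.txt")
  writeLines(c(sprintf("package_version: %s",
                       as.character(utils::packageVersion("probecap"))),
               paste0(names(run$effective_config), ": ",
                      vapply(run$effective_config, function(v)
                        paste(format(v), collapse = ","), character(1)))),
             manifest_path)
  if (isTRUE(zip)) {
    owd <- setwd(dirname(normalizePath(directory))); on.exit(setwd(owd))
    utils::zip(paste0(basename(directory), ".zip"),
               file.path(basename(directory),
                         c(basename(files), "run_manifest.txt")))
  }
  invisible(files)
}
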