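config_defaults <- function() {
  list(max_len = 20000L,
       identity_threshold = 0.9, word_size = 8L, both_strands = FALSE,
       global_identity = TRUE, best_cluster = FALSE, band_width = 20L,
       probe_length = 50L, gc_min = 35, gc_max = 65,
       tm_min = 55, tm_max = 65, max_probes_per_cluster = 3L,
       consensus_column_threshold = 0.9, tile_step = NULL,
       tm_method = "nearest_neighbor", salt_molar = 0.05, oligo_molar = 2.5e-7,
       seed_word_length = 10L, seed_gap_length = 2L, seed_n_words = 4L,
       step4 = NULL, output_dir = NULL, zip = FALSE)
}

#' The bundled "paper" parameter preset
#'
#' 50-mer probes, GC 35-65%, melting temperature 55-65 deg C, at most 3
#' probes per cluster, clustering at 90% identity — the standard operating
#' point for large-scale capture designs.
#'
#' @param name Preset name; only `"paper"` is defined.
#' @return A named list of configuration values for [validate_config()].
#' @export
preset_config <- function(name = "paper") {
  if (!identical(name, "paper")) stop("unknown preset: ", name)
  list(probe_length = 50L, gc_min = 35, gc_max = 65, tm_min = 55, tm_max = 65,
       max_probes_per_cluster = 3L, identity_threshold = 0.9)
}

#' Validate and complete a run configuration
#'
#' Fills defaults for missing keys, rejects unknown keys (strict mode) and
#' enforces cross-field invariants, returning a fully explicit configuration
#' that is echoed into the run manifest. `step4` may hold a named sublist of
#' probe-parameter overrides applied only at the rescue stage.
#'
#' @param raw Named list of configuration values (possibly empty).
#' @return An object of class `run_config` with elements `max_len`,
#'   `clustering` ([clustering_params()]), `probe` and `probe_step4`
#'   ([probe_design_params()]), `seed` ([build_seed()]), `output_dir`,
#'   `zip` and `effective` (the flat effective key-value list).
#' @export
validate_config <- function(raw = list()) {
  if (inherits(raw, "run_config")) return(raw)
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw, keep.null = TRUE)
  if (cfg$gc_min > cfg$gc_max)
    stop("gc_min exceeds gc_max (gc_min = ", cfg$gc_min,
         ", gc_max = ", cfg$gc_max, ")")
  if (cfg$tm_min > cfg$tm_max)
    stop("tm_min exceeds tm_max (tm_min = ", cfg$tm_min,
         ", tm_max = ", cfg$tm_max, ")")
  if (is.null(cfg$tile_step)) cfg$tile_step <- cfg$probe_length
  probe_keys <- c("probe_length", "gc_min", "gc_max", "tm_min", "tm_max",
                  "max_probes_per_cluster", "consensus_column_threshold",
                  "tile_step", "tm_method", "salt_molar", "oligo_molar")
  probe <- do.call(probe_design_params, cfg[probe_keys])
  step4_cfg <- cfg[probe_keys]
  if (!is.null(cfg$step4)) {
    bad <- setdiff(names(cfg$step4), probe_keys)
    if (length(bad) > 0L)
      stop("unknown step4 override key(s): ", paste(bad, collapse = ", "))
    step4_cfg <- utils::modifyList(step4_cfg, cfg$step4)
    if (step4_cfg$gc_min > step4_cfg$gc_max)
      stop("step4 gc_min exceeds gc_max")
  }
  probe_step4 <- do.call(probe_design_params, step4_cfg)
  clustering <- clustering_params(cfg$identity_threshold, cfg$word_size,
                                  cfg$both_strands, cfg$global_identity,
                                  cfg$best_cluster, cfg$band_width)
  seed <- build_seed(cfg$seed_word_length, cfg$seed_gap_length,
                     cfg$seed_n_words)
  if (nchar(seed$pattern) > cfg$probe_length)
    stop("seed pattern (", nchar(seed$pattern),
         " bases) does not fit inside probe_length (", cfg$probe_length, ")")
  effective <- cfg
  effective$step4 <- if (is.null(cfg$step4)) "none"
    else paste(names(cfg$step4), unlist(cfg$step4), sep = "=", collapse = ";")
  effective$output_dir <- if (is.null(cfg$output_dir)) "" else cfg$output_dir
  structure(list(max_len = cfg$max_len, clustering = clustering,
                 probe = probe, probe_step4 = probe_step4, seed = seed,
                 output_dir = cfg$output_dir, zip = isTRUE(cfg$zip),
                 effective = effective),
            class = "run_config")
}

# member records of each cluster, oriented to the representative's forward
# strand (reverse-complement members are flipped so probes always report on
# the representative strand)
oriented_members <- function(clusters, records) {
  mem <- cluster_member_records(clusters, records)
  a <- clusters$assignments
  for (cc in names(mem)) {
    rows <- a[a$cluster_id == as.integer(cc), , drop = FALSE]
    flip <- rows$id[rows$strand == "-"]
    if (length(flip) > 0L) {
      i <- mem[[cc]]$id %in% flip
      mem[[cc]]$seq[i] <- reverse_complement(mem[[cc]]$seq[i])
    }
  }
  mem
}

#' Run the full probe-design pipeline
#'
#' Executes, in order: the genomic-length filter, greedy incremental
#' clustering, group-specific primary probe design per cluster, rescue
#' design (consensus tiling / direct tiling) for clusters left probe-less,
#' probe deduplication, and per-stage summaries. Every stage is
#' deterministic, so a fixed input and configuration reproduce the output
#' byte for byte. If an output directory is configured (or given), the six
#' standard output files are written there.
#'
#' @param input Path to a FASTA file, or a data frame of records
#'   (`id`, `seq`).
#' @param config A configuration list or [validate_config()] result.
#' @param output_dir Optional output directory (overrides the config key).
#' @return An object of class `capture_run` with the clusters, the probe
#'   tables of both generations, the non-redundant set, both summaries, the
#'   effective configuration, and (when written) the output file manifest.
#' @export
run_pipeline <- function(input, config = list(), output_dir = NULL) {
  config <- validate_config(config)
  records <- if (is.character(input)) read_fasta(input) else input
  stopifnot(is.data.frame(records))

  fg <- filter_genomic(records, config$max_len)
  if (nrow(fg$kept) == 0L)
    stop("clustering stage: no sequences remain after the genomic-length filter")

  clusters <- tryCatch(greedy_cluster(fg$kept, config$clustering),
                       error = function(e)
                         stop("clustering stage failed: ", conditionMessage(e)))

  mem <- oriented_members(clusters, fg$kept)
  all_members <- lapply(mem, function(df) df$seq)
  key_table <- build_key_table(all_members, config$seed,
                               config$clustering$both_strands)

  rej1 <- c(contains_n = 0L, gc_out = 0L, tm_out = 0L, nonspecific = 0L)
  probes1_list <- lapply(names(mem), function(cc) {
    p <- design_primary_probes(cc, all_members, config$probe, config$seed,
                               config$clustering$both_strands,
                               member_ids = mem[[cc]]$id,
                               .key_table = key_table)
    rej1 <<- rej1 + attr(p, "rejections")
    p
  })
  probes1 <- do.call(rbind, probes1_list)
  rownames(probes1) <- NULL

  probeless <- setdiff(names(mem), unique(probes1$cluster_id))
  rescue <- design_rescue_probes(mem[probeless], config$probe_step4)
  rej2 <- attr(rescue, "rejections")
  probes2 <- rbind(probes1, rescue)
  rownames(probes2) <- NULL

  nr <- nonredundant(probes2)
  s1 <- summarize_run("run1", clusters, probes1, rej1)
  s2 <- summarize_run("run2", clusters, probes2, c(rej1, setNames(
    rej2, paste0("rescue_", names(rej2)))))

  run <- structure(list(
    n_input = nrow(records), n_kept = nrow(fg$kept),
    n_removed_genomic = nrow(fg$removed),
    clusters = clusters,
    probes_run1 = probes1, probes_rescue = rescue, probes_run2 = probes2,
    probes_nonredundant = nr,
    summary_run1 = s1, summary_run2 = s2,
    effective_config = config$effective,
    files = NULL), class = "capture_run")

  outdir <- if (!is.null(output_dir)) output_dir else config$output_dir
  if (!is.null(outdir))
    run$files <- write_outputs(run, outdir, zip = config$zip)
  run
}

#' @export
print.capture_run <- function(x, ...) {
  cat("capture_run\n")
  cat(sprintf("  input: %d sequences (%d removed as genomic, %d kept)\n",
              x$n_input, x$n_removed_genomic, x$n_kept))
  cat(sprintf("  clusters: %d\n", x$clusters$n_clusters))
  cat(sprintf("  primary:  %d probes over %d clusters\n",
              x$summary_run1$probes_emitted,
              x$summary_run1$clusters_with_probes))
  cat(sprintf("  final:    %d probes over %d clusters (%d rescue)\n",
              x$summary_run2$probes_emitted,
              x$summary_run2$clusters_with_probes, nrow(x$probes_rescue)))
  cat(sprintf("  non-redundant probes: %d\n", nrow(x$probes_nonredundant)))
  invisible(x)
}

#' @export
summary.capture_run <- function(object, ...) {
  cyc <- object$probes_run2$cycles
  cat(sprintf(paste0(
    "Probe design run\n",
    "  sequences kept / removed:  %d / %d\n",
    "  clusters:                  %d\n",
    "  clusters with probes:      %d after primary, %d after rescue\n",
    "  probes:                    %d primary + %d rescue = %d (%d non-redundant)\n"),
    object$n_kept, object$n_removed_genomic, object$clusters$n_clusters,
    object$summary_run1$clusters_with_probes,
    object$summary_run2$clusters_with_probes,
    nrow(object$probes_run1), nrow(object$probes_rescue),
    nrow(object$probes_run2), nrow(object$probes_nonredundant)))
  if (length(cyc) > 0L)
    cat(sprintf("  synthesis cycles:          mean %.1f, max %d\n",
                mean(cyc), max(cyc)))
  invisible(object)
}
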