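# Build the global spaced-key table used for specificity checks:
# unique (key, cluster_id) pairs over every window of every sequence,
# keyed by `key`. all_clusters: named list of character vectors.
build_key_table <- function(all_clusters, seed, both_strands = FALSE) {
  pieces <- list()
  for (cc in names(all_clusters)) {
    for (s in all_clusters[[cc]]) {
      k <- seed_keys(s, seed)
      if (both_strands) k <- c(k, seed_keys(reverse_complement(s), seed))
      if (length(k) > 0L)
        pieces[[length(pieces) + 1L]] <-
          data.table::data.table(skey = unique(k), cluster_id = cc)
    }
  }
  dt <- if (length(pieces) == 0L)
    data.table::data.table(skey = character(0), cluster_id = character(0))
  else unique(data.table::rbindlist(pieces))
  data.table::setkeyv(dt, "skey")
  dt
}

# Greedy selection maximizing (coverage desc, min offset distance to the
# already-selected set desc, offset asc, seq asc, source asc). The first
# pick has infinite distance for every candidate, so it reduces to
# (coverage desc, offset asc, seq asc).
select_spread <- function(cand, k) {
  picked <- integer(0)
  while (length(picked) < k && length(picked) < nrow(cand)) {
    remaining <- setdiff(seq_len(nrow(cand)), picked)
    mind <- if (length(picked) == 0L) rep(Inf, length(remaining))
    else vapply(remaining, function(i)
      min(abs(cand$offset[i] - cand$offset[picked])), numeric(1))
    ord <- order(-cand$coverage[remaining], -mind,
                 cand$offset[remaining], cand$seq[remaining],
                 cand$source_record[remaining])
    picked <- c(picked, remaining[ord[1L]])
  }
  cand[picked, , drop = FALSE]
}

#' Design group-specific (primary) probes for one cluster
#'
#' Enumerates every probe-length window of every member sequence, drops
#' windows failing the GC/Tm/N filters, rejects windows that seed-match any
#' sequence outside the cluster (specificity against the input itself), and
#' selects up to `max_probes_per_cluster` of the survivors: the best-covering
#' candidate first, then greedy farthest-point selection on source offsets so
#' that both conserved and variable regions of the group are represented.
#' An empty result is allowed and flags the cluster for the rescue stage.
#'
#' @param cluster_id Cluster to design for (must be a name of
#'   `all_clusters`).
#' @param all_clusters Named list (names = cluster ids) of character vectors
#'   of member sequences, oriented to the representative's forward strand.
#' @param params A [probe_design_params()] object.
#' @param seed A [build_seed()] object; its pattern must fit inside
#'   `probe_length`.
#' @param both_strands Match candidates against both strands.
#' @param member_ids Optional character vector of member record ids (same
#'   order as the member sequences); window sources are reported with these.
#' @param .key_table Precomputed result of the internal global key-table
#'   builder; the pipeline passes it so the table is built once per run.
#'   Leave `NULL` to have it computed from `all_clusters`.
#' @return A data frame of probes (`probe_id`, `cluster_id`, `stage`,
#'   `source_record`, `offset`, `seq`, `gc`, `tm`, `coverage`, `cycles`)
#'   with a `rejections` attribute tallying why windows were dropped.
#' @export
design_primary_probes <- function(cluster_id, all_clusters,
                                  params = probe_design_params(),
                                  seed = build_seed(), both_strands = FALSE,
                                  member_ids = NULL,
                                  .key_table = NULL) {
  cc <- as.character(cluster_id)
  if (!cc %in% names(all_clusters)) stop("unknown cluster id: ", cc)
  if (nchar(seed$pattern) > params$probe_length)
    stop("seed pattern longer than probe_length")
  members <- all_clusters[[cc]]
  if (is.null(member_ids))
    member_ids <- if (!is.null(names(members))) names(members)
                  else paste0("member", seq_along(members))
  keys_tab <- if (is.null(.key_table))
    build_key_table(all_clusters, seed, both_strands) else .key_table

  plen <- nchar(seed$pattern)
  n_anchor <- params$probe_length - plen + 1L
  rej <- c(contains_n = 0L, gc_out = 0L, tm_out = 0L, nonspecific = 0L)

  member_keys <- lapply(members, function(s) {
    k <- seed_keys(s, seed)
    if (both_strands) c(k, seed_keys(reverse_complement(s), seed)) else k
  })

  cand_list <- list()
  for (j in seq_along(members)) {
    wm <- window_metrics(members[[j]], params$probe_length, params$tm_method,
                         params$salt_molar, params$oligo_molar)
    if (nrow(wm) == 0L) next
    rej[["contains_n"]] <- rej[["contains_n"]] + sum(wm$has_n)
    ok_n <- !wm$has_n
    gc_ok <- ok_n & wm$gc >= params$gc_min & wm$gc <= params$gc_max
    rej[["gc_out"]] <- rej[["gc_out"]] + sum(ok_n & !gc_ok)
    tm_ok <- gc_ok & wm$tm >= params$tm_min & wm$tm <= params$tm_max
    rej[["tm_out"]] <- rej[["tm_out"]] + sum(gc_ok & !tm_ok)
    keep <- which(tm_ok)
    if (length(keep) == 0L) next
    cand_list[[length(cand_list) + 1L]] <- data.frame(
      mem = j, source_record = member_ids[j], offset = wm$offset[keep],
      seq = wm$window[keep], gc = wm$gc[keep], tm = wm$tm[keep],
      stringsAsFactors = FALSE)
  }
  empty <- data.frame(probe_id = character(0), cluster_id = character(0),
                      stage = character(0), source_record = character(0),
                      offset = integer(0), seq = character(0),
                      gc = numeric(0), tm = numeric(0),
                      coverage = integer(0), cycles = integer(0),
                      stringsAsFactors = FALSE)
  if (length(cand_list) == 0L)
    return(structure(empty, rejections = rej))
  cand <- do.call(rbind, cand_list)

  # anchor keys of candidate i: the source member's forward keys at offsets
  # offset .. offset + n_anchor - 1 (all inside the window by construction)
  fwd_keys <- lapply(members, function(s) seed_keys(s, seed))
  anchor_idx <- rep(seq_len(nrow(cand)), each = n_anchor)
  anchor_keys <- unlist(lapply(seq_len(nrow(cand)), function(i) {
    fwd_keys[[cand$mem[i]]][cand$offset[i] + seq_len(n_anchor)]
  }), use.names = FALSE)
  if (both_strands) {
    rc_keys <- unlist(lapply(seq_len(nrow(cand)), function(i)
      seed_keys(reverse_complement(cand$seq[i]), seed)), use.names = FALSE)
    anchor_idx <- c(anchor_idx, rep(seq_len(nrow(cand)), each = n_anchor))
    anchor_keys <- c(anchor_keys, rc_keys)
  }
  akdt <- data.table::data.table(cand_id = anchor_idx, skey = anchor_keys)

  # specificity: no anchor key may occur in a foreign cluster
  hits <- keys_tab[akdt, on = "skey", nomatch = 0L, allow.cartesian = TRUE]
  bad <- unique(hits[cluster_id != cc, cand_id])
  rej[["nonspecific"]] <- length(unique(akdt$cand_id[akdt$cand_id %in% bad]))
  specific <- setdiff(seq_len(nrow(cand)), bad)
  if (length(specific) == 0L)
    return(structure(empty, rejections = rej))
  cand <- cand[specific, , drop = FALSE]
  akdt <- akdt[!cand_id %in% bad]
  akdt[, cand_id := match(cand_id, specific)]

  # coverage: number of members sharing at least one anchor key
  mkdt <- data.table::rbindlist(lapply(seq_along(members), function(j)
    data.table::data.table(skey = unique(member_keys[[j]]), mem = j)))
  cov_hits <- unique(mkdt[akdt, on = "skey", nomatch = 0L,
                          allow.cartesian = TRUE][, list(cand_id, mem)])
  cov <- integer(nrow(cand))
  if (nrow(cov_hits) > 0L) {
    tab <- cov_hits[, list(n_hit = .N), by = "cand_id"]
    cov[tab$cand_id] <- tab$n_hit
  }
  cand$coverage <- cov

  sel <- select_spread(cand, params$max_probes_per_cluster)
  if (nrow(sel) == 0L) return(structure(empty, rejections = rej))
  data.frame(
    probe_id = sprintf("C%s_P%d", cc, seq_len(nrow(sel))),
    cluster_id = cc, stage = "primary",
    source_record = sel$source_record, offset = sel$offset, seq = sel$seq,
    gc = sel$gc, tm = sel$tm, coverage = sel$coverage,
    cycles = synthesis_cycles(sel$seq),
    stringsAsFactors = FALSE, row.names = NULL) |>
    structure(rejections = rej)
}
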