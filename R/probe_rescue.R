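#' Center-star multiple sequence alignment
#'
#' Deterministic small-scale MSA for consensus calling: the center is the
#' member maximizing summed pairwise identity (ties: first in input order);
#' every other member is globally aligned to the center (match +1,
#' mismatch -1, gap -2) and the pairwise alignments are merged under the
#' once-a-gap-always-a-gap rule (coincident center-gap columns from
#' different members are merged).
#'
#' @param members Named character vector (or data frame with `id`, `seq`)
#'   of at least 2 member sequences.
#' @return An object of class `msa`: `list(row_ids = , rows = )` where
#'   `rows` are equal-length strings over `A,C,G,T,N,-` and removing the
#'   gaps of row i reproduces member i.
#' @export
center_star_align <- function(members) {
  if (is.data.frame(members)) members <- setNames(members$seq, members$id)
  if (is.null(names(members)))
    names(members) <- paste0("member", seq_along(members))
  n <- length(members)
  if (n < 2L) stop("center_star_align needs at least 2 members")

  # center = member with the highest summed pairwise identity
  idsum <- numeric(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    al <- cpp_global_align(members[[i]], members[[j]], -1L, 1L, -1L, -2L, FALSE)
    idn <- al$matches / min(nchar(members[[i]]), nchar(members[[j]]))
    idsum[i] <- idsum[i] + idn; idsum[j] <- idsum[j] + idn
  }
  ci <- which.max(idsum)
  center <- members[[ci]]

  mc <- strsplit(center, "", fixed = TRUE)[[1L]]  # master center row
  rows <- list()                                  # merged non-center rows
  row_ids <- character(0)
  for (j in setdiff(seq_len(n), ci)) {
    al <- cpp_global_align(center, members[[j]], -1L, 1L, -1L, -2L, TRUE)
    ca <- strsplit(al$aligned_a, "", fixed = TRUE)[[1L]]
    ma <- strsplit(al$aligned_b, "", fixed = TRUE)[[1L]]
    # walk master vs pairwise center, producing source-column maps
    im <- 1L; ip <- 1L
    take_master <- integer(0); take_pair <- integer(0)
    while (im <= length(mc) || ip <= length(ca)) {
      m_gap <- im <= length(mc) && mc[im] == "-"
      p_gap <- ip <= length(ca) && ca[ip] == "-"
      if (im <= length(mc) && ip <= length(ca) && !m_gap && !p_gap) {
        take_master <- c(take_master, im); take_pair <- c(take_pair, ip)
        im <- im + 1L; ip <- ip + 1L
      } else if (m_gap && p_gap) {
        take_master <- c(take_master, im); take_pair <- c(take_pair, ip)
        im <- im + 1L; ip <- ip + 1L
      } else if (m_gap) {
        take_master <- c(take_master, im); take_pair <- c(take_pair, NA)
        im <- im + 1L
      } else if (p_gap) {
        take_master <- c(take_master, NA); take_pair <- c(take_pair, ip)
        ip <- ip + 1L
      } else if (im > length(mc)) {
        take_master <- c(take_master, NA); take_pair <- c(take_pair, ip)
        ip <- ip + 1L
      } else {
        take_master <- c(take_master, im); take_pair <- c(take_pair, NA)
        im <- im + 1L
      }
    }
    remap <- function(r, take) {
      out <- rep("-", length(take))
      out[!is.na(take)] <- r[take[!is.na(take)]]
      out
    }
    mc <- remap(mc, take_master)
    rows <- lapply(rows, remap, take = take_master)
    rows[[length(rows) + 1L]] <- remap(ma, take_pair)
    row_ids <- c(row_ids, names(members)[j])
  }
  all_rows <- c(list(mc), rows)
  all_ids <- c(names(members)[ci], row_ids)
  ord <- match(names(members), all_ids)  # restore input order
  structure(list(row_ids = names(members),
                 rows = vapply(all_rows[ord], paste, character(1),
                               collapse = "")),
            class = "msa")
}

#' Consensus sequence of an alignment
#'
#' Columns with more than 50% gap characters are dropped. For each kept
#' column, the most common base (A/C/G/T, ties broken alphabetically) among
#' the non-gap characters is emitted if its frequency among non-gap
#' characters reaches `column_threshold`; otherwise the column is `N`
#' (ambiguous, and any probe window containing it is later discarded).
#'
#' @param alignment An `msa` object (or list with `rows`).
#' @param column_threshold Fraction in `(0.5, 1]`, default 0.9.
#' @return `list(seq = , column_support = )` where `column_support` gives the
#'   winning base's non-gap frequency per kept column.
#' @export
consensus <- function(alignment, column_threshold = 0.9) {
  stopifnot(column_threshold > 0.5, column_threshold <= 1)
  mat <- do.call(rbind, strsplit(alignment$rows, "", fixed = TRUE))
  keep_base <- character(0); support <- numeric(0)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    nongap <- col[col != "-"]
    if (length(nongap) <= length(col) / 2) next  # > 50% gaps: drop column
    counts <- table(factor(nongap[nongap != "N"], levels = c("A", "C", "G", "T")))
    f <- max(counts) / length(nongap)
    base <- if (sum(counts) == 0L || f < column_threshold) "N"
            else names(counts)[which.max(counts)]
    keep_base <- c(keep_base, base)
    support <- c(support, f)
  }
  list(seq = paste(keep_base, collapse = ""), column_support = support)
}

#' Tile probe-length windows across a sequence
#'
#' Windows start at offsets `0, step, 2*step, ...` while they fit; a final
#' 3'-anchored window at `len - probe_length` is added if not already
#' present, so the sequence end is always covered. Windows are 0-based,
#' half-open `[offset, offset + probe_length)`. Windows containing `N` are
#' not excluded here (the filter stage does that).
#'
#' @param seq Sequence to tile.
#' @param probe_length Window width.
#' @param step Tiling step (>= 1).
#' @return Data frame `offset`, `window`; empty if the sequence is shorter
#'   than `probe_length`.
#' @export
tile <- function(seq, probe_length, step = probe_length) {
  stopifnot(step >= 1L)
  L <- nchar(seq)
  if (L < probe_length)
    return(data.frame(offset = integer(0), window = character(0),
                      stringsAsFactors = FALSE))
  offs <- seq.int(0L, L - probe_length, by = step)
  if (offs[length(offs)] != L - probe_length)
    offs <- c(offs, L - probe_length)
  data.frame(offset = as.integer(offs),
             window = substring(seq, offs + 1L, offs + probe_length),
             stringsAsFactors = FALSE)
}

#' Rescue probe design for probe-less clusters
#'
#' Clusters that received no group-specific probes are rescued: multi-member
#' clusters are aligned ([center_star_align()]), a consensus is called at the
#' column threshold, and the consensus is tiled; singleton clusters are tiled
#' directly. Windows containing `N` are dropped, survivors are filtered with
#' [passes_filters()], ranked by offset ascending, and capped at
#' `max_probes_per_cluster`. The rescue stage may run with its own, typically
#' relaxed, parameter set so that clusters whose sequences fall outside the
#' primary GC/Tm window can still be captured.
#'
#' @param probeless_clusters Named list (names = cluster ids) of data frames
#'   (`id`, `seq`) of member records, oriented to the representative strand.
#' @param params A [probe_design_params()] object (possibly the relaxed
#'   stage-IV override).
#' @return Data frame of probes with stage `"rescue_consensus"` or
#'   `"rescue_direct"` and a `rejections` attribute.
#' @export
design_rescue_probes <- function(probeless_clusters,
                                 params = probe_design_params()) {
  rej <- c(contains_n = 0L, gc_out = 0L, tm_out = 0L, too_short = 0L)
  out <- list()
  for (cc in names(probeless_clusters)) {
    mem <- probeless_clusters[[cc]]
    if (nrow(mem) >= 2L) {
      msa <- center_star_align(setNames(mem$seq, mem$id))
      src <- consensus(msa, params$consensus_column_threshold)$seq
      stage <- "rescue_consensus"; source_record <- "consensus"
    } else {
      src <- mem$seq[1L]
      stage <- "rescue_direct"; source_record <- mem$id[1L]
    }
    tiles <- tile(src, params$probe_length, params$tile_step)
    if (nrow(tiles) == 0L) { rej[["too_short"]] <- rej[["too_short"]] + 1L; next }
    has_n <- grepl("N", tiles$window, fixed = TRUE)
    rej[["contains_n"]] <- rej[["contains_n"]] + sum(has_n)
    tiles <- tiles[!has_n, , drop = FALSE]
    if (nrow(tiles) == 0L) next
    gc <- vapply(tiles$window, gc_percent, numeric(1), USE.NAMES = FALSE)
    gc_ok <- gc >= params$gc_min & gc <= params$gc_max
    rej[["gc_out"]] <- rej[["gc_out"]] + sum(!gc_ok)
    tm <- vapply(tiles$window, melting_temp, numeric(1),
                 method = params$tm_method, salt_molar = params$salt_molar,
                 oligo_molar = params$oligo_molar, USE.NAMES = FALSE)
    tm_ok <- gc_ok & tm >= params$tm_min & tm <= params$tm_max
    rej[["tm_out"]] <- rej[["tm_out"]] + sum(gc_ok & !tm_ok)
    keep <- which(tm_ok)
    if (length(keep) == 0L) next
    keep <- keep[order(tiles$offset[keep])]
    keep <- head(keep, params$max_probes_per_cluster)
    out[[length(out) + 1L]] <- data.frame(
      probe_id = sprintf("C%s_R%d", cc, seq_along(keep)),
      cluster_id = cc, stage = stage, source_record = source_record,
      offset = tiles$offset[keep], seq = tiles$window[keep],
      gc = gc[keep], tm = tm[keep], coverage = nrow(mem),
      cycles = synthesis_cycles(tiles$window[keep]),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- if (length(out) == 0L)
    data.frame(probe_id = character(0), cluster_id = character(0),
               stage = character(0), source_record = character(0),
               offset = integer(0), seq = character(0), gc = numeric(0),
               tm = numeric(0), coverage = integer(0), cycles = integer(0),
               stringsAsFactors = FALSE)
  else do.call(rbind, out)
  structure(res, rejections = rej)
}
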