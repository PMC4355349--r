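#' Clustering parameters
#'
#' Bundles the six knobs of the greedy incremental clusterer: the identity
#' threshold a member must reach against its cluster representative, the
#' word size of the shared-word prescreen, whether both strands are compared,
#' whether identity is computed globally (denominator = shorter sequence
#' length) or over the aligned region only, whether a sequence joins the
#' first acceptable cluster or the best one, and the alignment bandwidth.
#'
#' @param identity_threshold Fraction in `[0.4, 1]`; members must align to
#'   their representative at or above this identity. The 0.4 floor keeps the
#'   short-word prescreen meaningful.
#' @param word_size Prescreen word length (>= 4).
#' @param both_strands Also compare the reverse complement.
#' @param global_identity Identity denominator is the shorter sequence length
#'   (`TRUE`, the default) or the aligned columns excluding terminal gaps.
#' @param best_cluster Join the highest-identity cluster instead of the first
#'   acceptable one; ties go to the lowest cluster id.
#' @param band_width Banded-alignment half width; the band is widened by the
#'   length difference of the two sequences so the global alignment always
#'   fits.
#' @return An object of class `clustering_params`.
#' @export
clustering_params <- function(identity_threshold = 0.9, word_size = 8L,
                              both_strands = FALSE, global_identity = TRUE,
                              best_cluster = FALSE, band_width = 20L) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            word_size >= 4L, band_width >= 1L)
  if (identity_threshold < 0.4)
    stop("identity_threshold below 0.4: the short-word prescreen is not valid there")
  structure(list(identity_threshold = identity_threshold,
                 word_size = as.integer(word_size),
                 both_strands = isTRUE(both_strands),
                 global_identity = isTRUE(global_identity),
                 best_cluster = isTRUE(best_cluster),
                 band_width = as.integer(band_width)),
            class = "clustering_params")
}

as_seq <- function(x) {
  if (is.data.frame(x)) x$seq[1L] else as.character(x)[1L]
}

align_identity <- function(a, b, band, global) {
  al <- cpp_global_align(a, b, band, 1L, -1L, -2L, keep_alignment = !global)
  if (global) {
    al$matches / min(nchar(a), nchar(b))
  } else {
    ra <- strsplit(al$aligned_a, "")[[1L]]
    rb <- strsplit(al$aligned_b, "")[[1L]]
    inner <- which(ra != "-" & rb != "-")
    if (length(inner) == 0L) return(0)
    cols <- max(inner) - min(inner) + 1L
    al$matches / cols
  }
}

#' Pairwise sequence identity
#'
#' Identity between two sequences under a banded global alignment
#' (match +1, mismatch -1, gap -2). With `global_identity` the denominator is
#' the shorter sequence length; otherwise the aligned columns excluding
#' terminal gaps. With `both_strands` the better of the forward and
#' reverse-complement orientations is returned together with the achieving
#' strand (ties prefer `"+"`).
#'
#' @param a,b Sequences (character scalars or single-row record data frames).
#' @param params A [clustering_params()] object.
#' @return `list(identity = , strand = )` with strand `"+"` or `"-"`.
#' @export
pairwise_identity <- function(a, b, params = clustering_params()) {
  a <- as_seq(a); b <- as_seq(b)
  stopifnot(nchar(a) >= 1L, nchar(b) >= 1L)
  fwd <- align_identity(a, b, params$band_width, params$global_identity)
  if (!params$both_strands)
    return(list(identity = fwd, strand = "+"))
  rev <- align_identity(reverse_complement(a), b,
                        params$band_width, params$global_identity)
  if (rev > fwd) list(identity = rev, strand = "-")
  else list(identity = fwd, strand = "+")
}

seq_words <- function(s, w) {
  n <- nchar(s)
  if (n < w) return(character(0))
  substring(s, 1:(n - w + 1L), w:n)
}

# Minimum number of query-word hits compatible with identity >= t.
# Matched alignment columns form runs contiguous in both sequences; runs are
# broken by mismatches, deletions and insertion events, bounded via the
# identity threshold and the length difference. Non-positive bounds mean the
# prescreen can only demand a single shared word.
prescreen_required <- function(len_short, len_long, threshold, word_size) {
  breakers <- 2L * floor((1 - threshold) * len_short) +
    (len_long - len_short) + 1L
  ceiling(threshold * len_short - 1e-9) - breakers * (word_size - 1L)
}

#' Shared-word prescreen
#'
#' Cheap filter run before alignment: counts positions of the shorter
#' sequence whose `word_size`-mer occurs anywhere in the longer sequence and
#' compares the count to a run-length lower bound implied by the identity
#' threshold. Pairs at or above the threshold are never screened out under
#' substitution-dominated divergence; a pair sharing no word at all is always
#' screened out. Pairs below the threshold may still pass (the filter is
#' one-sided).
#'
#' @inheritParams pairwise_identity
#' @return `TRUE` if the pair may reach the identity threshold.
#' @export
word_prescreen <- function(a, b, params = clustering_params()) {
  a <- as_seq(a); b <- as_seq(b)
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  w <- params$word_size
  if (nchar(a) < w) return(TRUE)  # too short for the filter to be valid
  req <- max(1L, prescreen_required(nchar(a), nchar(b),
                                    params$identity_threshold, w))
  hit <- function(query, target) {
    sum(seq_words(query, w) %in% seq_words(target, w)) >= req
  }
  if (hit(a, b)) return(TRUE)
  if (params$both_strands && hit(reverse_complement(a), b)) return(TRUE)
  FALSE
}

#' Greedy incremental clustering
#'
#' Sequences are processed in order of decreasing length (ties: input order).
#' Each sequence joins the first existing cluster (or, with `best_cluster`,
#' the highest-identity cluster) whose representative passes the word
#' prescreen and aligns at or above the identity threshold; otherwise it
#' founds a new cluster with itself as representative. Cluster ids are
#' assigned in creation order starting at 0.
#'
#' @param records Data frame of sequence records (`id`, `seq`).
#' @param params A [clustering_params()] object.
#' @return An object of class `capture_clusters`: a list with `assignments`
#'   (data frame `id`, `cluster_id`, `identity`, `strand`,
#'   `is_representative`, `length`), `n_clusters` and `params`.
#' @export
greedy_cluster <- function(records, params = clustering_params()) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L)
    return(structure(list(assignments = data.frame(
      id = character(0), cluster_id = integer(0), identity = numeric(0),
      strand = character(0), is_representative = logical(0),
      length = integer(0), stringsAsFactors = FALSE),
      n_clusters = 0L, params = params), class = "capture_clusters"))
  if (anyDuplicated(records$id)) stop("duplicate record ids")
  ord <- order(-nchar(records$seq))  # stable: ties keep input order
  recs <- records[ord, , drop = FALSE]
  t <- params$identity_threshold; w <- params$word_size

  rep_words <- data.table::data.table(word = character(0), cid = integer(0))
  rep_seq <- character(0); rep_len <- integer(0)

  n <- nrow(recs)
  cid_out <- integer(n); ident_out <- numeric(n); strand_out <- character(n)
  isrep_out <- logical(n)

  add_rep <- function(seqs_words, cid) {
    new <- data.table::data.table(word = unique(seqs_words), cid = cid)
    rep_words <<- data.table::rbindlist(list(rep_words, new))
    data.table::setkeyv(rep_words, "word")
  }

  for (i in seq_len(n)) {
    s <- recs$seq[i]; L <- nchar(s)
    cand <- integer(0)
    if (length(rep_seq) > 0L && L < w) {
      cand <- seq_along(rep_seq) - 1L  # too short to prescreen: try them all
    } else if (length(rep_seq) > 0L) {
      count_hits <- function(query) {
        qdt <- data.table::data.table(word = seq_words(query, w))
        j <- rep_words[qdt, on = "word", nomatch = 0L, allow.cartesian = TRUE]
        if (nrow(j) == 0L) integer(0) else {
          tab <- j[, list(n_hit = .N), by = "cid"]
          setNames(tab$n_hit, tab$cid)
        }
      }
      hits_f <- count_hits(s)
      hits_r <- if (params$both_strands) count_hits(reverse_complement(s))
                else integer(0)
      cids <- sort(unique(as.integer(c(names(hits_f), names(hits_r)))))
      for (cc in cids) {
        req <- max(1L, prescreen_required(min(L, rep_len[cc + 1L]),
                                          max(L, rep_len[cc + 1L]), t, w))
        hf <- if (as.character(cc) %in% names(hits_f)) hits_f[[as.character(cc)]] else 0L
        hr <- if (as.character(cc) %in% names(hits_r)) hits_r[[as.character(cc)]] else 0L
        if (max(hf, hr) >= req) cand <- c(cand, cc)
      }
    }
    assigned <- FALSE
    if (length(cand) > 0L) {
      best_id <- -1; best_cid <- NA_integer_; best_strand <- "+"
      for (cc in sort(cand)) {
        pi <- pairwise_identity(s, rep_seq[cc + 1L], params)
        if (pi$identity >= t) {
          if (!params$best_cluster) {
            cid_out[i] <- cc; ident_out[i] <- pi$identity
            strand_out[i] <- pi$strand; assigned <- TRUE
            break
          }
          if (pi$identity > best_id) {
            best_id <- pi$identity; best_cid <- cc; best_strand <- pi$strand
          }
        }
      }
      if (params$best_cluster && !is.na(best_cid)) {
        cid_out[i] <- best_cid; ident_out[i] <- best_id
        strand_out[i] <- best_strand; assigned <- TRUE
      }
    }
    if (!assigned) {
      cc <- length(rep_seq)
      rep_seq[cc + 1L] <- s; rep_len[cc + 1L] <- L
      if (L >= w) add_rep(seq_words(s, w), cc)
      cid_out[i] <- cc; ident_out[i] <- 1.0; strand_out[i] <- "+"
      isrep_out[i] <- TRUE
    }
  }

  assignments <- data.frame(
    id = recs$id, cluster_id = cid_out,
    identity = round(ident_out, 6), strand = strand_out,
    is_representative = isrep_out, length = nchar(recs$seq),
    stringsAsFactors = FALSE)
  structure(list(assignments = assignments,
                 n_clusters = length(rep_seq),
                 params = params),
            class = "capture_clusters")
}

#' @export
print.capture_clusters <- function(x, ...) {
  a <- x$assignments
  cat(sprintf("capture_clusters: %d sequences in %d clusters (threshold %.2f)\n",
              nrow(a), x$n_clusters, x$params$identity_threshold))
  sizes <- table(a$cluster_id)
  cat(sprintf("  cluster sizes: min %d / median %d / max %d; singletons: %d\n",
              min(sizes), stats::median(sizes), max(sizes), sum(sizes == 1L)))
  invisible(x)
}

#' Write clusters in .clstr-style text format
#'
#' One block per cluster: a `>Cluster <id>` header followed by one member
#' line per sequence, `<i>\t<length>nt, ><id>... at <strand>/<identity%>`;
#' the representative line ends in `*` instead. Identities are printed with
#' six decimals so [read_clstr()] round-trips.
#'
#' @param clusters A `capture_clusters` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_clstr <- function(clusters, path) {
  a <- clusters$assignments
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cc in sort(unique(a$cluster_id))) {
    writeLines(sprintf(">Cluster %d", cc), con)
    mem <- a[a$cluster_id == cc, , drop = FALSE]
    mem <- mem[order(!mem$is_representative, mem$id), , drop = FALSE]
    for (j in seq_len(nrow(mem))) {
      if (mem$is_representative[j]) {
        writeLines(sprintf("%d\t%dnt, >%s... *",
                           j - 1L, mem$length[j], mem$id[j]), con)
      } else {
        writeLines(sprintf("%d\t%dnt, >%s... at %s/%.6f%%",
                           j - 1L, mem$length[j], mem$id[j],
                           mem$strand[j], mem$identity[j] * 100), con)
      }
    }
  }
  invisible(path)
}

#' Read a .clstr-style cluster file written by [write_clstr()]
#'
#' @param path Path to a `.clstr`-style file.
#' @return Data frame `id`, `cluster_id`, `identity`, `strand`,
#'   `is_representative`, `length`.
#' @export
read_clstr <- function(path) {
  lines <- readLines(path)
  out <- list(); cc <- NA_integer_
  for (line in lines) {
    if (startsWith(line, ">Cluster")) {
      cc <- as.integer(sub("^>Cluster\\s+", "", line))
    } else if (nzchar(line)) {
      m <- regmatches(line, regexec(
        "^[0-9]+\t([0-9]+)nt, >(.*)\\.\\.\\. (\\*|at ([+-])/([0-9.]+)%)$", line))[[1L]]
      if (length(m) == 0L) stop("unparseable cluster line: ", line)
      is_rep <- m[4L] == "*"
      out[[length(out) + 1L]] <- data.frame(
        id = m[3L], cluster_id = cc,
        identity = if (is_rep) 1.0 else as.numeric(m[6L]) / 100,
        strand = if (is_rep) "+" else m[5L],
        is_representative = is_rep,
        length = as.integer(m[2L]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# per-cluster member records, in cluster id order
cluster_member_records <- function(clusters, records) {
  a <- clusters$assignments
  idx <- match(a$id, records$id)
  split(records[idx, , drop = FALSE], a$cluster_id)
}
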