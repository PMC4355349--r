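#' Build a spaced seed
#'
#' A spaced seed is a match pattern of care (`1`) and don't-care (`0`)
#' positions: `n_words` care-runs of `word_length` bases separated by
#' `gap_length` don't-cares. A seed hit requires agreement only at care
#' positions, so mismatches falling into the gaps are tolerated. Gaps must
#' be shorter than 3 bases.
#'
#' @param word_length Length of each care run (>= 1).
#' @param gap_length Don't-care run between words: 0, 1 or 2.
#' @param n_words Number of care runs (>= 1).
#' @return An object of class `spaced_seed` with elements `pattern` (the
#'   0/1 string), `care` (0-based care positions), `word_length`,
#'   `gap_length`, `n_words`.
#' @examples
#' build_seed(4, 2, 2)$pattern  # "1111001111"
#' @export
build_seed <- function(word_length = 10L, gap_length = 2L, n_words = 4L) {
  stopifnot(word_length >= 1L, n_words >= 1L)
  if (gap_length >= 3L || gap_length < 0L)
    stop("gap_length must be less than 3 bases")
  word <- strrep("1", word_length)
  gap <- strrep("0", gap_length)
  pattern <- paste(rep(word, n_words), collapse = gap)
  care <- which(strsplit(pattern, "", fixed = TRUE)[[1L]] == "1") - 1L
  structure(list(pattern = pattern, care = as.integer(care),
                 word_length = as.integer(word_length),
                 gap_length = as.integer(gap_length),
                 n_words = as.integer(n_words)),
            class = "spaced_seed")
}

#' @export
print.spaced_seed <- function(x, ...) {
  cat(sprintf("spaced_seed: %d words of %d, gaps of %d (%s)\n",
              x$n_words, x$word_length, x$gap_length, x$pattern))
  invisible(x)
}

# spaced-seed keys of every window of s (0-based window offsets)
seed_keys <- function(s, seed) {
  cpp_spaced_keys(s, seed$care, nchar(seed$pattern))
}

#' Spaced-seed match between a candidate probe and a target sequence
#'
#' `TRUE` iff some placement of the seed pattern within the candidate agrees
#' with some placement in the target at every care position (don't-care
#' positions are free). With `both_strands` the reverse complement of the
#' candidate is also tried.
#'
#' @param candidate Candidate probe sequence (length >= the seed pattern).
#' @param target Target sequence.
#' @param seed A [build_seed()] object.
#' @param both_strands Also test the candidate's reverse complement.
#' @return Logical scalar.
#' @export
seed_match <- function(candidate, target, seed = build_seed(),
                       both_strands = FALSE) {
  plen <- nchar(seed$pattern)
  if (nchar(candidate) < plen)
    stop("candidate shorter than the seed pattern")
  if (nchar(target) < plen) return(FALSE)
  tk <- seed_keys(target, seed)
  if (any(seed_keys(candidate, seed) %in% tk)) return(TRUE)
  if (both_strands &&
      any(seed_keys(reverse_complement(candidate), seed) %in% tk))
    return(TRUE)
  FALSE
}

#' Within-cluster coverage of a candidate probe
#'
#' Number of cluster members (including the candidate's source) that the
#' candidate seed-matches.
#'
#' @param candidate Candidate probe sequence.
#' @param cluster_members Character vector of member sequences.
#' @param seed A [build_seed()] object.
#' @param both_strands Also test the candidate's reverse complement.
#' @return Integer count in `[0, length(cluster_members)]`.
#' @export
score_coverage <- function(candidate, cluster_members, seed = build_seed(),
                           both_strands = FALSE) {
  sum(vapply(cluster_members, function(m)
    seed_match(candidate, m, seed, both_strands), logical(1)))
}

#' Cross-cluster specificity of a candidate probe
#'
#' `TRUE` iff the candidate seed-matches no sequence of any other cluster.
#' Specificity is checked against the input sequences themselves, which is
#' what makes the design fast: no external database scan is needed.
#'
#' @param candidate Candidate probe sequence.
#' @param all_clusters Named list (names = cluster ids) of character vectors
#'   of member sequences.
#' @param own_cluster_id The candidate's cluster id.
#' @param seed A [build_seed()] object.
#' @param both_strands Also test the candidate's reverse complement.
#' @return Logical scalar.
#' @export
is_specific <- function(candidate, all_clusters, own_cluster_id,
                        seed = build_seed(), both_strands = FALSE) {
  own <- as.character(own_cluster_id)
  for (cc in names(all_clusters)) {
    if (cc == own) next
    for (m in all_clusters[[cc]]) {
      if (seed_match(candidate, m, seed, both_strands)) return(FALSE)
    }
  }
  TRUE
}
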