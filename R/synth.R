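#' Mutate a sequence with substitutions and short indels
#'
#' Each site independently substitutes to a uniformly chosen different base
#' with probability `sub_rate`; independently, an indel event (insertion or
#' deletion with equal probability, length 1-3) starts at each site with
#' probability `indel_rate`. Deterministic given the R random-number state.
#'
#' @param seq Sequence over `A,C,G,T`.
#' @param sub_rate Per-site substitution probability in `[0, 1)`.
#' @param indel_rate Per-site indel-event probability in `[0, 1)`.
#' @return The mutated sequence.
#' @export
mutate_seq <- function(seq, sub_rate, indel_rate = 0) {
  stopifnot(sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  sub_at <- which(stats::runif(n) < sub_rate)
  if (length(sub_at) > 0L) {
    shift <- sample.int(3L, length(sub_at), replace = TRUE)
    chars[sub_at] <- bases[((match(chars[sub_at], bases) - 1L + shift) %% 4L) + 1L]
  }
  if (indel_rate > 0) {
    ev_at <- which(stats::runif(n) < indel_rate)
    # apply right to left so earlier positions stay valid
    for (pos in rev(ev_at)) {
      len <- sample.int(3L, 1L)
      if (stats::runif(1) < 0.5) {              # insertion after pos
        ins <- sample(bases, len, replace = TRUE)
        chars <- append(chars, ins, after = pos)
      } else {                                   # deletion starting at pos
        del <- pos:min(length(chars), pos + len - 1L)
        chars <- chars[-del]
      }
    }
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic gene-family dataset with planted truth
#'
#' Each family draws an independent random ancestor (so between-family
#' identity sits at the random background, roughly 25-40% under global
#' alignment) and derives members by [mutate_seq()]; within-family divergence
#' is therefore about `within_divergence` to the ancestor and up to twice
#' that between members. Record ids are assigned after shuffling and encode
#' nothing about family membership; the planted truth is returned separately.
#'
#' The defaults emulate moderately diverged gene families of the kind
#' targeted in functional metagenomics. `gc_bias` may be a vector (recycled
#' over families) to build mixed datasets; a strongly skewed value such as
#' 0.8 produces families whose windows fail standard GC filters, exercising
#' the rescue stage.
#'
#' @param n_families Number of families.
#' @param members_per_family Members per family.
#' @param ancestor_length Ancestor length in bases.
#' @param within_divergence Per-site substitution rate from ancestor to
#'   member (<= 0.15).
#' @param indel_rate Per-site indel-event rate (events of length 1-3).
#' @param gc_bias Ancestor GC fraction, scalar or per-family vector.
#' @param seed Optional RNG seed (integer) for a reproducible dataset.
#' @return `list(records = , truth = )`: records is a data frame `id`,
#'   `desc`, `seq`; truth maps `id` to `family`.
#' @export
generate_dataset <- function(n_families = 10L, members_per_family = 20L,
                             ancestor_length = 1000L,
                             within_divergence = 0.03, indel_rate = 0.001,
                             gc_bias = 0.5, seed = NULL) {
  stopifnot(within_divergence <= 0.15, n_families >= 1L,
            members_per_family >= 1L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  gc <- rep_len(gc_bias, n_families)
  seqs <- character(0); fam <- integer(0)
  for (f in seq_len(n_families)) {
    w <- c((1 - gc[f]) / 2, gc[f] / 2, gc[f] / 2, (1 - gc[f]) / 2)
    ancestor <- paste(sample(bases, ancestor_length, replace = TRUE, prob = w),
                      collapse = "")
    for (m in seq_len(members_per_family)) {
      seqs <- c(seqs, mutate_seq(ancestor, within_divergence, indel_rate))
      fam <- c(fam, f)
    }
  }
  ord <- sample.int(length(seqs))
  ids <- sprintf("seq_%05d", seq_along(seqs))
  records <- data.frame(id = ids, desc = "", seq = seqs[ord],
                        stringsAsFactors = FALSE)
  truth <- data.frame(id = ids, family = fam[ord], stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}
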