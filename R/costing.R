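#' Array synthesis cycles needed to build a probe
#'
#' Photolithographic array synthesizers deliver one base per cycle in a fixed
#' repeating order; each position of a probe must wait for the next delivery
#' of its base. The cycle count of a probe is therefore the index of the last
#' delivery cycle used when bases are added one at a time, and is a direct
#' proxy for manufacturing cost. Probes are synthesized 3' to 5' by default
#' (the direction is configurable since the platform convention is not
#' universal); a probe of length L needs between L and 4L cycles.
#'
#' @param seqs Character vector of probe sequences over `A,C,G,T`.
#' @param cycle_order Base delivery order, a permutation of `"ACGT"`.
#' @param direction `"3to5"` (default: synthesis starts at the probe's 3'
#'   end, i.e. the reversed sequence is walked) or `"5to3"` (the sequence is
#'   walked as given).
#' @return Integer vector of cycle counts.
#' @examples
#' synthesis_cycles("AAAA")                     # 13: A delivered at 1,5,9,13
#' synthesis_cycles("ACGT", direction = "5to3") # 4
#' @export
synthesis_cycles <- function(seqs, cycle_order = "ACGT",
                             direction = c("3to5", "5to3")) {
  direction <- match.arg(direction)
  ord <- strsplit(cycle_order, "", fixed = TRUE)[[1L]]
  if (length(ord) != 4L || !setequal(ord, c("A", "C", "G", "T")))
    stop("cycle_order must be a permutation of ACGT")
  vapply(seqs, function(s) {
    if (grepl("[^ACGT]", s))
      stop("probe contains a non-ACGT character: cycles are undefined")
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    if (direction == "3to5") chars <- rev(chars)
    p <- match(chars, ord)
    # first base waits for its first delivery; each later base waits
    # ((gap to previous base's slot) mod 4) + 1 further cycles
    as.integer(p[1L] + sum(((diff(p) - 1L) %% 4L) + 1L))
  }, integer(1), USE.NAMES = FALSE)
}
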