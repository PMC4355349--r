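# Unified nearest-neighbor stack parameters for DNA/DNA duplexes
# (dH kcal/mol, dS cal/(mol K)); symmetric stacks share one entry via
# reverse-complement lookup at table build time.
nn_stack_table <- local({
  dH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
          CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  dS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
          CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  rc <- function(d) chartr("ACGT", "TGCA", paste0(substr(d, 2, 2), substr(d, 1, 1)))
  H <- S <- numeric(length(dinucs)); names(H) <- names(S) <- dinucs
  for (d in dinucs) {
    key <- if (d %in% names(dH)) d else rc(d)
    H[d] <- dH[[key]]; S[d] <- dS[[key]]
  }
  list(dH = H, dS = S,
       # duplex initiation per terminal base
       init_dH = c(A = 2.3, T = 2.3, C = 0.1, G = 0.1),
       init_dS = c(A = 4.1, T = 4.1, C = -2.8, G = -2.8))
})

GAS_CONSTANT <- 1.987  # cal/(mol K)

#' GC content of a sequence
#'
#' @param seq Character scalar over `A`, `C`, `G`, `T` (no ambiguity codes:
#'   a probe sequence must be fully specified).
#' @return GC percentage: `100 * (G + C) / length`.
#' @export
gc_percent <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq))
    stop("gc_percent requires an unambiguous sequence over A/C/G/T")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

#' Oligonucleotide melting temperature
#'
#' Two methods are available. `"nearest_neighbor"` (the default) sums
#' unified dinucleotide stack enthalpies/entropies plus terminal initiation
#' terms and evaluates
#' `Tm = 1000 * dH / (dS + 0.368 * (N - 1) * log(Na) + R * log(C_T / 4)) - 273.15`
#' with `N` the oligo length, `Na` the monovalent salt molarity and `C_T`
#' the total oligo molarity (non-self-complementary duplex). `"gc_rule"` is
#' the quick formula `64.9 + 41 * (gc_count - 16.4) / length`.
#'
#' @param seq Character scalar over `A`, `C`, `G`, `T`.
#' @param method `"nearest_neighbor"` or `"gc_rule"`.
#' @param salt_molar Monovalent cation concentration (mol/L), default 0.05.
#' @param oligo_molar Total oligo concentration (mol/L), default 0.25 uM.
#' @return Melting temperature in degrees Celsius.
#' @export
melting_temp <- function(seq, method = c("nearest_neighbor", "gc_rule"),
                         salt_molar = 0.05, oligo_molar = 2.5e-7) {
  method <- match.arg(method)
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq))
    stop("melting_temp requires an unambiguous sequence over A/C/G/T")
  n <- nchar(seq)
  if (method == "gc_rule") {
    gc_count <- n * gc_percent(seq) / 100
    return(64.9 + 41 * (gc_count - 16.4) / n)
  }
  if (n < 8L) stop("nearest_neighbor method requires length >= 8")
  stacks <- substring(seq, 1:(n - 1L), 2:n)
  dH <- sum(nn_stack_table$dH[stacks]) +
    nn_stack_table$init_dH[[substr(seq, 1L, 1L)]] +
    nn_stack_table$init_dH[[substr(seq, n, n)]]
  dS <- sum(nn_stack_table$dS[stacks]) +
    nn_stack_table$init_dS[[substr(seq, 1L, 1L)]] +
    nn_stack_table$init_dS[[substr(seq, n, n)]]
  dS_salt <- dS + 0.368 * (n - 1L) * log(salt_molar)
  1000 * dH / (dS_salt + GAS_CONSTANT * log(oligo_molar / 4)) - 273.15
}

#' Probe design parameters
#'
#' @param probe_length Probe length in bases (>= 20); default 50.
#' @param gc_min,gc_max Inclusive GC-content bounds in percent.
#' @param tm_min,tm_max Inclusive melting-temperature bounds in deg C.
#' @param max_probes_per_cluster Cap on probes emitted per cluster.
#' @param consensus_column_threshold Minimum fraction of (non-gap) agreement
#'   for a consensus column to be called; lower-support columns become `N`.
#' @param tile_step Tiling step in bases; defaults to `probe_length`
#'   (end-to-end tiles).
#' @param tm_method,salt_molar,oligo_molar Passed to [melting_temp()].
#' @return An object of class `probe_design_params`.
#' @export
probe_design_params <- function(probe_length = 50L, gc_min = 35, gc_max = 65,
                                tm_min = 55, tm_max = 65,
                                max_probes_per_cluster = 3L,
                                consensus_column_threshold = 0.9,
                                tile_step = probe_length,
                                tm_method = c("nearest_neighbor", "gc_rule"),
                                salt_molar = 0.05, oligo_molar = 2.5e-7) {
  tm_method <- match.arg(tm_method)
  stopifnot(probe_length >= 20L, gc_min <= gc_max, tm_min <= tm_max,
            max_probes_per_cluster >= 1L, tile_step >= 1L,
            tile_step <= probe_length,
            consensus_column_threshold > 0.5, consensus_column_threshold <= 1)
  structure(list(probe_length = as.integer(probe_length),
                 gc_min = gc_min, gc_max = gc_max,
                 tm_min = tm_min, tm_max = tm_max,
                 max_probes_per_cluster = as.integer(max_probes_per_cluster),
                 consensus_column_threshold = consensus_column_threshold,
                 tile_step = as.integer(tile_step),
                 tm_method = tm_method,
                 salt_molar = salt_molar, oligo_molar = oligo_molar),
            class = "probe_design_params")
}

#' Does a candidate probe pass the GC/Tm filters?
#'
#' `TRUE` iff the sequence has no `N`, its GC content lies in
#' `[gc_min, gc_max]` and its melting temperature lies in
#' `[tm_min, tm_max]` (all bounds inclusive). The sequence must have exactly
#' `probe_length` bases.
#'
#' @param seq Candidate probe sequence.
#' @param params A [probe_design_params()] object.
#' @return Logical scalar.
#' @export
passes_filters <- function(seq, params = probe_design_params()) {
  seq <- toupper(seq)
  if (nchar(seq) != params$probe_length)
    stop(sprintf("probe must be exactly %d bases, got %d",
                 params$probe_length, nchar(seq)))
  if (grepl("[^ACGT]", seq)) return(FALSE)
  gc <- gc_percent(seq)
  if (gc < params$gc_min || gc > params$gc_max) return(FALSE)
  tm <- melting_temp(seq, params$tm_method, params$salt_molar,
                     params$oligo_molar)
  tm >= params$tm_min && tm <= params$tm_max
}

# GC/Tm/N-content for every window of width `width` in `seq`, via cumulative
# sums (O(L) per sequence). Returns a data.frame with 0-based offsets;
# windows containing N get NA gc/tm and has_n = TRUE.
window_metrics <- function(seq, width, tm_method = "nearest_neighbor",
                           salt_molar = 0.05, oligo_molar = 2.5e-7) {
  n <- nchar(seq)
  if (n < width)
    return(data.frame(offset = integer(0), window = character(0),
                      gc = numeric(0), tm = numeric(0), has_n = logical(0)))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  offs <- 0:(n - width)
  cum_gc <- cumsum(chars %in% c("G", "C"))
  cum_n <- cumsum(chars == "N")
  win_sum <- function(cum) cum[offs + width] - c(0, cum)[offs + 1L]
  gc_count <- win_sum(cum_gc)
  n_count <- win_sum(cum_n)
  gc <- 100 * gc_count / width
  if (tm_method == "gc_rule") {
    tm <- 64.9 + 41 * (gc_count - 16.4) / width
  } else {
    stacks <- paste0(chars[-n], chars[-1L])
    sH <- nn_stack_table$dH[stacks]; sS <- nn_stack_table$dS[stacks]
    sH[is.na(sH)] <- 0; sS[is.na(sS)] <- 0  # N-containing stacks; masked below
    cH <- cumsum(sH); cS <- cumsum(sS)
    stack_H <- cH[offs + width - 1L] - c(0, cH)[offs + 1L]
    stack_S <- cS[offs + width - 1L] - c(0, cS)[offs + 1L]
    iH <- nn_stack_table$init_dH; iS <- nn_stack_table$init_dS
    ends_first <- chars[offs + 1L]; ends_last <- chars[offs + width]
    dH <- stack_H + ifelse(ends_first == "N", NA, iH[ends_first]) +
      ifelse(ends_last == "N", NA, iH[ends_last])
    dS <- stack_S + ifelse(ends_first == "N", NA, iS[ends_first]) +
      ifelse(ends_last == "N", NA, iS[ends_last])
    dS_salt <- dS + 0.368 * (width - 1L) * log(salt_molar)
    tm <- 1000 * dH / (dS_salt + GAS_CONSTANT * log(oligo_molar / 4)) - 273.15
  }
  has_n <- n_count > 0L
  gc[has_n] <- NA_real_; tm[has_n] <- NA_real_
  data.frame(offset = offs,
             window = substring(seq, offs + 1L, offs + width),
             gc = gc, tm = tm, has_n = has_n, stringsAsFactors = FALSE)
}
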