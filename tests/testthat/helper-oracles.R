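# Independent reference implementations used to check the package's fast
# paths. These are deliberately written as plain, slow R code.

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Full (unbanded) Needleman-Wunsch with the package's scores and the same
# traceback preference (diagonal > up > left), returning score and matches.
oracle_nw <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  S <- matrix(0, n + 1, m + 1)
  S[1, ] <- gap * (0:m); S[, 1] <- gap * (0:n)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(S[i, j] + ifelse(ca[i] == cb[j], match, mismatch),
                           S[i, j + 1] + gap, S[i + 1, j] + gap)
  }
  i <- n; j <- m; matches <- 0
  while (i > 0 || j > 0) {
    diag_ok <- i > 0 && j > 0 &&
      S[i + 1, j + 1] == S[i, j] + ifelse(ca[i] == cb[j], match, mismatch)
    up_ok <- i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap
    if (diag_ok) {
      if (ca[i] == cb[j]) matches <- matches + 1
      i <- i - 1; j <- j - 1
    } else if (up_ok) i <- i - 1 else j <- j - 1
  }
  list(score = S[n + 1, m + 1], matches = matches)
}

oracle_identity <- function(a, b) {
  oracle_nw(a, b)$matches / min(nchar(a), nchar(b))
}

# Brute-force spaced-seed match: every target offset x every anchor within
# the candidate, comparing care positions one by one.
oracle_seed_match <- function(candidate, target, seed) {
  care <- seed$care  # 0-based
  plen <- nchar(seed$pattern)
  cc <- strsplit(candidate, "")[[1]]; tc <- strsplit(target, "")[[1]]
  if (length(tc) < plen || length(cc) < plen) return(FALSE)
  for (anchor in 0:(length(cc) - plen)) {
    for (off in 0:(length(tc) - plen)) {
      if (all(cc[anchor + care + 1] == tc[off + care + 1])) return(TRUE)
    }
  }
  FALSE
}

# Second melting-temperature implementation: per-stack loop over the
# published unified parameter table.
oracle_tm_nn <- function(seq, salt_molar = 0.05, oligo_molar = 2.5e-7) {
  tab <- list(
    AA = c(-7.9, -22.2), TT = c(-7.9, -22.2),
    AT = c(-7.2, -20.4), TA = c(-7.2, -21.3),
    CA = c(-8.5, -22.7), TG = c(-8.5, -22.7),
    GT = c(-8.4, -22.4), AC = c(-8.4, -22.4),
    CT = c(-7.8, -21.0), AG = c(-7.8, -21.0),
    GA = c(-8.2, -22.2), TC = c(-8.2, -22.2),
    CG = c(-10.6, -27.2), GC = c(-9.8, -24.4),
    GG = c(-8.0, -19.9), CC = c(-8.0, -19.9))
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  dH <- 0; dS <- 0
  for (i in 1:(n - 1)) {
    p <- tab[[paste0(chars[i], chars[i + 1])]]
    dH <- dH + p[1]; dS <- dS + p[2]
  }
  for (end in chars[c(1, n)]) {
    if (end %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  dS <- dS + 0.368 * (n - 1) * log(salt_molar)
  1000 * dH / (dS + 1.987 * log(oligo_molar / 4)) - 273.15
}

# Greedy-walk synthesis simulation: step through delivery cycles one at a
# time, coupling the next base whenever its reagent comes around.
oracle_cycles <- function(seq, cycle_order = "ACGT", direction = "3to5") {
  ord <- strsplit(cycle_order, "")[[1]]
  chars <- strsplit(seq, "")[[1]]
  if (direction == "3to5") chars <- rev(chars)
  cycle <- 0; pos <- 1
  while (pos <= length(chars)) {
    cycle <- cycle + 1
    if (ord[((cycle - 1) %% 4) + 1] == chars[pos]) pos <- pos + 1
  }
  cycle
}

# Prescreen-free greedy clustering with unbanded alignment: the reference
# pass the fast clusterer must reproduce.
oracle_greedy_cluster <- function(records, identity_threshold = 0.9,
                                  best_cluster = FALSE) {
  ord <- order(-nchar(records$seq))
  recs <- records[ord, , drop = FALSE]
  reps <- character(0)
  cid <- integer(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    assigned <- NA_integer_; best <- -1
    for (k in seq_along(reps)) {
      idn <- oracle_identity(recs$seq[i], reps[k])
      if (idn >= identity_threshold) {
        if (!best_cluster) { assigned <- k - 1L; break }
        if (idn > best) { best <- idn; assigned <- k - 1L }
      }
    }
    if (is.na(assigned)) {
      reps <- c(reps, recs$seq[i])
      assigned <- length(reps) - 1L
    }
    cid[i] <- assigned
  }
  data.frame(id = recs$id, cluster_id = cid, stringsAsFactors = FALSE)
}

# Adjusted Rand index from the contingency table.
oracle_ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c / choose(n, 2)
  (a - expected) / ((b + c) / 2 - expected)
}

# Two partitions agree (same grouping, labels free)? True iff the label
# contingency table is a bijection.
same_partition <- function(ids1, cid1, ids2, cid2) {
  m <- match(ids1, ids2)
  tab <- table(cid1, cid2[m])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
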