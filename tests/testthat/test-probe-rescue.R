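degap <- function(row) gsub("-", "", row, fixed = TRUE)

test_that("center-star alignment of identical members is gap-free", {
  s <- random_seq(120)
  msa <- center_star_align(setNames(rep(s, 4), paste0("m", 1:4)))
  expect_true(all(msa$rows == s))
  expect_equal(msa$row_ids, paste0("m", 1:4))
})

test_that("two members reduce to the plain pairwise global alignment", {
  set.seed(91)
  a <- random_seq(100); b <- mutate_seq(a, 0.08, 0.01)
  msa <- center_star_align(c(x = a, y = b))
  al <- probecap:::cpp_global_align(a, b, -1L, 1L, -1L, -2L, TRUE)
  # center is one of the two; rows must reproduce the pairwise alignment
  rows <- setNames(msa$rows, msa$row_ids)
  expect_equal(degap(rows[["x"]]), a)
  expect_equal(degap(rows[["y"]]), b)
  score <- function(ra, rb) {
    ca <- strsplit(ra, "")[[1]]; cb <- strsplit(rb, "")[[1]]
    sum(ifelse(ca == "-" | cb == "-", -2, ifelse(ca == cb, 1, -1)))
  }
  expect_equal(score(rows[["x"]], rows[["y"]]), al$score)
})

test_that("merged alignments preserve members and induced pairwise scores", {
  set.seed(92)
  for (trial in 1:5) {
    a <- random_seq(100)
    members <- setNames(c(a, vapply(1:4, function(i)
      mutate_seq(a, runif(1, 0.02, 0.1), 0.01), character(1))),
      paste0("m", 1:5))
    msa <- center_star_align(members)
    expect_equal(length(unique(nchar(msa$rows))), 1L)
    rows <- setNames(msa$rows, msa$row_ids)
    for (id in names(members)) expect_equal(degap(rows[[id]]), members[[id]])

    # induced (center, member) alignments: dropping double-gap columns must
    # restore the independent optimal pairwise score
    idsum <- sapply(seq_along(members), function(i) sum(sapply(
      seq_along(members)[-i], function(j)
        oracle_nw(members[[i]], members[[j]])$matches /
          min(nchar(members[[i]]), nchar(members[[j]])))))
    center_id <- names(members)[which.max(idsum)]
    for (id in setdiff(names(members), center_id)) {
      ca <- strsplit(rows[[center_id]], "")[[1]]
      cm <- strsplit(rows[[id]], "")[[1]]
      keep <- !(ca == "-" & cm == "-")
      induced <- sum(ifelse(ca[keep] == "-" | cm[keep] == "-", -2,
                            ifelse(ca[keep] == cm[keep], 1, -1)))
      expect_equal(induced,
                   oracle_nw(members[[center_id]], members[[id]])$score)
    }
  }
})

test_that("consensus calls columns by support and drops gap-heavy columns", {
  rows <- rep("ACGT", 3)
  cons <- consensus(list(rows = rows), 0.9)
  expect_equal(cons$seq, "ACGT")

  # 10 rows, 9 agree on C: threshold 0.9 is met inclusively
  rows <- c(rep("C", 9), "T")
  expect_equal(consensus(list(rows = rows), 0.9)$seq, "C")
  # 8 of 10: below threshold -> N
  rows <- c(rep("C", 8), "T", "T")
  expect_equal(consensus(list(rows = rows), 0.9)$seq, "N")
  # column with > 50% gaps is dropped entirely
  rows <- c("A-G", "A-G", "ACG", "A-G")
  expect_equal(consensus(list(rows = rows), 0.9)$seq, "AG")

  set.seed(93)
  for (trial in 1:10) {
    n <- sample(4:12, 1); L <- sample(20:60, 1)
    mat <- matrix(sample(c("A", "C", "G", "T", "-"), n * L, TRUE,
                         prob = c(0.3, 0.3, 0.15, 0.15, 0.1)), n, L)
    rows <- apply(mat, 1, paste, collapse = "")
    got <- consensus(list(rows = rows), 0.8)
    want <- character(0)
    for (j in 1:L) {
      col <- mat[, j]
      nongap <- col[col != "-"]
      if (length(nongap) <= n / 2) next
      counts <- table(factor(nongap, levels = c("A", "C", "G", "T")))
      want <- c(want, if (max(counts) / length(nongap) >= 0.8)
        names(counts)[which.max(counts)] else "N")
    }
    expect_equal(got$seq, paste(want, collapse = ""))
  }
})

test_that("tiling offsets follow the step plus the anchored terminal tile", {
  t1 <- tile(random_seq(120), 50, 50)
  expect_equal(t1$offset, c(0L, 50L, 70L))
  expect_equal(tile(random_seq(50), 50, 50)$offset, 0L)
  expect_equal(nrow(tile(random_seq(49), 50, 50)), 0L)
  t2 <- tile(random_seq(100), 50, 50)  # 50 divides exactly: no extra tile
  expect_equal(t2$offset, c(0L, 50L))
  expect_true(all(nchar(t1$window) == 50))
})

test_that("singleton rescue tiles the lone sequence", {
  set.seed(94)
  s <- paste(rep(c("A", "C", "G", "T"), 50), collapse = "")  # 200 nt, GC 50%
  params <- probe_design_params(gc_min = 35, gc_max = 65, tm_min = 0,
                                tm_max = 120, max_probes_per_cluster = 10)
  probes <- design_rescue_probes(list("7" = data.frame(id = "solo", seq = s)),
                                 params)
  expect_equal(nrow(probes), 4L)  # offsets 0, 50, 100, 150
  expect_true(all(probes$stage == "rescue_direct"))
  expect_true(all(probes$source_record == "solo"))
  params3 <- probe_design_params(gc_min = 35, gc_max = 65, tm_min = 0,
                                 tm_max = 120, max_probes_per_cluster = 3)
  expect_equal(nrow(design_rescue_probes(
    list("7" = data.frame(id = "solo", seq = s)), params3)), 3L)
})

test_that("identical members rescue to the tiling of the common sequence", {
  set.seed(95)
  s <- random_seq(180)
  params <- probe_design_params(gc_min = 0, gc_max = 100, tm_min = 0,
                                tm_max = 120, max_probes_per_cluster = 10)
  probes <- design_rescue_probes(
    list("3" = data.frame(id = paste0("m", 1:4), seq = rep(s, 4))), params)
  want <- tile(s, 50, 50)
  expect_equal(probes$offset, want$offset)
  expect_equal(probes$seq, want$window)
  expect_true(all(probes$stage == "rescue_consensus"))
})

test_that("rescue equals the composition of align, consensus, tile and filter", {
  set.seed(96)
  for (trial in 1:4) {
    a <- random_seq(300)
    n <- sample(c(1, 3, 6), 1)
    mem <- data.frame(id = paste0("m", seq_len(n)),
                      seq = vapply(seq_len(n), function(i)
                        if (i == 1) a else mutate_seq(a, 0.02, 0.001),
                        character(1)))
    params <- probe_design_params(gc_min = 30, gc_max = 70, tm_min = 50,
                                  tm_max = 80, max_probes_per_cluster = 5)
    got <- design_rescue_probes(list("0" = mem), params)

    src <- if (n == 1) mem$seq else
      consensus(center_star_align(setNames(mem$seq, mem$id)), 0.9)$seq
    tl <- tile(src, params$probe_length, params$tile_step)
    tl <- tl[!grepl("N", tl$window), , drop = FALSE]
    keep <- vapply(tl$window, passes_filters, logical(1), params = params,
                   USE.NAMES = FALSE)
    want <- head(tl[keep, , drop = FALSE], 5)
    expect_equal(got$offset, want$offset)
    expect_equal(got$seq, want$window)
  }
})

test_that("every rescue probe passes the filters and contains no N", {
  set.seed(97)
  a <- random_seq(400)
  # enough members that the 90% column threshold tolerates single deviations
  mem <- data.frame(id = paste0("m", 1:10),
                    seq = vapply(1:10, function(i) mutate_seq(a, 0.01, 0.001),
                                 character(1)))
  params <- probe_design_params(gc_min = 30, gc_max = 70, tm_min = 50,
                                tm_max = 85, max_probes_per_cluster = 10)
  probes <- design_rescue_probes(list("0" = mem), params)
  expect_gt(nrow(probes), 0L)
  for (w in probes$seq) {
    expect_false(grepl("N", w))
    expect_true(passes_filters(w, params))
  }
})
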