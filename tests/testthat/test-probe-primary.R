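# Independent re-implementation of the primary-design contract used as the
# exhaustive oracle: brute-force matching, independent filters, and the same
# documented selection rule coded from scratch.
oracle_primary <- function(cluster_id, all_clusters, params, seed,
                           member_ids) {
  members <- all_clusters[[cluster_id]]
  foreign <- unlist(all_clusters[setdiff(names(all_clusters), cluster_id)],
                    use.names = FALSE)
  cand <- NULL
  for (j in seq_along(members)) {
    s <- members[[j]]
    if (nchar(s) < params$probe_length) next
    for (o in 0:(nchar(s) - params$probe_length)) {
      w <- substr(s, o + 1, o + params$probe_length)
      if (grepl("N", w)) next
      gc <- 100 * lengths(regmatches(w, gregexpr("[GC]", w))) / nchar(w)
      if (gc < params$gc_min || gc > params$gc_max) next
      tm <- oracle_tm_nn(w, params$salt_molar, params$oligo_molar)
      if (tm < params$tm_min || tm > params$tm_max) next
      if (any(vapply(foreign, oracle_seed_match, logical(1),
                     candidate = w, seed = seed))) next
      cov <- sum(vapply(members, oracle_seed_match, logical(1),
                        candidate = w, seed = seed))
      cand <- rbind(cand, data.frame(source_record = member_ids[j],
                                     offset = o, seq = w, coverage = cov,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(cand)) return(cand)
  picked <- integer(0)
  while (length(picked) < params$max_probes_per_cluster &&
         length(picked) < nrow(cand)) {
    rem <- setdiff(seq_len(nrow(cand)), picked)
    mind <- if (length(picked) == 0) rep(Inf, length(rem))
    else vapply(rem, function(i) min(abs(cand$offset[i] - cand$offset[picked])),
                numeric(1))
    o <- order(-cand$coverage[rem], -mind, cand$offset[rem], cand$seq[rem],
               cand$source_record[rem])
    picked <- c(picked, rem[o[1]])
  }
  out <- cand[picked, , drop = FALSE]
  rownames(out) <- NULL
  out
}

test_that("a cluster of identical sequences yields the full per-cluster quota", {
  set.seed(81)
  s <- random_seq(200)
  all_clusters <- list("0" = rep(s, 5))
  params <- probe_design_params(gc_min = 0, gc_max = 100, tm_min = 0,
                                tm_max = 120)
  probes <- design_primary_probes("0", all_clusters, params)
  expect_equal(nrow(probes), params$max_probes_per_cluster)
  expect_true(all(probes$coverage == 5L))
  expect_true(all(probes$stage == "primary"))
  expect_true(all(nchar(probes$seq) == 50L))
})

test_that("a cluster whose windows all fail the GC bounds yields no probes", {
  all_clusters <- list("0" = rep(strrep("AT", 100), 3))
  probes <- design_primary_probes("0", all_clusters, probe_design_params())
  expect_equal(nrow(probes), 0L)
  expect_gt(attr(probes, "rejections")[["gc_out"]], 0L)
})

test_that("primary design equals the exhaustive brute-force oracle", {
  set.seed(82)
  seed <- build_seed(10, 2, 4)
  mk_fam <- function(n, len, div) {
    a <- random_seq(len)
    vapply(seq_len(n), function(i) mutate_seq(a, div), character(1))
  }
  for (trial in 1:3) {
    all_clusters <- list("0" = mk_fam(3, 100, 0.03),
                         "1" = mk_fam(3, 100, 0.05),
                         "2" = mk_fam(3, 100, 0.02))
    ids <- lapply(all_clusters, function(x) paste0("m", seq_along(x)))
    params <- if (trial == 1)
      probe_design_params(gc_min = 0, gc_max = 100, tm_min = 0, tm_max = 120)
    else probe_design_params(gc_min = 30, gc_max = 70, tm_min = 50,
                             tm_max = 80)
    for (cc in names(all_clusters)) {
      got <- design_primary_probes(cc, all_clusters, params, seed,
                                   member_ids = ids[[cc]])
      want <- oracle_primary(cc, all_clusters, params, seed, ids[[cc]])
      if (is.null(want)) {
        expect_equal(nrow(got), 0L)
      } else {
        expect_equal(got[c("source_record", "offset", "seq", "coverage")],
                     want, info = paste("trial", trial, "cluster", cc))
      }
    }
  }
})

test_that("every emitted primary probe is specific by brute-force scan", {
  set.seed(83)
  d <- generate_dataset(5, 4, 300, 0.03, 0.001)
  cl <- greedy_cluster(d$records)
  mem <- probecap:::oriented_members(cl, d$records)
  all_clusters <- lapply(mem, function(df) df$seq)
  seed <- build_seed()
  params <- probe_design_params(gc_min = 20, gc_max = 80, tm_min = 40,
                                tm_max = 90)
  for (cc in names(all_clusters)) {
    probes <- design_primary_probes(cc, all_clusters, params, seed,
                                    member_ids = mem[[cc]]$id)
    foreign <- unlist(all_clusters[setdiff(names(all_clusters), cc)],
                      use.names = FALSE)
    for (w in probes$seq) {
      expect_false(any(vapply(foreign, oracle_seed_match, logical(1),
                              candidate = w, seed = seed)))
    }
    expect_lte(nrow(probes), params$max_probes_per_cluster)
    for (w in probes$seq) expect_true(passes_filters(w, params))
  }
})

test_that("primary design is deterministic", {
  set.seed(84)
  a <- random_seq(250)
  all_clusters <- list("0" = c(a, mutate_seq(a, 0.04), mutate_seq(a, 0.04)),
                       "1" = random_seq(250))
  params <- probe_design_params(gc_min = 20, gc_max = 80, tm_min = 40,
                                tm_max = 90)
  p1 <- design_primary_probes("0", all_clusters, params)
  p2 <- design_primary_probes("0", all_clusters, params)
  expect_identical(p1, p2)
})

test_that("adding a duplicate member never decreases coverage", {
  set.seed(85)
  seed <- build_seed()
  a <- random_seq(200)
  members <- c(a, mutate_seq(a, 0.05), mutate_seq(a, 0.08))
  for (i in 1:10) {
    o <- sample(150, 1)
    cand <- substr(a, o, o + 49)
    expect_gte(score_coverage(cand, c(members, members[1]), seed),
               score_coverage(cand, members, seed))
  }
})
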