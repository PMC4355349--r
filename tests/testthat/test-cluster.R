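test_that("pairwise identity matches forced small cases", {
  p <- clustering_params()
  expect_equal(pairwise_identity("ACGTACGTAC", "ACGTACGTAC", p),
               list(identity = 1.0, strand = "+"))
  expect_equal(pairwise_identity("ACGTACGTAC", "ACGTACGTAT", p)$identity, 0.9)
})

test_that("banded identity equals the unbanded DP oracle when the alignment fits the band", {
  set.seed(21)
  p <- clustering_params(band_width = 60)
  for (i in 1:40) {
    a <- random_seq(60)
    b <- if (i %% 2 == 0) random_seq(60) else mutate_seq(a, runif(1, 0, 0.2))
    got <- pairwise_identity(a, b, p)$identity
    expect_equal(got, oracle_identity(a, b), info = paste("pair", i))
  }
})

test_that("reverse-complement pairs are recognised on the minus strand", {
  set.seed(3)
  a <- random_seq(120)
  p <- clustering_params(both_strands = TRUE)
  rc <- probecap:::reverse_complement(a)
  res <- pairwise_identity(rc, a, p)
  expect_equal(res$identity, 1.0)
  expect_equal(res$strand, "-")
  # without strand comparison the pair looks unrelated
  expect_lt(pairwise_identity(rc, a, clustering_params())$identity, 0.6)
})

test_that("word prescreen passes identical pairs and rejects word-free pairs", {
  p <- clustering_params()
  s <- random_seq(100)
  expect_true(word_prescreen(s, s, p))
  expect_false(word_prescreen(strrep("A", 50), strrep("C", 50), p))
})

test_that("word prescreen never rejects a pair at or above the identity threshold", {
  set.seed(77)
  p <- clustering_params()
  n_checked <- 0L
  for (i in 1:300) {
    a <- random_seq(sample(60:400, 1))
    b <- mutate_seq(a, runif(1, 0, 0.12), runif(1, 0, 0.004))
    idn <- pairwise_identity(a, b, clustering_params(band_width = 500))$identity
    if (idn >= p$identity_threshold) {
      n_checked <- n_checked + 1L
      expect_true(word_prescreen(a, b, p), info = paste("pair", i))
    }
  }
  expect_gt(n_checked, 100L)  # the property was actually exercised
})

test_that("greedy clustering handles forced small configurations", {
  s <- random_seq(200)
  recs <- data.frame(id = paste0("r", 1:5), seq = rep(s, 5))
  cl <- greedy_cluster(recs)
  expect_equal(cl$n_clusters, 1L)
  expect_equal(nrow(cl$assignments), 5L)
  expect_true(all(cl$assignments$identity == 1))

  set.seed(5)
  a <- random_seq(300)
  recs <- data.frame(id = c("a", "b", "c"),
                     seq = c(a, mutate_seq(a, 0.05), random_seq(300)))
  cl <- greedy_cluster(recs)
  expect_equal(cl$n_clusters, 2L)
  expect_equal(nrow(greedy_cluster(recs[0, ])$assignments), 0L)
})

test_that("clustering output is a partition with stored identities above threshold", {
  set.seed(9)
  d <- generate_dataset(5, 8, 400, 0.03, 0.001)
  cl <- greedy_cluster(d$records)
  a <- cl$assignments
  expect_setequal(a$id, d$records$id)            # no loss
  expect_equal(anyDuplicated(a$id), 0L)          # no duplication
  expect_true(all(a$identity >= cl$params$identity_threshold))
  reps <- a[a$is_representative, ]
  expect_equal(nrow(reps), cl$n_clusters)
  expect_true(all(reps$identity == 1.0 & reps$strand == "+"))
  # one representative per cluster, and it is the longest member
  for (cc in unique(a$cluster_id)) {
    mem <- a[a$cluster_id == cc, ]
    expect_equal(sum(mem$is_representative), 1L)
    expect_equal(max(mem$length), mem$length[mem$is_representative])
  }
})

test_that("prescreen and banding do not change the greedy partition", {
  set.seed(33)
  for (rep in 1:6) {
    d <- generate_dataset(n_families = sample(3:6, 1),
                          members_per_family = sample(3:8, 1),
                          ancestor_length = sample(200:400, 1),
                          within_divergence = runif(1, 0.01, 0.06),
                          indel_rate = 0.001)
    cl <- greedy_cluster(d$records)
    ref <- oracle_greedy_cluster(d$records)
    expect_true(same_partition(cl$assignments$id, cl$assignments$cluster_id,
                               ref$id, ref$cluster_id),
                info = paste("instance", rep))
  }
})

test_that("best_cluster assignment picks the highest-identity cluster", {
  set.seed(13)
  a <- random_seq(300)
  b <- mutate_seq(a, 0.08)          # close to a but below c's identity
  probe <- mutate_seq(b, 0.02)      # much closer to b than to a
  recs <- data.frame(id = c("a", "b", "x"), seq = c(a, b, probe))
  cl_first <- greedy_cluster(recs, clustering_params(identity_threshold = 0.85))
  cl_best <- greedy_cluster(recs, clustering_params(identity_threshold = 0.85,
                                                    best_cluster = TRUE))
  ax <- cl_best$assignments
  expect_equal(ax$cluster_id[ax$id == "x"], ax$cluster_id[ax$id == "b"])
  expect_gte(ax$identity[ax$id == "x"],
             cl_first$assignments$identity[cl_first$assignments$id == "x"])
})

test_that(".clstr output round-trips through the parser", {
  set.seed(17)
  d <- generate_dataset(4, 5, 300, 0.04, 0.001)
  cl <- greedy_cluster(d$records)
  f <- withr::local_tempfile(fileext = ".clstr")
  write_clstr(cl, f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, ">Cluster")), cl$n_clusters)
  expect_equal(sum(endsWith(lines, "*")), cl$n_clusters)
  back <- read_clstr(f)
  a <- cl$assignments[order(cl$assignments$id), ]
  b <- back[order(back$id), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(b$cluster_id, a$cluster_id)
  expect_equal(b$identity, a$identity, tolerance = 1e-6)
  expect_equal(b[c("id", "strand", "is_representative", "length")],
               a[c("id", "strand", "is_representative", "length")])
})
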