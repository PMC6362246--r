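test_that("pairwise identity handles identity and containment cases", {
  a <- rand_dna(100)
  r <- pairwise_identity(a, a)
  expect_equal(r$identity, 1)
  expect_equal(r$aligned_len, 100)
  expect_equal(r$coverage_short, 1)
  sub <- substr(a, 26, 75)
  r2 <- pairwise_identity(a, sub)
  expect_equal(r2$identity, 1)
  expect_equal(r2$coverage_short, 1)
  expect_error(pairwise_identity("", a), "non-empty")
})

test_that("pairwise identity matches the dynamic-programming oracle", {
  set.seed(31)
  # related pairs: the optimum is essentially unique, full stats compare
  for (i in 1:5) {
    a <- rand_dna(200)
    chars <- strsplit(a, "", fixed = TRUE)[[1]]
    mut <- sample(200, 8)
    for (m in mut) chars[m] <- sample(setdiff(c("A", "C", "G", "T"),
                                              chars[m]), 1)
    b <- paste(substr(paste(chars, collapse = ""), 11, 190), collapse = "")
    got <- pairwise_identity(a, b)
    want <- oracle_local_align(a, b)
    expect_equal(got$identity, want$matches / want$columns)
    expect_equal(got$aligned_len, want$columns)
    expect_equal(got$coverage_short,
                 (want$b_span[2] - want$b_span[1] + 1) / nchar(b))
  }
  # unrelated pairs: compare the (unique) optimal score
  for (i in 1:5) {
    a <- rand_dna(200); b <- rand_dna(200)
    aln <- larvaseq:::align_pair(a, b, "local")
    expect_equal(Biostrings::score(aln), oracle_local_align(a, b)$score)
  }
})

test_that("greedy clustering obeys identity, coverage and containment", {
  a <- rand_dna(300)
  three <- c(s1 = a, s2 = a, s3 = a)
  cl <- greedy_cluster(three, cluster_params(0.95, 0.9))
  expect_equal(length(cl$clusters), 1L)
  expect_setequal(cl$clusters[[1]], names(three))

  set.seed(77)
  u <- c(x = rand_dna(300), y = rand_dna(300))
  # oracle: best local identity between unrelated 300-mers is far below 0.8
  o <- oracle_local_align(u[["x"]], u[["y"]])
  expect_lt(o$matches / max(o$columns, 150), 0.8)
  cl2 <- greedy_cluster(u, cluster_params(0.80, 0.80))
  expect_equal(length(cl2$clusters), 2L)

  big <- rand_dna(1000)
  pair <- c(long = big, frag = substr(big, 451, 550))
  cl3 <- greedy_cluster(pair, cluster_params(0.95, 0.9))
  expect_equal(length(cl3$clusters), 1L)  # coverage of shorter = 1

  # reverse-complement members still cluster
  rcpair <- c(fwd = big, rev = rc(big))
  cl4 <- greedy_cluster(rcpair, cluster_params(0.95, 0.9))
  expect_equal(length(cl4$clusters), 1L)
})

test_that("automatic merge parameters follow the length-based formulas", {
  m100 <- auto_merge_params(setNames(rep(strrep("A", 100), 3),
                                     paste0("s", 1:3)), 0.99)
  expect_equal(m100$min_overlap, 21L)  # floor binds: 0.05*100 = 5
  m1000 <- auto_merge_params(setNames(rep(strrep("A", 1000), 3),
                                      paste0("s", 1:3)), 0.80)
  expect_equal(m1000$min_overlap, 50L)
  expect_equal(m1000$max_clip, 20L)
  expect_equal(m1000$overlap_identity, 0.80)
  single <- auto_merge_params(c(s = strrep("A", 500)), 0.99)
  expect_s3_class(single, "merge_params")
})

test_that("end-overlap merging joins, respects thresholds, collapses", {
  set.seed(5)
  x <- rand_dna(150)
  s1 <- substr(x, 1, 100); s2 <- substr(x, 71, 150)  # exact 30-nt overlap
  mg <- merge_cluster(c(a = s1, b = s2), merge_params(21, 0.99, 0))
  expect_equal(length(mg$seqs), 1L)
  expect_equal(nchar(mg$seqs[[1]]), 150L)  # 100 + 80 - 30
  expect_equal(unname(mg$seqs[[1]]), x)
  expect_setequal(mg$members[[1]], c("a", "b"))

  # overlap below min_overlap: no merge
  y <- rand_dna(200)
  t1 <- substr(y, 1, 100); t2 <- substr(y, 86, 200)  # 15-nt overlap
  mg2 <- merge_cluster(c(a = t1, b = t2), merge_params(21, 0.99, 0))
  expect_equal(length(mg2$seqs), 2L)

  # identical sequences collapse to one
  mg3 <- merge_cluster(c(a = x, b = x), merge_params(21, 0.99, 0))
  expect_equal(length(mg3$seqs), 1L)
  expect_equal(unname(mg3$seqs[[1]]), x)

  # reverse-complement overlap is found
  mg4 <- merge_cluster(c(a = s1, b = rc(s2)), merge_params(21, 0.99, 0))
  expect_equal(length(mg4$seqs), 1L)
  expect_equal(nchar(mg4$seqs[[1]]), 150L)
})

test_that("zero-noise redundant set reduces to one contig per gene", {
  cfg <- sim_config(seed = 2, n_genes = 5, copies_per_gene = 4,
                    isoform_rate = 0, point_mutation_rate = 0,
                    truncation_fraction = 0, utr_noise_len = 0)
  gt <- generate_redundant_transcripts(cfg)
  expect_equal(length(gt$transcripts), 25L)
  rs <- run_schedule(gt$transcripts)
  expect_equal(length(rs$contigs), 5L)
  expect_equal(length(unique(rs$gene_groups$gene)), 5L)
  # no-loss: every input appears exactly once in the membership map
  expect_setequal(rs$members$input_id, names(gt$transcripts))
  expect_equal(anyDuplicated(rs$members$input_id), 0L)
  # recovered groups match the truth partition exactly
  truth <- setNames(gt$truth$gene_id, gt$truth$contig_id)
  pred <- setNames(rs$members$gene, rs$members$input_id)
  expect_equal(length(unique(paste(truth[names(pred)], pred))), 5L)
})

test_that("divergent genes are never merged and schedules are idempotent", {
  set.seed(13)
  two <- c(g1 = rand_dna(600), g2 = rand_dna(600))
  o <- oracle_local_align(two[["g1"]], two[["g2"]])
  expect_lt(o$matches / max(o$columns, 300), 0.8)  # oracle identity bound
  rs <- run_schedule(two)
  expect_equal(length(rs$contigs), 2L)
  expect_equal(length(unique(rs$gene_groups$gene)), 2L)
  # idempotence: reducing the output changes nothing
  rs2 <- run_schedule(rs$contigs)
  expect_equal(sort(unname(rs2$contigs)), sort(unname(rs$contigs)))
  # single sequence passes through unchanged
  solo_seq <- rand_dna(500)
  one <- run_schedule(c(solo = solo_seq))
  expect_equal(length(one$contigs), 1L)
  expect_equal(unname(one$contigs[[1]]), solo_seq)
  expect_equal(names(one$contigs), "solo")
})

test_that("truncated mutated copies are recovered to their true genes", {
  cfg <- sim_config(seed = 11, n_genes = 8, copies_per_gene = 3,
                    isoform_rate = 0, point_mutation_rate = 0.02,
                    truncation_fraction = 0.3, utr_noise_len = 0)
  gt <- generate_redundant_transcripts(cfg)
  rs <- run_schedule(gt$transcripts)
  truth <- setNames(gt$truth$gene_id, gt$truth$contig_id)
  pred <- setNames(rs$members$gene, rs$members$input_id)
  ids <- names(truth)
  expect_gte(mclust::adjustedRandIndex(truth[ids], pred[ids]), 0.95)
})
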