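test_that("zero-noise generation duplicates the reference exactly", {
  cfg <- sim_config(seed = 4, n_genes = 1, copies_per_gene = 1,
                    isoform_rate = 0, point_mutation_rate = 0,
                    truncation_fraction = 0, utr_noise_len = 0)
  gt <- generate_redundant_transcripts(cfg)
  expect_equal(length(gt$transcripts), 2L)
  expect_equal(unname(gt$transcripts[[1]]), unname(gt$transcripts[[2]]))
  expect_equal(unique(gt$truth$gene_id), "gene001")
  # truth closure: one row per emitted contig
  expect_setequal(gt$truth$contig_id, names(gt$transcripts))
})

test_that("mutated copies stay close to their reference", {
  cfg <- sim_config(seed = 7, n_genes = 5, copies_per_gene = 3,
                    isoform_rate = 0, point_mutation_rate = 0.01,
                    truncation_fraction = 0, utr_noise_len = 0)
  gt <- generate_redundant_transcripts(cfg)
  expect_equal(length(gt$transcripts), 20L)
  # within-gene pairwise identity >= 0.95, checked by the DP oracle
  for (g in unique(gt$truth$gene_id)) {
    ids <- gt$truth$contig_id[gt$truth$gene_id == g]
    pick <- combn(ids, 2)[, 1:2, drop = FALSE]  # two pairs per gene
    for (k in seq_len(ncol(pick))) {
      o <- oracle_local_align(gt$transcripts[[pick[1, k]]],
                              gt$transcripts[[pick[2, k]]])
      expect_gte(o$matches / o$columns, 0.95)
    }
  }
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 7, n_genes = 3)
  a <- generate_redundant_transcripts(cfg)
  b <- generate_redundant_transcripts(cfg)
  expect_identical(a, b)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(a$transcripts, f1)
  write_fasta(b$transcripts, f2)
  expect_identical(readLines(f1), readLines(f2))
  # counts and variants are deterministic too
  expect_identical(simulate_stage_counts(cfg),
                   simulate_stage_counts(cfg))
  expect_identical(simulate_variants(a$transcripts, cfg),
                   simulate_variants(a$transcripts, cfg))
})

test_that("simulated counts match the NB moment formulas", {
  cfg <- sim_config(seed = 21, n_genes = 1000, baseline_mean = 100,
                    dispersion = 0.1, de_fraction = 0)
  sim <- simulate_stage_counts(cfg)
  x <- as.vector(sim$cm$counts)
  n <- length(x)
  mom <- oracle_nb_moments(100, 0.1)
  # sample mean within 3 standard errors of the true mean
  expect_lt(abs(mean(x) - mom$mean), 3 * sqrt(mom$var / n))
  # sample variance within 3 SEs of mu + phi mu^2 = 1100 (so var/mean
  # ratio consistent with 1 + phi mu = 11)
  se_var <- sqrt((mom$mu4 - mom$var^2) / n)
  expect_lt(abs(var(x) - mom$var), 3 * se_var)
  expect_equal(nrow(sim$truth), 0L)
})

test_that("planted fold-changes shift the planted stage mean", {
  cfg <- sim_config(seed = 22, n_genes = 2000, baseline_mean = 100,
                    de_fraction = 0.001, fold_change = 8)
  sim <- simulate_stage_counts(cfg)
  expect_equal(nrow(sim$truth), 2L)
  for (i in seq_len(nrow(sim$truth))) {
    y <- sim$cm$counts[sim$truth$gene[i], sim$truth$stage[i]]
    expected <- if (sim$truth$direction[i] == "up") 800 else 12.5
    # NB sd at mu=800 is ~264; a single draw stays within 4 sd
    expect_lt(abs(y - expected), 4 * sqrt(expected + 0.1 * expected^2) + 5)
  }
})

test_that("spiked contaminants are counted and flagged in the hit table", {
  tset <- c(h1 = rand_dna(500), h2 = rand_dna(500))
  none <- spike_contaminants(tset, 0, seed = 3)
  expect_equal(length(none$transcripts), 2L)
  expect_equal(sum(none$hits$subject_group == "other"), 0L)
  sp <- spike_contaminants(tset, 3, seed = 3)
  expect_equal(length(sp$contaminant_ids), 3L)
  expect_equal(sum(sp$hits$subject_group == "other"), 3L)
  con <- sp$hits[sp$hits$subject_group == "other", ]
  expect_true(all(con$query_coverage > 0.7))
  expect_true(all(con$percent_identity > 80))
})

test_that("variant simulation hits its configured class rates", {
  set.seed(1)
  contigs <- setNames(replicate(100, rand_dna(1000)), sprintf("c%03d", 1:100))
  cfg <- sim_config(seed = 11, snv_density = 30, tstv_ratio = 1.5,
                    indel_fraction = 0.05)
  v <- simulate_variants(contigs, cfg, seed = 11)
  cls <- classify_variant(v$ref, v$alt)
  ts <- sum(cls == "transition"); tv <- sum(cls == "transversion")
  # realized Ts fraction within the 99% binomial band around 0.6
  band <- qbinom(c(0.005, 0.995), ts + tv, 1.5 / 2.5)
  expect_gte(ts, band[1]); expect_lte(ts, band[2])
  # realized total count within the 99% Poisson band around 3000
  pband <- qpois(c(0.005, 0.995), 100 * 30)
  expect_gte(nrow(v), pband[1]); expect_lte(nrow(v), pband[2])
  # positions unique per contig
  expect_false(any(duplicated(v[, c("contig", "pos")])))
  # density 0 -> no variants
  cfg0 <- sim_config(seed = 11, snv_density = 0)
  expect_equal(nrow(simulate_variants(contigs, cfg0)), 0L)
  # tstv -> infinity limit: no transversions among SNVs
  cfgInf <- sim_config(seed = 12, snv_density = 1, tstv_ratio = 1e6,
                       indel_fraction = 0)
  vInf <- simulate_variants(contigs, cfgInf)
  expect_gt(nrow(vInf), 20)
  expect_false(any(classify_variant(vInf$ref, vInf$alt) == "transversion"))
})

test_that("annotation fixture is closed over its ontology and plantable", {
  genes <- sprintf("g%03d", 1:100)
  ann <- generate_annotation(genes, n_terms = 40, terms_per_gene = 3,
                             planted_term = "GO:9999999",
                             planted_genes = genes[1:10], seed = 5)
  expect_true(all(ann$annotation$term %in% ann$terms$term))
  planted <- ann$annotation[ann$annotation$term == "GO:9999999", ]
  expect_setequal(planted$gene, genes[1:10])
  # empty annotation cases
  empty <- generate_annotation(genes, n_terms = 10, terms_per_gene = 0)
  expect_equal(nrow(empty$annotation), 0L)
  expect_error(generate_annotation(genes, planted_term = "GO:1",
                                   planted_genes = "nope"), "subset")
})

test_that("a planted term dominates a full enrichment run", {
  genes <- sprintf("g%03d", 1:100)
  ann <- generate_annotation(genes, n_terms = 40, terms_per_gene = 3,
                             planted_term = "GO:9999999",
                             planted_genes = genes[1:10], seed = 6)
  rows <- go_enrich(test = genes[1:10], reference = genes, ann = ann)
  top <- rows[which.min(rows$p_value), ]
  expect_equal(top$term, "GO:9999999")
  expect_gte(top$ratio, 1.5)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(point_mutation_rate = 1.2), "fraction")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(fold_change = 1), "fold_change")
  expect_error(sim_config(gene_length = 100), "300")
})
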