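toy_ann <- function(map) {
  # map: named list gene -> character vector of terms
  ann <- do.call(rbind, lapply(names(map), function(g)
    if (length(map[[g]]) > 0)
      data.frame(gene = g, term = map[[g]], stringsAsFactors = FALSE)))
  terms <- sort(unique(ann$term))
  list(annotation = ann,
       terms = data.frame(term = terms, name = terms,
                          namespace = rep("biological_process",
                                          length(terms)),
                          stringsAsFactors = FALSE))
}

test_that("the worked hypergeometric example reproduces exactly", {
  # reference of 20 genes, 5 carry term T; test of 5 genes, 4 carry T
  ref <- sprintf("g%02d", 1:20)
  carriers <- ref[c(1:4, 6)]
  ann <- toy_ann(setNames(lapply(ref, function(g)
    if (g %in% carriers) "T" else character(0)), ref))
  rows <- go_enrich(test = ref[1:5], reference = ref, ann = ann)
  expect_equal(rows$ratio, (4 / 5) / (5 / 20))
  expect_equal(rows$p_value, 76 / 15504)
  expect_equal(rows$k_test, 4L)
  expect_equal(rows$k_ref, 5L)
})

test_that("enrichment p-values equal exhaustive tail enumeration", {
  set.seed(16)
  for (N in c(12, 20, 30)) {
    for (rep in 1:10) {
      K <- sample(1:N, 1)
      n <- sample(1:N, 1)
      genes <- sprintf("x%02d", 1:N)
      carriers <- sample(genes, K)
      test <- sample(genes, n)
      k <- length(intersect(test, carriers))
      if (k == 0) next
      ann <- toy_ann(setNames(lapply(genes, function(g)
        if (g %in% carriers) "T" else character(0)), genes))
      rows <- go_enrich(test, genes, ann)
      expect_equal(rows$p_value, oracle_hyper_tail(k, K, N, n),
                   tolerance = 1e-12)
    }
  }
})

test_that("identity test set gives unit ratios and p-values", {
  genes <- sprintf("y%02d", 1:15)
  ann <- toy_ann(setNames(lapply(genes, function(g)
    sample(c("A", "B"), 1)), genes))
  rows <- go_enrich(genes, genes, ann)
  expect_true(all(rows$ratio == 1))
  expect_true(all(rows$p_value == 1))
  # a term absent from the test set produces no row
  ann2 <- toy_ann(list(a = "T1", b = "T2"))
  rows2 <- go_enrich("a", c("a", "b"), ann2)
  expect_equal(rows2$term, "T1")
  # test must be inside the reference
  expect_error(go_enrich("z", genes, ann), "subset")
})

test_that("term filtering applies both cutoffs with stated boundaries", {
  rows <- data.frame(term = c("a", "b", "c", "d"),
                     k_test = c(4, 5, 10, 10), n_test = 10,
                     k_ref = 10, n_ref = 20,
                     ratio = c(2, 2, 1.49, 1.5),
                     p_value = 0.01, p_adjusted = 0.02,
                     stringsAsFactors = FALSE)
  kept <- filter_terms(rows)
  expect_setequal(kept$term, c("b", "d"))
  expect_equal(nrow(filter_terms(rows[0, ])), 0L)
  # monotone: tightening cutoffs never adds rows
  expect_true(all(filter_terms(rows, 6, 2)$term %in% kept$term))
})

test_that("stage test sets follow the mean and unity rules", {
  tpm <- rbind(g1 = c(10, 1, 1, 0),     # mean 3: stage-1 only
               g2 = c(2, 2, 2, 2),      # flat: nowhere (2 > 2 false)
               g3 = c(1.5, 0.5, 0.5, 0.5))  # mean 0.75: stage-1
  colnames(tpm) <- paste0("s", 1:4)
  degs <- rownames(tpm)
  expect_setequal(stage_test_set(tpm, degs, "s1"), c("g1", "g3"))
  for (s in paste0("s", 2:4))
    expect_equal(length(stage_test_set(tpm, degs, s)), 0L)
  expect_error(stage_test_set(tpm, degs, "nope"), "unknown")
})

test_that("term ranking orders by summed stage TPM of annotated genes", {
  ann <- toy_ann(list(a = "T1", b = "T2", c = "T3", d = "T1"))
  tpm <- matrix(c(30, 30, 20, 20), 4, 1,
                dimnames = list(c("a", "b", "c", "d"), "s1"))
  rows <- data.frame(term = c("T1", "T2", "T3"), name = NA,
                     k_test = 5, n_test = 5, k_ref = 5, n_ref = 5,
                     ratio = 2, p_value = 0.01, p_adjusted = 0.01,
                     stringsAsFactors = FALSE)
  rk <- rank_predominant_terms(rows, ann, tpm, c("a", "b", "c", "d"),
                               "s1", top_k = 2)
  expect_equal(rk$term, c("T1", "T2"))      # 50 then 30
  expect_equal(rk$tpm_total, c(50, 30))
  all_terms <- rank_predominant_terms(rows, ann, tpm, letters[1:4], "s1",
                                      top_k = 10)
  expect_equal(nrow(all_terms), 3L)
})

test_that("enrichment p-values are calibrated on random annotations", {
  # uniform annotations, no planted term: the discrete hypergeometric
  # test is valid (never anti-conservative) and, with well-populated
  # terms, not far below the nominal level either
  set.seed(17)
  genes <- sprintf("g%04d", 1:400)
  hits <- 0; total <- 0
  for (rep in 1:40) {
    ann <- generate_annotation(genes, n_terms = 50, terms_per_gene = 5,
                               seed = 200 + rep)
    rows <- go_enrich(sample(genes, 100), genes, ann)
    hits <- hits + sum(rows$p_value < 0.05)
    total <- total + nrow(rows)
  }
  expect_gte(total, 2000)
  se <- sqrt(0.05 * 0.95 / total)
  expect_lt(hits / total, 0.05 + 3 * se)  # super-uniform at 0.05
  expect_gt(hits / total, 0.01)           # but not degenerate
})
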