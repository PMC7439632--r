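# Small configurations keep these structural tests fast; the full-scale
# planted-signal and null experiments live in test-acceptance.R.
small_cfg <- function(...) {
  benchmark_config(n_proteins = 150, n_diseases = 20,
                   proteins_per_disease = c(3, 20), n_pos = 15, ...)
}

test_that("generation is byte-identical for identical configs and seeds", {
  b1 <- generate_benchmark(small_cfg(seed = 5))
  b2 <- generate_benchmark(small_cfg(seed = 5))
  expect_identical(b1$kg$triples, b2$kg$triples)
  expect_identical(b1$pairs, b2$pairs)
  expect_identical(b1$protein_sets, b2$protein_sets)
  b3 <- generate_benchmark(small_cfg(seed = 6))
  expect_false(identical(b1$kg$triples, b3$kg$triples))
})

test_that("the benchmark files round-trip through the loaders", {
  b <- generate_benchmark(small_cfg(seed = 7))
  dir <- withr::local_tempdir()
  write_benchmark(b, dir)
  kg <- suppressMessages(load_triples(file.path(dir, "triples.tsv")))
  expect_equal(as.data.frame(kg$triples[, c("subject", "predicate", "object")]),
               as.data.frame(b$kg$triples[, c("subject", "predicate", "object")]))
  tab <- load_directionality(file.path(dir, "directionality.tsv"))
  expect_identical(tab$entries, b$directionality$entries)
  pairs <- load_pairs(file.path(dir, "pairs.tsv"))
  expect_equal(as.data.frame(pairs), as.data.frame(b$pairs))
  # the mapping chain reproduces the generator's protein sets
  mapping <- load_concept_mapping(file.path(dir, "mapping.tsv"))
  hierarchy <- load_subclass_hierarchy(file.path(dir, "hierarchy.tsv"))
  assoc <- load_associations(file.path(dir, "associations.tsv"))
  for (code in names(b$protein_sets)[1:5]) {
    expect_identical(assign_disease_proteins(code, mapping, hierarchy, assoc,
                                             quiet = TRUE),
                     b$protein_sets[[code]])
  }
})

test_that("negative modes produce the documented designs", {
  b_rev <- generate_benchmark(small_cfg(seed = 8, negative_mode = "reversal"))
  pos <- b_rev$pairs[b_rev$pairs$label == "positive", ]
  neg <- b_rev$pairs[b_rev$pairs$label == "negative", ]
  expect_equal(nrow(neg), nrow(pos))
  expect_setequal(paste(neg$first, neg$second), paste(pos$second, pos$first))

  b_rnd <- generate_benchmark(small_cfg(seed = 8, negative_mode = "random",
                                        n_neg = 30))
  expect_equal(sum(b_rnd$pairs$label == "negative"), 30)
  keys <- paste(b_rnd$pairs$first, b_rnd$pairs$second)
  expect_false(any(duplicated(keys)))

  b_rw <- generate_benchmark(small_cfg(seed = 8, negative_mode = "rewired",
                                       n_neg = 15))
  posw <- b_rw$pairs[b_rw$pairs$label == "positive", ]
  negw <- b_rw$pairs[b_rw$pairs$label == "negative", ]
  expect_equal(nrow(negw), 15)
  # degree matching: negatives re-pair the positives' diseases side by side
  expect_true(all(negw$first %in% posw$first))
  expect_true(all(negw$second %in% posw$second))

  b_dis <- generate_benchmark(benchmark_config(
    n_proteins = 150, n_diseases = 80, proteins_per_disease = c(3, 20),
    n_pos = 20, negative_mode = "disjoint", n_neg = 20, seed = 9))
  dis <- c(b_dis$pairs$first, b_dis$pairs$second)
  expect_false(any(duplicated(dis)))

  b_apm <- generate_benchmark(small_cfg(seed = 8, negative_mode = "all_pairs_minus"))
  expect_equal(nrow(b_apm$pairs), 20 * 19)
})

test_that("infeasible configurations are rejected", {
  expect_error(benchmark_config(n_proteins = 10, proteins_per_disease = c(5, 60)),
               "infeasible")
  expect_error(benchmark_config(n_diseases = 5, n_pos = 50), "infeasible")
  expect_error(benchmark_config(beta = 1.2), "\\[0, 1\\]")
  expect_error(benchmark_config(n_diseases = 30, n_pos = 20,
                                negative_mode = "disjoint", n_neg = 20),
               "disjoint")
})

test_that("presets approximate the two reference designs", {
  j <- emulate_paper_shape("jensen_like")
  expect_equal(j$negative_mode, "all_pairs_minus")
  # negatives >> positives: all-pairs design gives at least 50 negatives per positive
  expect_gte((j$n_diseases * (j$n_diseases - 1) - j$n_pos) / j$n_pos, 50)
  v <- emulate_paper_shape("vandenakker_like")
  expect_equal(v$n_pos, 55)
  bench <- generate_benchmark(emulate_paper_shape(
    "vandenakker_like", n_proteins = 400, proteins_per_disease = c(4, 40),
    lambda_indirect = 1, seed = 3))
  expect_equal(sum(bench$pairs$label == "positive"), 55)
  expect_equal(sum(bench$pairs$label == "negative"), 370)
  expect_error(emulate_paper_shape("unknown_preset"))
})

test_that("sampled disease set sizes hit the presets' medians within a factor of two", {
  for (preset in c("jensen_like", "vandenakker_like")) {
    cfg <- emulate_paper_shape(preset)
    sizes <- draw_disease_sizes(cfg, n = 1000, seed = 4)
    target <- if (preset == "jensen_like") 29 else 49
    expect_gte(median(sizes), target / 2)
    expect_lte(median(sizes), target * 2)
  }
})

test_that("beta changes orientations only, never edge existence", {
  cfg0 <- small_cfg(seed = 11, beta = 0)
  cfg8 <- small_cfg(seed = 11, beta = 0.8)
  b0 <- generate_benchmark(cfg0)
  b8 <- generate_benchmark(cfg8)
  undirected_key <- function(kg) {
    tr <- as.data.frame(kg$triples)
    sort(paste(pmin(tr$subject, tr$object), tr$predicate,
               pmax(tr$subject, tr$object)))
  }
  expect_identical(undirected_key(b0$kg), undirected_key(b8$kg))
  expect_identical(b0$pairs, b8$pairs)
  expect_identical(b0$protein_sets, b8$protein_sets)
  expect_false(identical(b0$kg$triples, b8$kg$triples))
})

test_that("undirected feature matrices are invariant to beta", {
  for (beta in c(0, 0.5, 1)) {
    b <- generate_benchmark(small_cfg(seed = 12, beta = beta))
    cand <- candidate_pairs(b$pairs, b$protein_sets, quiet = TRUE)
    fm <- build_feature_matrix(cand, b$kg, feature_variant("metapath", "undirected"),
                               b$directionality)
    if (beta == 0) ref <- fm$matrix else expect_identical(as.matrix(fm$matrix),
                                                          as.matrix(ref))
  }
})

test_that("swapping a positive with its reversal mirrors oriented feature incidence", {
  b <- generate_benchmark(small_cfg(seed = 13, beta = 1, negative_mode = "reversal"))
  cand <- candidate_pairs(b$pairs, b$protein_sets, quiet = TRUE)
  fm <- build_feature_matrix(cand, b$kg, feature_variant("split", "mixed"),
                             b$directionality)
  m <- as.matrix(fm$matrix)
  swap <- function(s) {
    tmp <- gsub(":fwd", ":@@", s, fixed = TRUE)
    tmp <- gsub(":rev", ":fwd", tmp, fixed = TRUE)
    gsub(":@@", ":rev", tmp, fixed = TRUE)
  }
  pos_rows <- which(cand$label == "positive")
  for (i in pos_rows[1:5]) {
    twin <- which(cand$first == cand$second[i] & cand$second == cand$first[i])
    expect_length(twin, 1)
    expect_setequal(swap(colnames(m)[m[i, ]]), colnames(m)[m[twin, ]])
  }
})

test_that("mixed-variant AUC increases monotonically with the planted signal strength", {
  aucs <- sapply(c(0, 0.5, 1), function(beta) {
    b <- generate_benchmark(benchmark_config(
      n_proteins = 600, n_diseases = 60, proteins_per_disease = c(4, 30),
      n_pos = 80, negative_mode = "reversal", beta = beta, seed = 17))
    cand <- candidate_pairs(b$pairs, b$protein_sets, quiet = TRUE)
    fm <- build_feature_matrix(cand, b$kg, feature_variant("metapath", "mixed"),
                               b$directionality)
    run_cv(fm, labels = cand$label, folds = 5, repeats = 2, seed = 17,
           num.trees = 150)$mean_auc
  })
  # monotone within simulation error: each step up in beta must not lose more
  # than a couple of AUC points, and the extremes must be clearly ordered
  expect_gt(aucs[3], aucs[1] + 0.1)
  expect_gt(aucs[2], aucs[1] - 0.02)
  expect_gt(aucs[3], aucs[2] - 0.02)
})
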