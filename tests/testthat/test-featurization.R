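fig_variants <- primary_variants()

test_that("signatures of the worked example differ across the four variants exactly as expected", {
  tab <- default_directionality()
  pl <- as_path_list(extract_paths(example_kg(), example_setA(), example_setB()))
  sigs <- lapply(fig_variants, function(v)
    sort(unique(unlist(lapply(pl, path_signatures, variant = v, table = tab)))))
  expect_equal(sigs$metapath_undirected,
               c("direct|inhibits", "indirect|inhibits->inhibits",
                 "overlap", "overlap|binds with"))
  expect_equal(sigs$metapath_mixed,
               c("direct|inhibits:fwd", "indirect|inhibits:fwd->inhibits:fwd",
                 "overlap", "overlap|binds with"))
  expect_equal(sigs$split_undirected,
               c("direct|inhibits", "indirect|inhibits",
                 "overlap", "overlap|binds with"))
  expect_equal(sigs$split_mixed,
               c("direct|inhibits:fwd", "indirect|inhibits:fwd",
                 "overlap", "overlap|binds with"))
  # the loop predicate never carries orientation in undirected/mixed modes
  expect_false(any(grepl("binds with:", unlist(sigs))))
})

test_that("direct paths flip fwd/rev when viewed from the reversed candidate", {
  tab <- default_directionality()
  v <- feature_variant("metapath", "mixed")
  path_ab <- list(scenario = "direct", nodes = c("DP2", "DP4"),
                  edges = data.frame(predicate = "inhibits", orientation = "fwd"))
  path_ba <- list(scenario = "direct", nodes = c("DP4", "DP2"),
                  edges = data.frame(predicate = "inhibits", orientation = "rev"))
  expect_equal(path_signatures(path_ab, v, tab), "direct|inhibits:fwd")
  expect_equal(path_signatures(path_ba, v, tab), "direct|inhibits:rev")
  # undirected mode collapses both views
  vu <- feature_variant("metapath", "undirected")
  expect_equal(path_signatures(path_ab, vu, tab),
               path_signatures(path_ba, vu, tab))
})

test_that("metapath concatenates indirect components; split separates them", {
  tab <- default_directionality()
  path <- list(scenario = "indirect", nodes = c("A", "M", "B"),
               edges = data.frame(predicate = c("inhibits", "inhibits"),
                                  orientation = c("fwd", "rev")))
  expect_equal(path_signatures(path, feature_variant("metapath", "mixed"), tab),
               "indirect|inhibits:fwd->inhibits:rev")
  expect_setequal(path_signatures(path, feature_variant("split", "mixed"), tab),
                  c("indirect|inhibits:fwd", "indirect|inhibits:rev"))
})

test_that("directed mode orients every predicate including loops", {
  tab <- default_directionality()
  vd <- feature_variant("metapath", "directed")
  loop <- list(scenario = "overlap", nodes = "DP1",
               edges = data.frame(predicate = "binds with", orientation = "loop"))
  expect_setequal(path_signatures(loop, vd, tab),
                  c("overlap", "overlap|binds with:loop"))
  bare <- list(scenario = "overlap", nodes = "DP1",
               edges = data.frame(predicate = character(),
                                  orientation = character()))
  expect_equal(path_signatures(bare, vd, tab), "overlap")
})

test_that("feature matrix cells equal naive per-path recomputation", {
  tab <- toy_directionality()
  set.seed(30)
  df <- random_triples(n_proteins = 30, n_triples = 250, loop_prob = 0.06, seed = 30)
  kg <- knowledge_graph(df)
  prot <- sprintf("P%02d", 1:30)
  pairs <- data.frame(first = sprintf("X%02d", 1:12),
                      second = sprintf("Y%02d", 1:12),
                      label = rep(c("positive", "negative"), 6))
  sets <- c(stats::setNames(lapply(1:12, function(i) sample(prot, 5)), pairs$first),
            stats::setNames(lapply(1:12, function(i) sample(prot, 5)), pairs$second))
  cand <- candidate_pairs(pairs, sets, quiet = TRUE)
  paths <- extract_candidate_paths(cand, kg)
  for (v in fig_variants) {
    fm <- featurize_paths(paths, v, tab, labels = cand$label)
    m <- as.matrix(fm$matrix)
    expect_equal(colnames(m), sort(colnames(m)))
    for (i in seq_len(nrow(cand))) {
      naive <- sort(unique(unlist(lapply(as_path_list(paths[[i]]),
                                         path_signatures, variant = v,
                                         table = tab))))
      expect_identical(sort(colnames(m)[m[i, ]]), naive)
    }
  }
})

test_that("candidates without paths keep an all-false row", {
  kg <- example_kg()
  pairs <- data.frame(first = c("A", "B"), second = c("B", "C"),
                      label = c("positive", "negative"))
  sets <- list(A = example_setA(), B = example_setB(), C = "LONER")
  cand <- candidate_pairs(pairs, sets, quiet = TRUE)
  fm <- build_feature_matrix(cand, kg, feature_variant("metapath", "mixed"),
                             default_directionality())
  m <- as.matrix(fm$matrix)
  expect_equal(sum(m["B->C", ]), 0)
  expect_gt(sum(m["A->B", ]), 0)
  expect_error(featurize_paths(list(), feature_variant("split", "mixed")),
               "empty")
})

test_that("candidate reversal leaves undirected vectors fixed and mirrors oriented ones", {
  tab <- toy_directionality()
  df <- random_triples(n_proteins = 24, n_triples = 200, loop_prob = 0.08, seed = 77)
  kg <- knowledge_graph(df)
  set.seed(78)
  prot <- sprintf("P%02d", 1:24)
  A <- sample(prot, 6); B <- sample(prot, 6)
  fwd_paths <- extract_paths(kg, A, B)
  rev_paths <- extract_paths(kg, B, A)
  swap <- function(s) {
    tmp <- gsub(":fwd", ":@@", s, fixed = TRUE)
    tmp <- gsub(":rev", ":fwd", tmp, fixed = TRUE)
    gsub(":@@", ":rev", tmp, fixed = TRUE)
  }
  rev_metapath <- function(s) {
    # mirror component order of two-component indirect metapath signatures
    ifelse(grepl("^indirect\\|.*->", s),
           paste0("indirect|",
                  sapply(strsplit(sub("^indirect\\|", "", s), "->", fixed = TRUE),
                         function(x) paste(rev(x), collapse = "->"))),
           s)
  }
  for (rep in c("metapath", "split")) {
    vu <- feature_variant(rep, "undirected")
    su_ab <- sort(trajpath:::.collection_signatures(fwd_paths, vu, tab))
    su_ba <- sort(trajpath:::.collection_signatures(rev_paths, vu, tab))
    expect_identical(su_ab, su_ba)
    for (mode in c("mixed", "directed")) {
      v <- feature_variant(rep, mode)
      s_ab <- sort(trajpath:::.collection_signatures(fwd_paths, v, tab))
      s_ba <- sort(trajpath:::.collection_signatures(rev_paths, v, tab))
      expect_identical(sort(rev_metapath(swap(s_ba))), s_ab)
    }
  }
})

test_that("mixed mode with degenerate tables collapses to the pure modes", {
  df <- random_triples(n_proteins = 20, n_triples = 150, loop_prob = 0.1, seed = 5)
  kg <- knowledge_graph(df)
  set.seed(6)
  prot <- sprintf("P%02d", 1:20)
  A <- sample(prot, 5); B <- sample(prot, 5)
  paths <- extract_paths(kg, A, B)
  preds <- sprintf("pred%02d", 1:4)
  all_und <- directionality_table(data.frame(predicate = preds,
                                             category = "undirected"))
  all_dir <- directionality_table(data.frame(predicate = preds,
                                             category = "directed"))
  for (rep in c("metapath", "split")) {
    mix_und <- trajpath:::.collection_signatures(paths,
                                                 feature_variant(rep, "mixed"),
                                                 all_und)
    pure_und <- trajpath:::.collection_signatures(paths,
                                                  feature_variant(rep, "undirected"),
                                                  NULL)
    expect_setequal(mix_und, pure_und)
    # all-directed mixed equals directed mode except loop edges, which stay
    # orientation-free in mixed mode
    mix_dir <- trajpath:::.collection_signatures(paths,
                                                 feature_variant(rep, "mixed"),
                                                 all_dir)
    pure_dir <- trajpath:::.collection_signatures(paths,
                                                  feature_variant(rep, "directed"),
                                                  all_dir)
    strip_loop <- function(s) gsub(":loop", "", s, fixed = TRUE)
    expect_setequal(strip_loop(mix_dir), strip_loop(pure_dir))
  }
})

test_that("split signatures use exactly the components of the metapath signatures", {
  tab <- toy_directionality()
  df <- random_triples(n_proteins = 18, n_triples = 140, seed = 9)
  kg <- knowledge_graph(df)
  set.seed(10)
  prot <- sprintf("P%02d", 1:18)
  paths <- extract_paths(kg, sample(prot, 5), sample(prot, 5))
  meta <- trajpath:::.collection_signatures(paths, feature_variant("metapath", "mixed"), tab)
  split <- trajpath:::.collection_signatures(paths, feature_variant("split", "mixed"), tab)
  meta_ind <- sub("^indirect\\|", "", meta[grepl("^indirect", meta)])
  comps <- unique(unlist(strsplit(meta_ind, "->", fixed = TRUE)))
  split_ind <- unique(sub("^indirect\\|", "", split[grepl("^indirect", split)]))
  expect_setequal(split_ind, comps)
  # non-indirect signatures agree verbatim between representations
  expect_setequal(meta[!grepl("^indirect", meta)], split[!grepl("^indirect", split)])
})

test_that("sparse matrix round-trips through the triplet text format", {
  tab <- default_directionality()
  pairs <- data.frame(first = "A", second = "B", label = "positive")
  sets <- list(A = example_setA(), B = example_setB())
  cand <- candidate_pairs(pairs, sets, quiet = TRUE)
  fm <- build_feature_matrix(cand, example_kg(), feature_variant("split", "mixed"), tab)
  prefix <- file.path(withr::local_tempdir(), "fm")
  write_feature_matrix(fm, prefix)
  rows <- readLines(paste0(prefix, "_rows.tsv"))
  cols <- readLines(paste0(prefix, "_cols.tsv"))
  cells <- utils::read.delim(paste0(prefix, "_cells.tsv"))
  m2 <- Matrix::sparseMatrix(i = cells$row, j = cells$col, x = TRUE,
                             dims = c(length(rows), length(cols)),
                             dimnames = list(rows, cols))
  expect_equal(as.matrix(m2), as.matrix(fm$matrix))
})
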