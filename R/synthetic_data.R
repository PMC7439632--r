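# Synthetic benchmark generator.  Produces a complete, self-contained set of
# inputs -- protein knowledge graph, predicate directionality table,
# code->concept mapping, subclass hierarchy, gene-disease associations, and
# labelled candidate pairs -- with a *planted* association between trajectory
# direction and predicate orientation:
#
#   on paths sampled for positive pairs (A, B), every edge carrying a
#   directed predicate has its subject placed on the A side with probability
#   1/2 + beta/2; for negatives and for undirected predicates the orientation
#   is uniform.
#
# Because the signal lives in orientation only (edge existence is sampled
# identically for positives and negatives), feature sets that ignore
# orientation form a proper baseline: any AUC gain of the mixed/directed
# variants over the undirected ones is attributable to directionality.
# Reversal negatives (B, A) reuse the positives' edges, so telling them apart
# requires learning the temporal order, not the topology.

#' Configuration for the synthetic benchmark generator
#'
#' @param n_proteins size of the protein universe.
#' @param n_diseases number of diseases.
#' @param proteins_per_disease length-2 numeric: disease protein-set sizes are
#'   drawn log-uniformly between these bounds (emulating the strongly skewed
#'   set sizes of curated gene-disease catalogues).
#' @param vocabulary data.frame (`predicate`, `category`) of predicates to
#'   draw edges from; defaults to the packaged 47-predicate table
#'   (35 directed / 12 undirected).
#' @param predicate_weights how predicate usage frequencies are distributed:
#'   `"zipf"` (default; weight 1/rank over a seeded permutation of the
#'   vocabulary, emulating the heavy-tailed predicate usage of real knowledge
#'   graphs), `"uniform"`, or a numeric weight vector of the vocabulary's
#'   length.
#' @param beta planted signal strength in \[0, 1\]: excess probability that a
#'   directed edge on a positive pair's path points from the first-disease
#'   side to the second (`0` = no signal, orientation uniform everywhere).
#' @param n_pos number of positive (trajectory) pairs.
#' @param negative_mode `"reversal"` (the reversed sequence of every positive
#'   becomes a negative), `"random"` (`n_neg` random non-positive,
#'   non-reversal ordered pairs), `"rewired"` (`n_neg` degree-matched
#'   negatives obtained by re-pairing the positives' first and second
#'   diseases, approximately preserving each disease's per-side frequency),
#'   `"disjoint"`
#'   (every candidate pair, positive or negative, is built from its own two
#'   diseases, so candidates are structurally independent — the clean null
#'   design; requires `n_diseases >= 2 * (n_pos + n_neg)`), or
#'   `"all_pairs_minus"` (every other ordered pair).
#' @param n_neg number of negatives for the `"random"`, `"rewired"` and
#'   `"disjoint"` modes.
#' @param add_reversals when `negative_mode = "random"`, additionally append
#'   the reversal of every positive as a negative (via [build_negatives()]).
#' @param lambda_direct,lambda_indirect Poisson means of the number of
#'   planted direct / indirect paths per candidate pair.
#' @param background_degree expected number of uninformative background
#'   triples per protein (noise edges between random protein pairs).
#' @param self_loop_rate per-protein probability of a self-loop triple
#'   (e.g. homodimerization), feeding the overlap scenario.
#' @param subclass_prob per-disease probability of carrying part of its
#'   protein set on a subclass concept (exercises subclass expansion).
#' @param seed integer seed; all generation is deterministic given the seed.
#' @return an object of class `benchmark_config`.
#' @export
benchmark_config <- function(n_proteins = 1500,
                             n_diseases = 100,
                             proteins_per_disease = c(5, 60),
                             vocabulary = NULL,
                             predicate_weights = "zipf",
                             beta = 0.5,
                             n_pos = 50,
                             negative_mode = c("reversal", "random", "rewired",
                                               "disjoint", "all_pairs_minus"),
                             n_neg = 250,
                             add_reversals = FALSE,
                             lambda_direct = 2,
                             lambda_indirect = 4,
                             background_degree = 0.5,
                             self_loop_rate = 0.05,
                             subclass_prob = 0.3,
                             seed = 1) {
  negative_mode <- match.arg(negative_mode)
  if (is.null(vocabulary)) {
    tab <- default_directionality()
    vocabulary <- data.frame(predicate = names(tab$entries),
                             category = unname(tab$entries))
  }
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_diseases = as.integer(n_diseases),
              proteins_per_disease = as.numeric(proteins_per_disease),
              vocabulary = as.data.frame(vocabulary),
              predicate_weights = predicate_weights,
              beta = beta, n_pos = as.integer(n_pos),
              negative_mode = negative_mode, n_neg = as.integer(n_neg),
              add_reversals = isTRUE(add_reversals),
              lambda_direct = lambda_direct, lambda_indirect = lambda_indirect,
              background_degree = background_degree,
              self_loop_rate = self_loop_rate, subclass_prob = subclass_prob,
              seed = as.integer(seed))
  class(cfg) <- "benchmark_config"
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  with(cfg, {
    probs <- c(beta, self_loop_rate, subclass_prob)
    if (any(probs < 0 | probs > 1)) {
      stop("beta and all rate parameters must lie in [0, 1]", call. = FALSE)
    }
    if (background_degree < 0) {
      stop("background_degree must be non-negative", call. = FALSE)
    }
    if (length(proteins_per_disease) != 2 ||
        proteins_per_disease[1] < 1 ||
        proteins_per_disease[1] > proteins_per_disease[2]) {
      stop("proteins_per_disease must be an increasing pair >= 1", call. = FALSE)
    }
    if (proteins_per_disease[2] > n_proteins) {
      stop(sprintf("infeasible config: up to %g proteins per disease but only %d proteins",
                   proteins_per_disease[2], n_proteins), call. = FALSE)
    }
    if (n_pos > n_diseases * (n_diseases - 1) / 2) {
      stop("infeasible config: more positive pairs than unordered disease pairs",
           call. = FALSE)
    }
    if (negative_mode == "disjoint" && n_diseases < 2 * (n_pos + n_neg)) {
      stop("infeasible config: disjoint mode needs n_diseases >= 2 * (n_pos + n_neg)",
           call. = FALSE)
    }
    if (!all(c("predicate", "category") %in% names(vocabulary))) {
      stop("vocabulary needs predicate and category columns", call. = FALSE)
    }
    if (is.numeric(predicate_weights)) {
      if (length(predicate_weights) != nrow(vocabulary) ||
          any(predicate_weights < 0) || sum(predicate_weights) == 0) {
        stop("numeric predicate_weights must be non-negative, not all zero, and match the vocabulary length",
             call. = FALSE)
      }
    } else if (!identical(predicate_weights, "zipf") &&
               !identical(predicate_weights, "uniform")) {
      stop("predicate_weights must be 'zipf', 'uniform', or a numeric vector",
           call. = FALSE)
    }
  })
  invisible(cfg)
}

#' @export
print.benchmark_config <- function(x, ...) {
  cat(sprintf(paste0("<benchmark_config> %d proteins, %d diseases (set sizes %g-%g),",
                     " %d positives (%s negatives), beta = %.2f, seed = %d\n"),
              x$n_proteins, x$n_diseases, x$proteins_per_disease[1],
              x$proteins_per_disease[2], x$n_pos, x$negative_mode, x$beta, x$seed))
  invisible(x)
}

#' Preset configurations shaped like the two reference designs
#'
#' `jensen_like`: a registry-scale design — few positives against an
#' all-pairs negative background (negatives outnumber positives by roughly
#' 50:1) and strongly skewed disease protein-set sizes (log-uniform 7-94,
#' median about 26).  `vandenakker_like`: a small cohort design — 55
#' positives, 315 random negatives plus the 55 reversal negatives (370
#' negatives in total), larger protein sets (log-uniform 17-167, median
#' about 53).
#'
#' @param preset `"jensen_like"` or `"vandenakker_like"`.
#' @param ... overrides passed on to [benchmark_config()].
#' @return a [benchmark_config()].
#' @export
emulate_paper_shape <- function(preset = c("jensen_like", "vandenakker_like"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    jensen_like = list(n_diseases = 46, n_pos = 40,
                       negative_mode = "all_pairs_minus",
                       proteins_per_disease = c(7, 94), n_proteins = 800),
    vandenakker_like = list(n_diseases = 97, n_pos = 55,
                            negative_mode = "random", n_neg = 315,
                            add_reversals = TRUE,
                            proteins_per_disease = c(17, 167), n_proteins = 1500)
  )
  over <- list(...)
  do.call(benchmark_config, utils::modifyList(base, over))
}

#' Draw disease protein-set sizes for a configuration
#'
#' @param config a [benchmark_config()].
#' @param n number of draws.
#' @param seed integer seed.
#' @return integer vector of set sizes.
#' @export
draw_disease_sizes <- function(config, n = config$n_diseases, seed = config$seed) {
  lo <- config$proteins_per_disease[1]
  hi <- config$proteins_per_disease[2]
  rng <- .local_rng(seed)
  pmax(1L, pmin(config$n_proteins,
                as.integer(round(exp(rng$unif(n) * (log(hi) - log(lo)) + log(lo))))))
}

#' Generate a complete synthetic benchmark
#'
#' See the module header: edge *existence* is sampled identically for
#' positive and negative pairs; the planted signal lives purely in the
#' orientation of directed predicates on positive pairs' paths (probability
#' `1/2 + beta/2` of pointing towards the second disease).  With
#' `negative_mode = "reversal"` the negatives are the reversed positives and
#' share their edges, so only temporal order separates the classes.
#'
#' @param config a [benchmark_config()].
#' @return an object of class `trajectory_benchmark`: list with `config`,
#'   `kg` ([knowledge_graph()]), `directionality`
#'   ([directionality_table()]), `mapping`, `hierarchy`, `associations`
#'   (data.tables in the loader formats), `pairs` (`first`, `second`,
#'   `label`), and `protein_sets` (named list disease code -> proteins).
#' @export
generate_benchmark <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  .validate_config(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)

  proteins <- sprintf("PR%05d", seq_len(config$n_proteins))
  codes <- sprintf("D%03d", seq_len(config$n_diseases))
  concepts <- sprintf("C%04d", seq_len(config$n_diseases))
  vocab <- data.table(predicate = normalize_predicate(config$vocabulary$predicate),
                      category = tolower(config$vocabulary$category))
  directed_set <- vocab[category == "directed", predicate]
  n_vocab <- nrow(vocab)
  w <- if (is.numeric(config$predicate_weights)) {
    config$predicate_weights
  } else if (identical(config$predicate_weights, "zipf")) {
    # heavy-tailed usage: weight 1/rank, ranks assigned by a seeded permutation
    1 / sample.int(n_vocab)
  } else {
    rep(1, n_vocab)
  }
  draw_pred <- function(n) vocab$predicate[sample.int(n_vocab, n, replace = TRUE, prob = w)]

  # disease protein sets, split between the main concept and (sometimes) a
  # subclass concept so the mapping/expansion stage is exercised
  lo <- config$proteins_per_disease[1]; hi <- config$proteins_per_disease[2]
  sizes <- pmax(1L, pmin(config$n_proteins,
                         as.integer(round(exp(runif(config$n_diseases,
                                                    log(lo), log(hi)))))))
  protein_sets <- vector("list", config$n_diseases)
  names(protein_sets) <- codes
  mapping <- data.table(code = codes, vocabulary = "ICD10", concept_id = concepts)
  hier_rows <- list()
  assoc_rows <- list()
  for (i in seq_len(config$n_diseases)) {
    ps <- sort(sample(proteins, sizes[i]))
    protein_sets[[i]] <- ps
    if (runif(1) < config$subclass_prob && length(ps) >= 2) {
      k <- max(1L, as.integer(floor(length(ps) * 0.3)))
      sub_ps <- sample(ps, k)
      child_id <- paste0(concepts[i], ".1")
      hier_rows[[length(hier_rows) + 1L]] <-
        data.table(parent = concepts[i], child = child_id,
                   relation = sample(c("narrower", "child"), 1))
      assoc_rows[[length(assoc_rows) + 1L]] <-
        data.table(concept_id = child_id, protein_id = sub_ps)
      assoc_rows[[length(assoc_rows) + 1L]] <-
        data.table(concept_id = concepts[i], protein_id = setdiff(ps, sub_ps))
    } else {
      assoc_rows[[length(assoc_rows) + 1L]] <-
        data.table(concept_id = concepts[i], protein_id = ps)
    }
  }
  hierarchy <- if (length(hier_rows)) rbindlist(hier_rows) else
    data.table(parent = character(), child = character(), relation = character())
  associations <- unique(rbindlist(assoc_rows))

  # labelled pairs
  unordered <- CJ(i = seq_len(config$n_diseases), j = seq_len(config$n_diseases))[i < j]
  pick <- unordered[sample(.N, config$n_pos)]
  flip <- runif(config$n_pos) < 0.5
  positives <- data.table(first = codes[ifelse(flip, pick$j, pick$i)],
                          second = codes[ifelse(flip, pick$i, pick$j)],
                          label = "positive")
  key_of <- function(f, s) paste(f, s, sep = "\r")
  pos_keys <- key_of(positives$first, positives$second)
  rev_keys <- key_of(positives$second, positives$first)
  random_negs <- data.table(first = character(), second = character(),
                            label = character())
  if (config$negative_mode == "disjoint") {
    # structurally independent candidates: every pair gets its own diseases
    perm <- sample(codes)
    n_tot <- config$n_pos + config$n_neg
    firsts <- perm[seq_len(n_tot) * 2 - 1]
    seconds <- perm[seq_len(n_tot) * 2]
    positives <- data.table(first = firsts[seq_len(config$n_pos)],
                            second = seconds[seq_len(config$n_pos)],
                            label = "positive")
    pos_keys <- key_of(positives$first, positives$second)
    rev_keys <- key_of(positives$second, positives$first)
    random_negs <- data.table(first = firsts[-seq_len(config$n_pos)],
                              second = seconds[-seq_len(config$n_pos)],
                              label = "negative")
    negatives <- copy(random_negs)
  } else if (config$negative_mode == "reversal") {
    negatives <- data.table(first = positives$second, second = positives$first,
                            label = "negative")
  } else if (config$negative_mode == "all_pairs_minus") {
    grid <- CJ(first = codes, second = codes)[first != second]
    grid <- grid[!key_of(first, second) %chin% pos_keys]
    negatives <- grid[, .(first, second, label = "negative")]
  } else if (config$negative_mode == "rewired") {
    # degree-matched negatives: re-pair the positives' first/second diseases
    # through random permutations so each disease keeps its per-side marginal
    # frequency; removes any set-size / frequency signal from edge existence
    taken <- c(pos_keys, rev_keys)
    negs <- character(0)
    neg_first <- character(0); neg_second <- character(0)
    attempts <- 0
    while (length(negs) < config$n_neg && attempts < 200) {
      attempts <- attempts + 1
      perm <- sample.int(config$n_pos)
      f <- positives$first
      s <- positives$second[perm]
      k <- key_of(f, s)
      ok <- f != s & !(k %chin% taken) & !(k %chin% negs) & !duplicated(k)
      negs <- c(negs, k[ok])
      neg_first <- c(neg_first, f[ok]); neg_second <- c(neg_second, s[ok])
    }
    if (length(negs) < config$n_neg) {
      stop("infeasible config: could not rewire enough degree-matched negatives",
           call. = FALSE)
    }
    random_negs <- data.table(first = neg_first[seq_len(config$n_neg)],
                              second = neg_second[seq_len(config$n_neg)],
                              label = "negative")
    negatives <- copy(random_negs)
  } else {
    grid <- CJ(first = codes, second = codes)[first != second]
    grid <- grid[!key_of(first, second) %chin% c(pos_keys, rev_keys)]
    if (config$n_neg > nrow(grid)) {
      stop("infeasible config: not enough ordered pairs for n_neg random negatives",
           call. = FALSE)
    }
    random_negs <- grid[sample(.N, config$n_neg)][, .(first, second, label = "negative")]
    negatives <- copy(random_negs)
    if (config$add_reversals) {
      pr <- rbindlist(list(positives, negatives))
      negatives <- rbindlist(list(negatives,
                                  build_negatives(pr, mode = "reversal")))
    }
  }
  pairs <- rbindlist(list(positives, negatives))

  # planted connection paths: identical existence sampling for positives and
  # (non-reversal) random negatives; orientation biased only for positives
  triple_rows <- list()
  plant_for <- rbindlist(list(positives,
                              if (config$negative_mode == "all_pairs_minus")
                                negatives else random_negs), fill = TRUE)
  for (i in seq_len(nrow(plant_for))) {
    bias <- if (plant_for$label[i] == "positive") 0.5 + config$beta / 2 else 0.5
    A <- protein_sets[[plant_for$first[i]]]
    B <- protein_sets[[plant_for$second[i]]]
    nd <- rpois(1, config$lambda_direct)
    for (k in seq_len(nd)) {
      a <- A[sample.int(length(A), 1)]
      b <- B[sample.int(length(B), 1)]
      pred <- draw_pred(1)
      u <- runif(1)
      if (a == b) next  # shared protein drawn: no direct edge planted
      eff <- if (pred %chin% directed_set) bias else 0.5
      triple_rows[[length(triple_rows) + 1L]] <-
        if (u < eff) data.table(subject = a, predicate = pred, object = b)
        else data.table(subject = b, predicate = pred, object = a)
    }
    ni <- rpois(1, config$lambda_indirect)
    for (k in seq_len(ni)) {
      a <- A[sample.int(length(A), 1)]
      b <- B[sample.int(length(B), 1)]
      m <- proteins[sample.int(length(proteins), 1)]
      tries <- 0
      while ((m == a || m == b) && tries < 20) {
        m <- proteins[sample.int(length(proteins), 1)]
        tries <- tries + 1
      }
      if (m == a || m == b) next
      p1 <- draw_pred(1)
      u1 <- runif(1)
      p2 <- draw_pred(1)
      u2 <- runif(1)
      e1 <- if (p1 %chin% directed_set) bias else 0.5
      e2 <- if (p2 %chin% directed_set) bias else 0.5
      triple_rows[[length(triple_rows) + 1L]] <-
        if (u1 < e1) data.table(subject = a, predicate = p1, object = m)
        else data.table(subject = m, predicate = p1, object = a)
      triple_rows[[length(triple_rows) + 1L]] <-
        if (u2 < e2) data.table(subject = m, predicate = p2, object = b)
        else data.table(subject = b, predicate = p2, object = m)
    }
  }

  # self-loops (overlap scenario material) and background noise edges
  has_loop <- runif(config$n_proteins) < config$self_loop_rate
  if (any(has_loop)) {
    lp <- proteins[has_loop]
    triple_rows[[length(triple_rows) + 1L]] <-
      data.table(subject = lp,
                 predicate = draw_pred(length(lp)),
                 object = lp)
  }
  n_bg <- rpois(1, config$background_degree * config$n_proteins)
  if (n_bg > 0) {
    s <- proteins[sample.int(config$n_proteins, n_bg, replace = TRUE)]
    o <- proteins[sample.int(config$n_proteins, n_bg, replace = TRUE)]
    p <- draw_pred(n_bg)
    keep <- s != o
    if (any(keep)) {
      triple_rows[[length(triple_rows) + 1L]] <-
        data.table(subject = s[keep], predicate = p[keep], object = o[keep])
    }
  }

  triples <- rbindlist(triple_rows)
  triples[, provenance := "synthetic"]
  kg <- knowledge_graph(triples)
  directionality <- directionality_table(vocab)

  structure(list(config = config, kg = kg, directionality = directionality,
                 mapping = mapping, hierarchy = hierarchy,
                 associations = associations, pairs = pairs,
                 protein_sets = protein_sets),
            class = "trajectory_benchmark")
}

#' @export
print.trajectory_benchmark <- function(x, ...) {
  cat(sprintf("<trajectory_benchmark> %d triples, %d diseases, %d pairs (%d positive)\n",
              nrow(x$kg$triples), length(x$protein_sets), nrow(x$pairs),
              sum(x$pairs$label == "positive")))
  invisible(x)
}

#' Write a synthetic benchmark to a directory of TSV files
#'
#' Emits `triples.tsv`, `directionality.tsv`, `mapping.tsv`,
#' `hierarchy.tsv`, `associations.tsv`, and `pairs.tsv` in the formats read
#' by the corresponding loaders.
#'
#' @param bench a [generate_benchmark()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  stopifnot(inherits(bench, "trajectory_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_triples(bench$kg, file.path(dir, "triples.tsv"))
  fwrite(data.table(predicate = names(bench$directionality$entries),
                    category = unname(bench$directionality$entries)),
         file.path(dir, "directionality.tsv"), sep = "\t", col.names = FALSE)
  fwrite(bench$mapping, file.path(dir, "mapping.tsv"), sep = "\t", col.names = FALSE)
  fwrite(bench$hierarchy, file.path(dir, "hierarchy.tsv"), sep = "\t",
         col.names = FALSE)
  fwrite(bench$associations, file.path(dir, "associations.tsv"), sep = "\t",
         col.names = FALSE)
  fwrite(bench$pairs, file.path(dir, "pairs.tsv"), sep = "\t", col.names = FALSE)
  invisible(dir)
}
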