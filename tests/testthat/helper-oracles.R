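# Independent oracles and fixture builders used across the test files.
# These deliberately avoid the package's data.table join machinery: they use
# plain vectors, loops, and base R so they constitute an independent route to
# the same quantities.

# random triple table (may contain duplicates and self-loops)
random_triples <- function(n_proteins = 20, n_triples = 100, n_predicates = 4,
                           loop_prob = 0.05, seed = 1) {
  set.seed(seed)
  prot <- sprintf("P%02d", seq_len(n_proteins))
  pred <- sprintf("pred%02d", seq_len(n_predicates))
  s <- sample(prot, n_triples, replace = TRUE)
  o <- sample(prot, n_triples, replace = TRUE)
  keep_loop <- runif(n_triples) < loop_prob
  o[!keep_loop & o == s] <- sample(prot, sum(!keep_loop & o == s), replace = TRUE)
  data.frame(subject = s, predicate = sample(pred, n_triples, replace = TRUE),
             object = o, stringsAsFactors = FALSE)
}

# deduplicate a raw triple table the way a set of (s, p, o) keys would
dedup_triples <- function(df) {
  df[!duplicated(paste(df$subject, df$predicate, df$object, sep = "\r")), ,
     drop = FALSE]
}

# brute-force path enumeration between two protein sets: plain loops and
# logical indexing over the (deduplicated) triple rows
oracle_paths <- function(df, A, B) {
  df <- dedup_triples(df)
  loops <- df[df$subject == df$object, , drop = FALSE]
  non <- df[df$subject != df$object, , drop = FALSE]
  shared <- sort(intersect(A, B))
  overlap_loops <- data.frame(protein = character(), predicate = character())
  for (pr in shared) {
    lp <- loops$predicate[loops$subject == pr]
    if (length(lp) > 0) {
      overlap_loops <- rbind(overlap_loops,
                             data.frame(protein = pr, predicate = sort(lp)))
    }
  }
  direct <- data.frame(a = character(), b = character(), predicate = character(),
                       orient = character())
  for (i in seq_len(nrow(non))) {
    s <- non$subject[i]; o <- non$object[i]; p <- non$predicate[i]
    if (s %in% A && o %in% B) direct <- rbind(direct,
      data.frame(a = s, b = o, predicate = p, orient = "fwd"))
    if (o %in% A && s %in% B) direct <- rbind(direct,
      data.frame(a = o, b = s, predicate = p, orient = "rev"))
  }
  # indirect: ordered pairs of two *distinct* non-loop triples
  ind <- list()
  ns <- non$subject; no <- non$object; np <- non$predicate
  n <- nrow(non)
  for (i in seq_len(n)) {
    legs1 <- list()
    if (ns[i] %in% A) legs1[[length(legs1) + 1]] <- c(ns[i], no[i], "fwd")
    if (no[i] %in% A) legs1[[length(legs1) + 1]] <- c(no[i], ns[i], "rev")
    for (l1 in legs1) {
      a <- l1[1]; m <- l1[2]; o1 <- l1[3]
      if (m == a) next
      # second leg from m into B, any other triple, either orientation
      j_fwd <- which(ns == m & no %in% B & seq_len(n) != i)
      for (j in j_fwd) {
        if (m != no[j]) {
          ind[[length(ind) + 1]] <- data.frame(
            a = a, m = m, b = no[j], p1 = np[i], o1 = o1,
            p2 = np[j], o2 = "fwd")
        }
      }
      j_rev <- which(no == m & ns %in% B & seq_len(n) != i)
      for (j in j_rev) {
        if (m != ns[j]) {
          ind[[length(ind) + 1]] <- data.frame(
            a = a, m = m, b = ns[j], p1 = np[i], o1 = o1,
            p2 = np[j], o2 = "rev")
        }
      }
    }
  }
  indirect <- if (length(ind)) do.call(rbind, ind) else
    data.frame(a = character(), m = character(), b = character(),
               p1 = character(), o1 = character(), p2 = character(),
               o2 = character())
  # drop paths whose intermediate equals an endpoint
  indirect <- indirect[indirect$m != indirect$a & indirect$m != indirect$b, ,
                       drop = FALSE]
  list(overlap = shared, overlap_loops = overlap_loops, direct = direct,
       indirect = indirect)
}

# canonical string form of a path set for order-insensitive comparison
canon_direct <- function(df) sort(paste(df$a, df$b, df$predicate, df$orient))
canon_indirect <- function(df) sort(paste(df$a, df$m, df$b, df$p1, df$o1,
                                          df$p2, df$o2))

# a small directionality table for random-graph tests: odd predicates
# directed, even undirected
toy_directionality <- function(n_predicates = 4) {
  pred <- sprintf("pred%02d", seq_len(n_predicates))
  directionality_table(data.frame(
    predicate = pred,
    category = ifelse(seq_len(n_predicates) %% 2 == 1, "directed", "undirected")))
}

# the worked example graph: two diseases sharing DP1 (with a self-binding
# loop), a direct inhibition DP2 -> DP4, and an indirect path DP3 -> IP -> DP5
example_kg <- function() {
  knowledge_graph(data.frame(
    subject = c("DP1", "DP2", "DP3", "IP"),
    predicate = c("binds with", "inhibits", "inhibits", "inhibits"),
    object = c("DP1", "DP4", "IP", "DP5")))
}
example_setA <- function() c("DP1", "DP2", "DP3")
example_setB <- function() c("DP1", "DP4", "DP5")

# breadth-first reachability oracle over parent->child edges
oracle_descendants <- function(concept, parents, children) {
  seen <- concept
  queue <- concept
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    kids <- children[parents == cur]
    new <- setdiff(kids, seen)
    seen <- c(seen, new)
    queue <- c(queue, new)
  }
  sort(unique(seen))
}

# write a temporary TSV without header
write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}
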