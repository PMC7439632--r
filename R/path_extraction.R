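# Path extraction: enumerate all length-<=2 protein paths between the two
# protein sets of a candidate disease pair, classified into three scenarios:
#   overlap  - a protein shared by both sets, optionally with self-loop triples
#              (e.g. homodimerization);
#   direct   - a single non-loop triple joining a protein of A and one of B;
#   indirect - a two-triple path A-protein -- intermediate -- B-protein.
# Edge orientation is recorded relative to traversal from the A (first
# disease) side: "fwd" iff the triple's subject is the node nearer A.

#' Extract all length-<=2 paths between two protein sets
#'
#' @param kg a [knowledge_graph()].
#' @param setA,setB non-empty character vectors: the disease-protein sets of
#'   the first and the second disease.
#' @param exclude_disease_intermediates if `TRUE`, indirect paths whose
#'   intermediate protein belongs to `setA` or `setB` are discarded; by
#'   default any protein may act as intermediate.
#' @return an object of class `path_collection`: a list with data.tables
#'   `overlap` (`protein`), `overlap_loops` (`protein`, `predicate`),
#'   `direct` (`a`, `b`, `predicate`, `orient`),
#'   `indirect` (`a`, `m`, `b`, `p1`, `o1`, `p2`, `o2`), and a named
#'   integer vector `counts`.  Orientations are `"fwd"` / `"rev"`.
#'
#' @details Indirect paths use two *distinct* triples; a path that would
#'   traverse the same triple out and back (only possible when the two
#'   endpoints coincide) is excluded.  Endpoints may coincide when a shared
#'   protein reaches itself through an intermediate.  Self-loop triples never
#'   serve as direct or indirect legs.
#' @export
extract_paths <- function(kg, setA, setB, exclude_disease_intermediates = FALSE) {
  stopifnot(inherits(kg, "knowledge_graph"))
  setA <- unique(as.character(setA))
  setB <- unique(as.character(setB))
  if (length(setA) == 0) stop("empty protein set for the first disease (setA)",
                              call. = FALSE)
  if (length(setB) == 0) stop("empty protein set for the second disease (setB)",
                              call. = FALSE)

  loops <- .kg_loop_table(kg)
  shared <- sort(intersect(setA, setB))
  overlap <- data.table(protein = shared)
  overlap_loops <- loops[protein %chin% shared][order(protein, predicate)]

  ed <- .kg_edge_table(kg)
  direct <- ed[x %chin% setA & y %chin% setB,
               .(a = x, b = y, predicate, orient)]
  setorder(direct, a, b, predicate, orient)

  e1 <- ed[x %chin% setA, .(a = x, m = y, p1 = predicate, o1 = orient, tid1 = tid)]
  e2 <- ed[y %chin% setB, .(m = x, b = y, p2 = predicate, o2 = orient, tid2 = tid)]
  indirect <- merge(e1, e2, by = "m", allow.cartesian = TRUE)
  indirect <- indirect[m != a & m != b & tid1 != tid2,
                       .(a, m, b, p1, o1, p2, o2)]
  if (exclude_disease_intermediates) {
    indirect <- indirect[!(m %chin% setA) & !(m %chin% setB)]
  }
  setorder(indirect, a, m, b, p1, o1, p2, o2)

  counts <- c(overlap = nrow(overlap), direct = nrow(direct),
              indirect = nrow(indirect))
  structure(list(overlap = overlap, overlap_loops = overlap_loops,
                 direct = direct, indirect = indirect, counts = counts,
                 setA = setA, setB = setB),
            class = "path_collection")
}

#' @export
print.path_collection <- function(x, ...) {
  cat(sprintf("<path_collection> overlap: %d (loops: %d), direct: %d, indirect: %d\n",
              x$counts[["overlap"]], nrow(x$overlap_loops),
              x$counts[["direct"]], x$counts[["indirect"]]))
  invisible(x)
}

#' Flatten a path collection into individual path instances
#'
#' Each instance is a list with `scenario` (`overlap` / `direct` /
#' `indirect`), `nodes` (1, 2, or 3 proteins from the first-disease side to
#' the second), and `edges` (a data.frame of `predicate`, `orientation` with
#' orientation `fwd` / `rev` / `loop`, aligned with traversal order).  An
#' overlap instance carries its self-loop predicates as `loop` edges (zero or
#' more).
#'
#' @param paths a `path_collection`.
#' @return list of path instances.
#' @export
as_path_list <- function(paths) {
  stopifnot(inherits(paths, "path_collection"))
  out <- list()
  for (prot in paths$overlap$protein) {
    lp <- paths$overlap_loops[protein == prot, predicate]
    out[[length(out) + 1L]] <- list(
      scenario = "overlap", nodes = prot,
      edges = data.frame(predicate = lp,
                         orientation = rep("loop", length(lp))))
  }
  if (nrow(paths$direct) > 0) {
    for (i in seq_len(nrow(paths$direct))) {
      r <- paths$direct[i]
      out[[length(out) + 1L]] <- list(
        scenario = "direct", nodes = c(r$a, r$b),
        edges = data.frame(predicate = r$predicate, orientation = r$orient))
    }
  }
  if (nrow(paths$indirect) > 0) {
    for (i in seq_len(nrow(paths$indirect))) {
      r <- paths$indirect[i]
      out[[length(out) + 1L]] <- list(
        scenario = "indirect", nodes = c(r$a, r$m, r$b),
        edges = data.frame(predicate = c(r$p1, r$p2),
                           orientation = c(r$o1, r$o2)))
    }
  }
  out
}
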