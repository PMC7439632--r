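# Disease mapping: code -> concept mapping, subclass expansion, disease
# protein assignment, and construction of labelled candidate pair sets.

#' Load a code-to-concept mapping table
#'
#' Expects `code<TAB>vocabulary<TAB>concept_id` (no header, `#` comments
#' skipped).  A source code may map to zero, one, or many concepts.
#'
#' @param path path to the TSV file.
#' @return data.table with columns `code`, `vocabulary`, `concept_id`,
#'   class `concept_mapping`.
#' @export
load_concept_mapping <- function(path) {
  dt <- .read_tsv(path, c("code", "vocabulary", "concept_id"))
  setattr(dt, "class", c("concept_mapping", class(dt)))
  dt[]
}

#' Load a concept subclass hierarchy
#'
#' Expects `parent<TAB>child<TAB>relation` with relation `narrower` or
#' `child` (both denote a parent-to-subclass edge).
#'
#' @param path path to the TSV file.
#' @return data.table with columns `parent`, `child`, `relation`,
#'   class `subclass_hierarchy`.
#' @export
load_subclass_hierarchy <- function(path) {
  dt <- .read_tsv(path, c("parent", "child", "relation"))
  bad <- setdiff(unique(dt$relation), c("narrower", "child"))
  if (length(bad) > 0) {
    stop("unknown hierarchy relation(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  setattr(dt, "class", c("subclass_hierarchy", class(dt)))
  dt[]
}

#' Load curated gene-disease associations
#'
#' Expects `concept_id<TAB>protein_id`; duplicates are dropped.  Protein
#' identifiers share the namespace of the knowledge-graph nodes.
#'
#' @param path path to the TSV file.
#' @return data.table with columns `concept_id`, `protein_id`,
#'   class `gene_disease_associations`.
#' @export
load_associations <- function(path) {
  dt <- unique(.read_tsv(path, c("concept_id", "protein_id")))
  setattr(dt, "class", c("gene_disease_associations", class(dt)))
  dt[]
}

#' Load a labelled candidate-pair table
#'
#' Expects `first<TAB>second<TAB>label` with label `positive` or `negative`.
#'
#' @param path path to the TSV file.
#' @return data.table with columns `first`, `second`, `label`.
#' @export
load_pairs <- function(path) {
  dt <- .read_tsv(path, c("first", "second", "label"))
  bad <- setdiff(unique(dt$label), c("positive", "negative"))
  if (length(bad) > 0) {
    stop("pair labels must be positive/negative, got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dt[]
}

.read_tsv <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- fread(path, sep = "\t", header = FALSE, colClasses = "character")
  if (ncol(dt) < length(cols)) {
    stop(sprintf("%s: expected %d tab-separated columns", path, length(cols)),
         call. = FALSE)
  }
  dt <- dt[, seq_along(cols), with = FALSE]
  setnames(dt, cols)
  dt <- dt[!startsWith(trimws(dt[[1]]), "#")]
  dt
}

#' Expand a concept with all its subclasses
#'
#' Returns the concept together with every concept reachable through
#' parent-to-child (`narrower` / `child`) edges.  The closure is transitive
#' and cycle-safe; an unknown concept expands to itself.
#'
#' @param concept a concept id (scalar).
#' @param hierarchy a [load_subclass_hierarchy()] table (or any data.frame
#'   with `parent` and `child` columns).
#' @param max_depth maximum descent depth (`Inf` = full transitive closure;
#'   `1` = direct subclasses only).  Provided for sensitivity analysis.
#' @return character vector of concept ids, including `concept` itself.
#' @export
expand_with_subclasses <- function(concept, hierarchy, max_depth = Inf) {
  stopifnot(length(concept) == 1)
  h <- as.data.table(hierarchy)
  seen <- concept
  frontier <- concept
  depth <- 0
  while (length(frontier) > 0 && depth < max_depth) {
    kids <- h[parent %chin% frontier, unique(child)]
    frontier <- setdiff(kids, seen)
    seen <- c(seen, frontier)
    depth <- depth + 1
  }
  sort(unique(seen))
}

#' Assign disease proteins to a disease code
#'
#' Maps the code to its concept(s), expands each concept with its subclasses,
#' and returns the union of curated protein associations over all of them.
#' An empty result marks an unmappable disease (such diseases are excluded
#' from candidate construction downstream); the event is reported as a
#' message, not an error.
#'
#' @param code a disease code (scalar).
#' @param mapping a [load_concept_mapping()] table.
#' @param hierarchy a [load_subclass_hierarchy()] table.
#' @param assoc a [load_associations()] table.
#' @param vocabulary optional vocabulary filter (e.g. `"ICD10"`).
#' @param max_depth passed to [expand_with_subclasses()].
#' @param quiet suppress the unmapped-code message.
#' @return sorted character vector of protein identifiers (possibly empty).
#' @export
assign_disease_proteins <- function(code, mapping, hierarchy, assoc,
                                    vocabulary = NULL, max_depth = Inf,
                                    quiet = FALSE) {
  stopifnot(length(code) == 1)
  m <- as.data.table(mapping)
  if (!is.null(vocabulary)) m <- m[m[["vocabulary"]] == vocabulary]
  concepts <- unique(m[["concept_id"]][m[["code"]] == code])
  if (length(concepts) == 0) {
    if (!quiet) message("unmapped code: ", code)
    return(character())
  }
  expanded <- unique(unlist(lapply(concepts, expand_with_subclasses,
                                   hierarchy = hierarchy,
                                   max_depth = max_depth)))
  a <- as.data.table(assoc)
  sort(unique(a[concept_id %chin% expanded, protein_id]))
}

#' Construct negative (non-trajectory) pairs
#'
#' Two constructions are supported.  `all_pairs_minus` labels every ordered
#' pair of distinct diseases that is not a positive as a negative.
#' `reversal` emits, for each positive (A, B), the reversed pair (B, A) as a
#' negative unless (B, A) already appears in the supplied pair list (as a
#' positive or a negative), so each reversal occurs exactly once afterwards.
#'
#' @param pairs a labelled pair table (`first`, `second`, `label`) holding the
#'   positives and any pre-existing negatives.
#' @param diseases character vector of included diseases; required for
#'   `all_pairs_minus`, defaults to the diseases appearing in `pairs`.
#' @param mode `"all_pairs_minus"` or `"reversal"`.
#' @return data.table of new negative pairs (`first`, `second`,
#'   `label = "negative"`); bind to `pairs` to obtain the full candidate set.
#' @export
build_negatives <- function(pairs, diseases = NULL,
                            mode = c("all_pairs_minus", "reversal")) {
  mode <- match.arg(mode)
  pr <- as.data.table(pairs)[, .(first, second, label)]
  key_of <- function(f, s) paste(f, s, sep = "\r")
  pos <- pr[label == "positive"]
  neg <- pr[label == "negative"]
  clash <- intersect(key_of(pos$first, pos$second), key_of(neg$first, neg$second))
  if (length(clash) > 0) {
    stop("pair(s) labelled both positive and negative: ",
         paste(gsub("\r", " -> ", clash), collapse = ", "), call. = FALSE)
  }
  if (is.null(diseases)) diseases <- unique(c(pr$first, pr$second))
  if (!all(c(pos$first, pos$second) %in% diseases)) {
    stop("positives mention diseases outside the supplied disease set",
         call. = FALSE)
  }
  if (mode == "all_pairs_minus") {
    grid <- CJ(first = diseases, second = diseases)[first != second]
    grid <- grid[!key_of(first, second) %chin% key_of(pos$first, pos$second)]
    out <- grid[, .(first, second, label = "negative")]
  } else {
    rev_keys <- key_of(pos$second, pos$first)
    have <- key_of(pr$first, pr$second)
    new <- pos[!rev_keys %chin% have]
    out <- unique(new[, .(first = second, second = first, label = "negative")])
  }
  setorder(out, first, second)
  out[]
}

#' Build the candidate-pair set for featurization
#'
#' Attaches each disease's protein set to the labelled pairs and drops every
#' pair involving a disease with an empty protein set (unmappable diseases
#' cannot be represented on the protein level).
#'
#' @param pairs labelled pair table (`first`, `second`, `label`).
#' @param protein_sets named list: disease code -> character vector of
#'   protein identifiers.
#' @param quiet suppress the drop-count message.
#' @return an object of class `candidate_set`: a data.table with columns
#'   `pair_id`, `first`, `second`, `label` and list-columns `proteins_first`,
#'   `proteins_second`.
#' @export
candidate_pairs <- function(pairs, protein_sets, quiet = FALSE) {
  pr <- as.data.table(pairs)[, .(first, second, label)]
  if (any(pr$first == pr$second)) {
    stop("candidate pairs must have first != second", call. = FALSE)
  }
  dup <- pr[, .N, by = .(first, second)][N > 1]
  if (nrow(dup) > 0) {
    stop("duplicate candidate pair(s): ",
         paste(dup$first, "->", dup$second, collapse = ", "), call. = FALSE)
  }
  sizes <- lengths(protein_sets)
  mappable <- names(protein_sets)[sizes > 0]
  keep <- pr$first %chin% mappable & pr$second %chin% mappable
  if (!quiet && any(!keep)) {
    message(sprintf("dropped %d pair(s) involving diseases without disease proteins",
                    sum(!keep)))
  }
  pr <- pr[keep]
  if (nrow(pr) == 0) stop("no candidate pairs left after dropping unmappable diseases",
                          call. = FALSE)
  pr[, pair_id := sprintf("%s->%s", first, second)]
  pr[, proteins_first := protein_sets[first]]
  pr[, proteins_second := protein_sets[second]]
  setcolorder(pr, c("pair_id", "first", "second", "label"))
  setattr(pr, "class", c("candidate_set", class(pr)))
  pr[]
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d pairs (%d positive, %d negative), %d diseases\n",
              nrow(x), sum(x$label == "positive"), sum(x$label == "negative"),
              length(unique(c(x$first, x$second)))))
  invisible(x)
}
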