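# Knowledge-graph store: triples, indexing, and the predicate directionality
# table.  Triples are subject-predicate-object statements between proteins;
# the direction of a predicate runs from subject to object.

#' Normalize a predicate string
#'
#' Predicates are compared case-insensitively after whitespace normalization,
#' because source tables mix capitalizations of the same predicate.
#'
#' @param x character vector of predicate names.
#' @return normalized character vector (lower case, single internal spaces,
#'   trimmed).
#' @export
normalize_predicate <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Construct a knowledge graph from a triple table
#'
#' @param triples a data.frame with columns `subject`, `predicate`, `object`
#'   and optionally `provenance`.  Duplicate (subject, predicate, object) rows
#'   are collapsed to one; provenance is carried but never used in computation.
#' @return an object of class `knowledge_graph`: a list with the deduplicated
#'   `triples` data.table (with a stable integer triple id `tid`) and the
#'   `nodes` character vector (union of all subjects and objects).
#' @export
knowledge_graph <- function(triples) {
  dt <- as.data.table(triples)
  req <- c("subject", "predicate", "object")
  if (!all(req %in% names(dt))) {
    stop("triples must have columns subject, predicate, object", call. = FALSE)
  }
  if (!"provenance" %in% names(dt)) dt[, provenance := NA_character_]
  dt <- dt[, .(subject = as.character(subject),
               predicate = normalize_predicate(as.character(predicate)),
               object = as.character(object),
               provenance = as.character(provenance))]
  if (nrow(dt) > 0) {
    if (any(!nzchar(dt$subject)) || any(!nzchar(dt$object))) {
      stop("subject and object must be non-empty", call. = FALSE)
    }
    if (any(!nzchar(dt$predicate))) {
      stop("predicate must be non-empty", call. = FALSE)
    }
  }
  # collapse duplicates of the full (s, p, o) key; keep first provenance
  dt <- unique(dt, by = c("subject", "predicate", "object"))
  setorder(dt, subject, predicate, object)
  dt[, tid := seq_len(.N)]
  setkey(dt, subject)
  nodes <- sort(unique(c(dt$subject, dt$object)))
  structure(list(triples = dt[], nodes = nodes), class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph> %d triples, %d proteins, %d predicates\n",
              nrow(x$triples), length(x$nodes),
              length(unique(x$triples$predicate))))
  invisible(x)
}

#' Load protein triples from a TSV file
#'
#' Expects `subject<TAB>predicate<TAB>object[<TAB>provenance]`, no header;
#' lines starting with `#` are skipped.  Duplicate triples are collapsed.
#'
#' @param path path to the TSV file.
#' @param quiet suppress the row-count message.
#' @return a [knowledge_graph()].
#' @export
load_triples <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("triple file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) {
    warning("empty triple file: ", path, call. = FALSE)
    return(knowledge_graph(data.frame(subject = character(),
                                      predicate = character(),
                                      object = character())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 3)) {
    bad <- lineno[which(nfield < 3)[1]]
    stop(sprintf("malformed triple row at line %d of %s: fewer than 3 columns",
                 bad, path), call. = FALSE)
  }
  df <- data.frame(
    subject    = vapply(parts, `[`, "", 1L),
    predicate  = vapply(parts, `[`, "", 2L),
    object     = vapply(parts, `[`, "", 3L),
    provenance = vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_, "")
  )
  kg <- knowledge_graph(df)
  if (!quiet) {
    message(sprintf("loaded %d distinct triples (%d rows) from %s",
                    nrow(kg$triples), length(lines), path))
  }
  kg
}

#' Write a knowledge graph back to triples TSV
#'
#' Inverse of [load_triples()]: load -> write -> load round-trips to an
#' identical triple set.
#'
#' @param kg a `knowledge_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_triples <- function(kg, path) {
  stopifnot(inherits(kg, "knowledge_graph"))
  dt <- kg$triples[, .(subject, predicate, object,
                       provenance = fifelse(is.na(provenance), "", provenance))]
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Predicate directionality table
#'
#' Maps each predicate to `"directed"` or `"undirected"`.  A predicate whose
#' name starts with a negation prefix (default `"does not "`) inherits the
#' category of its de-negated base predicate; an explicit entry for a negated
#' form must agree with its base.
#'
#' @param entries data.frame with columns `predicate` and `category`
#'   (values `directed` / `undirected`).
#' @param negation_prefixes ordered character vector of prefixes identifying
#'   negated predicates.
#' @return an object of class `directionality_table`.
#' @export
directionality_table <- function(entries, negation_prefixes = "does not ") {
  dt <- as.data.table(entries)
  if (!all(c("predicate", "category") %in% names(dt))) {
    stop("entries must have columns predicate and category", call. = FALSE)
  }
  dt <- dt[, .(predicate = normalize_predicate(as.character(predicate)),
               category = tolower(trimws(as.character(category))))]
  bad <- setdiff(unique(dt$category), c("directed", "undirected"))
  if (length(bad) > 0) {
    stop("invalid directionality category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dup <- dt[, .N, by = .(predicate, category)][, .N, by = predicate][N > 1]
  if (nrow(dup) > 0) {
    stop("conflicting categories for predicate(s): ",
         paste(dup$predicate, collapse = ", "), call. = FALSE)
  }
  dt <- unique(dt, by = "predicate")
  map <- stats::setNames(dt$category, dt$predicate)
  # prefixes keep their trailing space: "does not " must not match "does nothing"
  prefixes <- tolower(gsub("[[:space:]]+", " ", negation_prefixes))
  tab <- structure(list(entries = map, negation_prefixes = prefixes),
                   class = "directionality_table")
  # explicit negated entries must agree with their base predicate
  for (p in names(map)) {
    base <- .strip_negation(p, tab$negation_prefixes, known = names(map))
    if (!is.null(base) && base %in% names(map) && map[[base]] != map[[p]]) {
      stop(sprintf("negated predicate '%s' (%s) disagrees with base '%s' (%s)",
                   p, map[[p]], base, map[[base]]), call. = FALSE)
    }
  }
  tab
}

#' @export
print.directionality_table <- function(x, ...) {
  n <- table(factor(x$entries, levels = c("directed", "undirected")))
  cat(sprintf("<directionality_table> %d predicates (%d directed, %d undirected)\n",
              length(x$entries), n[["directed"]], n[["undirected"]]))
  invisible(x)
}

# Strip a negation prefix and re-conjugate the leading verb to third person
# ("does not interact with" -> "interacts with").  Returns the first match
# that exists in `known` (if given), else the plain stripped form, else NULL.
.strip_negation <- function(predicate, prefixes, known = NULL) {
  for (pre in prefixes) {
    if (startsWith(predicate, pre)) {
      base <- substring(predicate, nchar(pre) + 1L)
      if (!nzchar(base)) next
      words <- strsplit(base, " ", fixed = TRUE)[[1]]
      conj <- base
      if (length(words) >= 1) {
        w <- words[1]
        suff <- if (grepl("(s|x|z|ch|sh)$", w)) "es" else "s"
        words[1] <- paste0(w, suff)
        conj <- paste(words, collapse = " ")
      }
      if (!is.null(known)) {
        if (base %in% known) return(base)
        if (conj %in% known) return(conj)
      }
      return(base)
    }
  }
  NULL
}

#' Load a predicate directionality table from TSV
#'
#' Expects `predicate<TAB>category` with category `directed` or `undirected`;
#' `#` comment lines are skipped.
#'
#' @param path path to the TSV file.
#' @param negation_prefixes see [directionality_table()].
#' @return a `directionality_table`.
#' @export
load_directionality <- function(path, negation_prefixes = "does not ") {
  if (!file.exists(path)) {
    stop("directionality file not found: ", path, call. = FALSE)
  }
  dt <- fread(path, sep = "\t", header = FALSE, col.names = c("predicate", "category"))
  dt <- dt[!startsWith(trimws(predicate), "#")]
  directionality_table(dt, negation_prefixes)
}

#' The packaged 47-predicate directionality table
#'
#' Returns the reference table shipped with the package: 12 undirected and 35
#' directed protein-interaction predicates.  The undirected predicates follow
#' an expert consensus categorization; the directed predicate names are a
#' synthetic reconstruction of a typical standardized biomedical predicate
#' vocabulary (see the fixture file name).
#'
#' @return a `directionality_table` with 47 predicates.
#' @export
default_directionality <- function() {
  path <- system.file("extdata", "predicate_directionality_synthetic.tsv",
                      package = "trajpath", mustWork = TRUE)
  load_directionality(path)
}

#' Categorize a predicate as directed or undirected
#'
#' Looks the (normalized) predicate up in the table; if absent, strips a
#' negation prefix and returns the category of the base predicate, retrying
#' with a third-person re-conjugation of the leading verb so that e.g.
#' `"does not interact with"` resolves to `"interacts with"`.
#'
#' @param predicate character vector of predicate names.
#' @param table a [directionality_table()].
#' @param unknown what to do with predicates absent after negation stripping:
#'   `"error"` (default) or `"undirected"` to treat them as undirected.
#' @return character vector of categories (`"directed"` / `"undirected"`).
#' @export
categorize_predicate <- function(predicate, table,
                                 unknown = c("error", "undirected")) {
  stopifnot(inherits(table, "directionality_table"))
  unknown <- match.arg(unknown)
  p <- normalize_predicate(predicate)
  known <- names(table$entries)
  out <- unname(table$entries[p])
  miss <- which(is.na(out))
  for (i in miss) {
    base <- .strip_negation(p[i], table$negation_prefixes, known = known)
    if (!is.null(base) && base %in% known) {
      out[i] <- table$entries[[base]]
    } else if (unknown == "undirected") {
      out[i] <- "undirected"
    } else {
      stop(sprintf("unknown predicate: '%s'", p[i]), call. = FALSE)
    }
  }
  out
}

#' List edges between two proteins
#'
#' Returns every triple connecting `p` and `q`, annotated with its orientation
#' relative to the (p, q) query order: `forward` if the triple's subject is
#' `p`, `reverse` if it is `q`.  When `p == q`, each self-loop triple is
#' returned once with orientation `loop`.
#'
#' @param kg a `knowledge_graph`.
#' @param p,q protein identifiers (may be absent from the graph).
#' @return a data.table with columns `predicate` and `orientation`.
#' @export
edges_between <- function(kg, p, q) {
  stopifnot(inherits(kg, "knowledge_graph"))
  tr <- kg$triples
  if (p == q) {
    hit <- tr[subject == p & object == p]
    return(data.table(predicate = hit$predicate,
                      orientation = rep("loop", nrow(hit))))
  }
  fwd <- tr[subject == p & object == q]
  rev <- tr[subject == q & object == p]
  data.table(
    predicate = c(fwd$predicate, rev$predicate),
    orientation = c(rep("forward", nrow(fwd)), rep("reverse", nrow(rev)))
  )
}

# Internal: doubled non-loop edge table for path extraction.
# One row per (triple, traversal direction): columns x, y, predicate, orient
# ("fwd" iff the triple's subject is x), tid.  Self-loops are excluded; they
# participate only in the overlap scenario.
.kg_edge_table <- function(kg) {
  tr <- kg$triples[subject != object]
  rbindlist(list(
    tr[, .(x = subject, y = object, predicate, orient = "fwd", tid)],
    tr[, .(x = object, y = subject, predicate, orient = "rev", tid)]
  ))
}

# Internal: self-loop triples (protein, predicate)
.kg_loop_table <- function(kg) {
  kg$triples[subject == object, .(protein = subject, predicate)]
}
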