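# End-to-end pipeline: map diseases -> extract paths once -> featurize per
# variant -> cross-validate with a shared fold map -> pairwise paired
# comparisons between direction modes within each representation.

#' Run the full trajectory-classification experiment
#'
#' @param input either a [generate_benchmark()] object or a named list of file
#'   paths (`triples`, `directionality`, `mapping`, `hierarchy`,
#'   `associations`, `pairs`) in the loader formats.
#' @param variants named list of [feature_variant()]s (default: the four
#'   primary variants).
#' @param repeats,folds cross-validation design (default 10 x 10).
#' @param seed run-level seed; every stochastic step derives from it.
#' @param undersample_to optional `c(n_pos, n_neg)`: undersample the candidate
#'   set to these class counts before evaluation.
#' @param num.trees,mtry forest size, forwarded to [run_cv()].
#' @param out_dir optional output directory; when given, writes
#'   `summary.tsv`, `comparisons.tsv`, per-variant ROC coordinates, the
#'   feature matrices (sparse triplet form), and a `manifest.yaml` sufficient
#'   to reproduce the run.
#' @param quiet suppress progress messages.
#' @return an object of class `pipeline_result`: list with `summary`
#'   (data.table: variant, representation, direction, mean/sd AUC in %),
#'   `cv` (named list of [run_cv()] results), `comparisons` (data.table of
#'   paired t-tests between direction modes within each representation),
#'   `youden` (per-variant [roc_youden()] on pooled out-of-fold scores),
#'   `candidates`, and `manifest`.
#' @export
run_pipeline <- function(input, variants = primary_variants(),
                         repeats = 10, folds = 10, seed = 1,
                         undersample_to = NULL,
                         num.trees = 500, mtry = NULL,
                         out_dir = NULL, quiet = FALSE) {
  if (length(variants) == 0) stop("variant list must be non-empty", call. = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  if (inherits(input, "trajectory_benchmark")) {
    kg <- input$kg; dir_tab <- input$directionality
    mapping <- input$mapping; hierarchy <- input$hierarchy
    assoc <- input$associations; pairs <- input$pairs
    input_desc <- list(type = "benchmark", config = input$config[
      setdiff(names(input$config), "vocabulary")])
  } else {
    need <- c("triples", "directionality", "mapping", "hierarchy",
              "associations", "pairs")
    miss <- setdiff(need, names(input))
    if (length(miss) > 0) stop("missing input path(s): ",
                               paste(miss, collapse = ", "), call. = FALSE)
    for (f in need) if (!file.exists(input[[f]]))
      stop("input file not found: ", input[[f]], call. = FALSE)
    kg <- load_triples(input$triples, quiet = quiet)
    dir_tab <- load_directionality(input$directionality)
    mapping <- load_concept_mapping(input$mapping)
    hierarchy <- load_subclass_hierarchy(input$hierarchy)
    assoc <- load_associations(input$associations)
    pairs <- load_pairs(input$pairs)
    input_desc <- list(type = "files", paths = input)
  }

  say("stage: disease mapping")
  codes <- sort(unique(c(pairs$first, pairs$second)))
  protein_sets <- lapply(codes, assign_disease_proteins, mapping = mapping,
                         hierarchy = hierarchy, assoc = assoc, quiet = TRUE)
  names(protein_sets) <- codes
  candidates <- candidate_pairs(pairs, protein_sets, quiet = quiet)

  if (!is.null(undersample_to)) {
    idx <- undersample(candidates$label, undersample_to[1], undersample_to[2],
                       seed = seed)
    candidates <- candidates[idx]
    setattr(candidates, "class", c("candidate_set", "data.table", "data.frame"))
  }

  say("stage: path extraction (%d candidates)", nrow(candidates))
  paths <- extract_candidate_paths(candidates, kg)

  say("stage: featurization (%d variants)", length(variants))
  mats <- lapply(variants, function(v)
    featurize_paths(paths, v, dir_tab, labels = candidates$label))

  say("stage: cross-validation (%d repeats x %d folds)", repeats, folds)
  fold_map <- make_folds(candidates$label, folds = folds, repeats = repeats,
                         seed = seed)
  cv <- vector("list", length(mats)); names(cv) <- names(mats)
  for (nm in names(mats)) {
    cv[[nm]] <- run_cv(mats[[nm]], fold_map = fold_map, seed = seed,
                       num.trees = num.trees, mtry = mtry)
    say("  %s: mean AUC %.3f (sd %.3f)", nm, cv[[nm]]$mean_auc, cv[[nm]]$sd_auc)
  }

  summary <- rbindlist(lapply(names(cv), function(nm) {
    v <- variants[[nm]]
    data.table(variant = nm, representation = v$representation,
               direction = v$direction_mode,
               mean_auc = 100 * cv[[nm]]$mean_auc,
               sd_auc = 100 * cv[[nm]]$sd_auc,
               n_features = ncol(mats[[nm]]$matrix))
  }))

  # paired comparisons between direction modes within each representation
  comp_rows <- list()
  reps <- unique(vapply(variants, `[[`, "", "representation"))
  for (rp in reps) {
    nms <- names(variants)[vapply(variants, function(v) v$representation == rp,
                                  TRUE)]
    if (length(nms) < 2) next
    for (i in seq_along(nms)) for (j in seq_along(nms)) {
      if (i >= j) next
      pc <- paired_fold_ttest(cv[[nms[i]]], cv[[nms[j]]])
      comp_rows[[length(comp_rows) + 1L]] <-
        data.table(variant_a = nms[i], variant_b = nms[j],
                   mean_diff = 100 * pc$mean_diff, t = pc$t, df = pc$df,
                   p_value = pc$p_value)
    }
  }
  comparisons <- if (length(comp_rows)) rbindlist(comp_rows) else
    data.table(variant_a = character(), variant_b = character(),
               mean_diff = numeric(), t = numeric(), df = integer(),
               p_value = numeric())

  # Youden operating point per variant from pooled out-of-fold scores
  youden <- lapply(cv, function(r)
    roc_youden(rowMeans(r$scores), r$labels))

  manifest <- list(package = "trajpath",
                   version = as.character(utils::packageVersion("trajpath")),
                   seed = seed, repeats = repeats, folds = folds,
                   num.trees = num.trees,
                   variants = names(variants),
                   undersample_to = undersample_to,
                   n_candidates = nrow(candidates),
                   input = input_desc)

  result <- structure(list(summary = summary, cv = cv,
                           comparisons = comparisons, youden = youden,
                           candidates = candidates, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(out_dir)) .write_pipeline_outputs(result, mats, out_dir)
  result
}

.write_pipeline_outputs <- function(result, mats, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(result$summary, file.path(out_dir, "summary.tsv"), sep = "\t")
  fwrite(result$comparisons, file.path(out_dir, "comparisons.tsv"), sep = "\t")
  for (nm in names(result$cv)) {
    fwrite(result$cv[[nm]]$auc, file.path(out_dir, paste0("auc_", nm, ".tsv")),
           sep = "\t")
    fwrite(result$youden[[nm]]$roc, file.path(out_dir, paste0("roc_", nm, ".tsv")),
           sep = "\t")
    write_feature_matrix(mats[[nm]], file.path(out_dir, paste0("features_", nm)))
  }
  manifest_path <- file.path(out_dir, "manifest.yaml")
  if (requireNamespace("yaml", quietly = TRUE)) {
    writeLines(yaml::as.yaml(result$manifest), manifest_path)
  } else {
    dput(result$manifest, file = file.path(out_dir, "manifest.R"))
  }
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$summary)
  if (nrow(x$comparisons) > 0) {
    cat("paired comparisons:\n")
    print(x$comparisons)
  }
  invisible(x)
}
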