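# Evaluation: random-forest classification of candidate pairs under repeated,
# fold-matched cross-validation, with paired significance testing,
# undersampling, and ROC/Youden reporting.

#' Rank-based AUC
#'
#' Area under the ROC curve computed through the Mann-Whitney U relation:
#' the probability that a random positive scores above a random negative
#' (ties counted half).
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels: logical, 0/1, or a factor/character with
#'   positive class `"positive"`/`"pos"`/`"1"`/`"TRUE"`.
#' @return AUC as a fraction in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  y <- .as_binary(labels)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes required to compute AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.as_binary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
    return(as.integer(labels))
  }
  l <- tolower(as.character(labels))
  as.integer(l %in% c("positive", "pos", "1", "true", "yes"))
}

#' Stratified fold assignments for repeated cross-validation
#'
#' Each repeat partitions the candidates into `folds` folds, stratified by
#' class so every fold contains both classes.  The assignment is a pure
#' function of (`labels`, `folds`, `repeats`, `seed`) and is intended to be
#' shared across feature variants so their per-fold results can be compared
#' with a paired test.
#'
#' @param labels binary labels (see [auc_score()]).
#' @param folds number of folds per repeat (default 10).
#' @param repeats number of repeats (default 10).
#' @param seed integer seed.
#' @return an object of class `fold_map`: an integer matrix
#'   (candidates x repeats) of fold ids, with attributes `folds`, `repeats`,
#'   `seed`.
#' @export
make_folds <- function(labels, folds = 10, repeats = 10, seed = 1) {
  y <- .as_binary(labels)
  n <- length(y)
  if (min(sum(y == 1L), sum(y == 0L)) < folds) {
    stop(sprintf("cannot stratify: minority class has %d cases for %d folds",
                 min(sum(y == 1L), sum(y == 0L)), folds), call. = FALSE)
  }
  rng <- .local_rng(seed)
  m <- matrix(NA_integer_, nrow = n, ncol = repeats)
  for (r in seq_len(repeats)) {
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      idx <- idx[rng$sample(length(idx))]
      m[idx, r] <- rep_len(seq_len(folds), length(idx))
    }
  }
  structure(m, folds = folds, repeats = repeats, seed = seed, class = "fold_map")
}

# seeded RNG that does not disturb the caller's .Random.seed
.local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  run <- function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    expr_fun()
  }
  list(
    sample = function(n, size = n) run(function() sample.int(n, size)),
    int = function(max, n = 1L) run(function() sample.int(max, n, replace = TRUE)),
    unif = function(n) run(function() runif(n))
  )
}

#' Repeated cross-validation of a random forest
#'
#' Trains a probability random forest on each training split and scores the
#' held-out fold; reports one AUC per (repeat, fold).  Forest defaults follow
#' common practice (500 trees, sqrt(p) candidate features per split) and are
#' exposed as arguments.
#'
#' @param x a [featurize_paths()] `feature_matrix`, or a plain (sparse or
#'   dense) numeric matrix of features.
#' @param labels binary labels; defaults to the labels stored in `x`.
#' @param fold_map a [make_folds()] assignment to reuse (pass the same object
#'   for every variant of a paired comparison); if `NULL`, one is created
#'   from `folds`, `repeats`, `seed`.
#' @param folds,repeats,seed used when `fold_map` is `NULL`; `seed` also
#'   drives the per-fold forest seeds.
#' @param num.trees,mtry,... forwarded to [ranger::ranger()].
#' @param variant_name descriptive label stored in the result.
#' @return an object of class `cv_result`: list with `auc` (data.table
#'   `repeat_`, `fold`, `auc`), `scores` (matrix candidates x repeats of
#'   out-of-fold positive-class probabilities), `fold_map`, `mean_auc`,
#'   `sd_auc`, `variant`.
#' @export
run_cv <- function(x, labels = NULL, fold_map = NULL, folds = 10, repeats = 10,
                   seed = 1, num.trees = 500, mtry = NULL,
                   variant_name = NULL, ...) {
  if (inherits(x, "feature_matrix")) {
    if (is.null(labels)) labels <- x$labels
    if (is.null(variant_name)) variant_name <- format(x$variant)
    x <- x$matrix
  }
  if (is.null(labels)) stop("labels are required", call. = FALSE)
  y <- .as_binary(labels)
  if (length(y) != nrow(x)) stop("labels must align with matrix rows", call. = FALSE)
  if (length(unique(y)) < 2) stop("both classes required", call. = FALSE)
  if (is.null(fold_map)) fold_map <- make_folds(y, folds, repeats, seed)
  stopifnot(inherits(fold_map, "fold_map"), nrow(fold_map) == length(y))
  nf <- attr(fold_map, "folds")
  nr <- attr(fold_map, "repeats")

  xm <- as.matrix(x)
  storage.mode(xm) <- "double"
  # ranger is happier with syntactic names; signatures stay on the features
  sig_names <- colnames(xm)
  if (ncol(xm) > 0) colnames(xm) <- sprintf("f%06d", seq_len(ncol(xm)))
  yf <- factor(ifelse(y == 1L, "pos", "neg"), levels = c("neg", "pos"))

  rng <- .local_rng(seed + 1L)
  forest_seeds <- rng$int(.Machine$integer.max - 1L, nr * nf)
  res <- vector("list", nr * nf)
  scores <- matrix(NA_real_, nrow = length(y), ncol = nr)
  k <- 0L
  for (r in seq_len(nr)) {
    fr <- fold_map[, r]
    for (f in seq_len(nf)) {
      k <- k + 1L
      test <- which(fr == f)
      train <- which(fr != f)
      if (length(unique(y[test])) < 2 || length(unique(y[train])) < 2) {
        stop(sprintf("fold %d of repeat %d lacks a class", f, r), call. = FALSE)
      }
      if (ncol(xm) == 0) {
        prob <- rep(mean(y[train]), length(test))
      } else {
        fit <- ranger::ranger(
          x = xm[train, , drop = FALSE], y = yf[train],
          probability = TRUE, num.trees = num.trees, mtry = mtry,
          seed = forest_seeds[k], num.threads = 1, verbose = FALSE, ...)
        prob <- stats::predict(fit, data = xm[test, , drop = FALSE],
                               num.threads = 1, verbose = FALSE)$predictions[, "pos"]
      }
      scores[test, r] <- prob
      res[[k]] <- data.table(repeat_ = r, fold = f,
                             auc = auc_score(prob, y[test]))
    }
  }
  auc_dt <- rbindlist(res)
  structure(list(auc = auc_dt, scores = scores, fold_map = fold_map,
                 labels = y,
                 mean_auc = mean(auc_dt$auc), sd_auc = sd(auc_dt$auc),
                 variant = variant_name %||% "unnamed",
                 features = sig_names),
            class = "cv_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: mean AUC %.3f (sd %.3f) over %d repeat x fold cells\n",
              x$variant, x$mean_auc, x$sd_auc, nrow(x$auc)))
  invisible(x)
}

#' Paired t-test between two fold-matched CV results
#'
#' Tests whether the per-fold AUC difference between two feature variants is
#' zero, using a two-sided paired t-test over the matched (repeat, fold)
#' cells.  Both results must have been produced with the *identical* fold
#' map; unpaired comparison is refused.
#'
#' @param a,b `cv_result` objects sharing a fold map.
#' @param granularity `"fold"` pairs all repeat x fold cells (default);
#'   `"repeat"` pairs the per-repeat mean AUCs.
#' @return an object of class `paired_comparison`: list with `differences`,
#'   `t`, `df`, `p_value`, `mean_diff` (a minus b), and the variant names.
#'   When every difference is zero the comparison degenerates: `t = 0`,
#'   `p_value = 1` ("no difference" by convention).
#' @export
paired_fold_ttest <- function(a, b, granularity = c("fold", "repeat")) {
  stopifnot(inherits(a, "cv_result"), inherits(b, "cv_result"))
  granularity <- match.arg(granularity)
  if (!identical(unclass(a$fold_map), unclass(b$fold_map))) {
    stop("fold maps differ: paired comparison requires identical fold assignments",
         call. = FALSE)
  }
  da <- a$auc[order(repeat_, fold)]
  db <- b$auc[order(repeat_, fold)]
  if (granularity == "repeat") {
    da <- da[, .(auc = mean(auc)), by = repeat_]
    db <- db[, .(auc = mean(auc)), by = repeat_]
  }
  d <- da$auc - db$auc
  n <- length(d)
  s <- sd(d)
  if (is.na(s) || s == 0) {
    tstat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    tstat <- mean(d) / (s / sqrt(n))
    p <- 2 * pt(-abs(tstat), df = n - 1)
  }
  structure(list(differences = d, t = tstat, df = n - 1, p_value = p,
                 mean_diff = mean(d), variant_a = a$variant,
                 variant_b = b$variant, granularity = granularity),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s vs %s: mean AUC diff %+.4f, t(%d) = %.2f, p = %.3g\n",
              x$variant_a, x$variant_b, x$mean_diff, x$df, x$t, x$p_value))
  invisible(x)
}

#' Undersample a candidate set to fixed class counts
#'
#' Uniform random subset without replacement, seeded; used to match the
#' positive/negative design of a smaller reference set.
#'
#' @param labels binary labels.
#' @param n_pos,n_neg requested numbers of positive and negative cases.
#' @param seed integer seed.
#' @return sorted integer vector of retained row indices.
#' @export
undersample <- function(labels, n_pos, n_neg, seed = 1) {
  y <- .as_binary(labels)
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  if (n_pos > length(pos) || n_neg > length(neg)) {
    stop(sprintf("insufficient cases: requested %d/%d, available %d positives / %d negatives",
                 n_pos, n_neg, length(pos), length(neg)), call. = FALSE)
  }
  rng <- .local_rng(seed)
  sort(c(pos[rng$sample(length(pos))][seq_len(n_pos)],
         neg[rng$sample(length(neg))][seq_len(n_neg)]))
}

#' ROC curve and the Youden-optimal operating point
#'
#' Scans every distinct score as a cutoff (predict positive when
#' `score >= cutoff`) and returns the full ROC together with the cutoff
#' maximizing the Youden index J = sensitivity + specificity - 1.  Ties in J
#' are broken towards higher sensitivity, then towards the lower cutoff.
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels (both classes required).
#' @return an object of class `youden_result`: list with `roc` (data.table
#'   `cutoff`, `sensitivity`, `specificity`), `cutoff`, `sensitivity`,
#'   `specificity`, `youden` (J), and `auc`.
#' @export
roc_youden <- function(scores, labels) {
  y <- .as_binary(labels)
  if (length(unique(y)) < 2) stop("both classes required", call. = FALSE)
  cuts <- sort(unique(scores))
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  # at cutoff c: TP = #positives with score >= c, FP = #negatives >= c
  sens <- vapply(cuts, function(cc) sum(scores >= cc & y == 1L) / n1, 0)
  spec <- vapply(cuts, function(cc) sum(scores < cc & y == 0L) / n0, 0)
  roc <- data.table(cutoff = cuts, sensitivity = sens, specificity = spec)
  j <- sens + spec - 1
  best <- order(-j, -sens, cuts)[1]
  structure(list(roc = roc, cutoff = cuts[best], sensitivity = sens[best],
                 specificity = spec[best], youden = j[best],
                 auc = auc_score(scores, y)),
            class = "youden_result")
}

#' @export
print.youden_result <- function(x, ...) {
  cat(sprintf("<youden_result> AUC %.3f; at cutoff %.4g: sensitivity %.3f, specificity %.3f, J = %.3f\n",
              x$auc, x$cutoff, x$sensitivity, x$specificity, x$youden))
  invisible(x)
}
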