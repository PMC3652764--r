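#' Jackknife (leave-one-out) evaluation of a structural-class fit
#'
#' For each sequence, an SVM with the fit's chosen cost and gamma is
#' trained on the remaining n-1 sequences and used to predict the held-out
#' one. Per-class accuracy is `TP_j / |C_j|` and overall accuracy is
#' `sum_j TP_j / sum_j |C_j|`, which always equals the size-weighted mean
#' of the per-class accuracies. Jackknife itself is deterministic; the
#' only randomness in the pipeline is fold shuffling during parameter
#' selection.
#'
#' By default the parameter pair selected once on the full dataset is
#' reused for every leave-one-out split, mirroring the common procedure;
#' this is mildly optimistic because the held-out point participated in
#' parameter selection. `nested = TRUE` re-runs the grid search inside
#' every split for an unbiased (and much slower) estimate.
#'
#' A training split that has lost a class entirely (the held-out sequence
#' was its only member) proceeds without that class; a warning lists the
#' sequences affected.
#'
#' @param object A [psse_fit()] object.
#' @param nested Re-select cost/gamma within each leave-one-out split.
#' @param ... Passed to the inner grid search when `nested = TRUE`.
#' @return Object of class `psse_eval`: confusion matrix (true class in
#'   rows), per-class accuracy, overall accuracy, the predictions, and the
#'   parameters used.
#' @export
jackknife <- function(object, nested = FALSE, ...) {
  stopifnot(inherits(object, "psse_fit"))
  fm <- object$features
  y <- object$labels
  n <- nrow(fm)
  if (n < 2L) stop("jackknife needs at least two sequences", call. = FALSE)
  preds <- character(n)
  singletons <- character(0)
  for (i in seq_len(n)) {
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < nlevels(droplevels(y)))
      singletons <- c(singletons, rownames(fm)[i])
    par <- if (nested) {
      s <- svm_grid_search(fm[-i, , drop = FALSE], ytr,
                           folds = object$folds, seed = object$seed, ...)
      list(cost = s$cost, gamma = s$gamma)
    } else {
      list(cost = object$cost, gamma = object$gamma)
    }
    m <- e1071::svm(fm[-i, , drop = FALSE], ytr, kernel = "radial",
                    cost = par$cost, gamma = par$gamma, scale = FALSE)
    preds[i] <- as.character(stats::predict(m, fm[i, , drop = FALSE]))
  }
  if (length(singletons) > 0L)
    warning("class absent from training split for: ",
            paste(singletons, collapse = ", "), call. = FALSE)
  evaluation_report(truth = as.character(y), predicted = preds,
                    ids = rownames(fm),
                    cost = object$cost, gamma = object$gamma,
                    nested = nested)
}

#' Build an evaluation report from truth and predictions
#'
#' @param truth Character vector of true classes.
#' @param predicted Character vector of predicted classes.
#' @param ids Optional sequence ids.
#' @param cost,gamma,nested Provenance fields stored in the report.
#' @return Object of class `psse_eval`.
#' @export
evaluation_report <- function(truth, predicted, ids = NULL,
                              cost = NA_real_, gamma = NA_real_,
                              nested = FALSE) {
  stopifnot(length(truth) == length(predicted))
  classes <- sort(unique(truth))
  confusion <- table(true = factor(truth, classes),
                     predicted = factor(predicted,
                                        sort(unique(c(classes, predicted)))))
  per_class <- vapply(classes, function(cl) {
    sum(truth == cl & predicted == cl) / sum(truth == cl)
  }, numeric(1L))
  overall <- sum(truth == predicted) / length(truth)
  # overall accuracy must equal the size-weighted mean of class accuracies
  sizes <- vapply(classes, function(cl) sum(truth == cl), numeric(1L))
  stopifnot(isTRUE(all.equal(overall,
                             sum(per_class * sizes) / sum(sizes))))
  structure(list(confusion = confusion, per_class = per_class,
                 class_sizes = sizes, overall = overall,
                 predictions = stats::setNames(predicted, ids),
                 truth = stats::setNames(truth, ids),
                 cost = cost, gamma = gamma, nested = nested),
            class = "psse_eval")
}

#' Format an evaluation report as a percentage table
#'
#' One row per structural class plus an `Overall` row, accuracies as
#' percentages rounded to 2 decimals (the conventional reporting layout).
#' Classes with no members are marked `NA`.
#'
#' @param report A `psse_eval` object.
#' @return Data frame with columns `class`, `n`, `accuracy_pct`.
#' @export
accuracy_report <- function(report) {
  stopifnot(inherits(report, "psse_eval"))
  data.frame(
    class = c(names(report$per_class), "Overall"),
    n = c(unname(report$class_sizes), sum(report$class_sizes)),
    accuracy_pct = sprintf("%.2f", 100 * c(unname(report$per_class),
                                           report$overall)),
    stringsAsFactors = FALSE)
}

#' @export
print.psse_eval <- function(x, ...) {
  cat("Jackknife structural-class evaluation",
      if (x$nested) "(nested parameter selection)" else
        sprintf("(cost = %g, gamma = %g)", x$cost, x$gamma), "\n")
  print(accuracy_report(x), row.names = FALSE)
  cat("\nConfusion matrix (rows = true class):\n")
  print(x$confusion)
  invisible(x)
}

#' @export
summary.psse_eval <- function(object, ...) print(object, ...)
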