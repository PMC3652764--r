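#' Fit a structural-class SVM on secondary-structure features
#'
#' The central model of the package: a Gaussian-kernel (RBF) support
#' vector machine over a chosen feature set, with the cost and kernel
#' width selected by grid search. The grid defaults to the 11 powers of
#' two from 2^-5 to 2^5 for both parameters; each candidate pair is scored
#' by mean overall accuracy under stratified k-fold cross-validation
#' (default 10-fold) on the training data, and ties are broken toward
#' smaller cost, then smaller gamma. Multi-class prediction uses libsvm's
#' one-vs-one decomposition. Features are standardised to zero mean and
#' unit variance over the dataset before the kernel (disable with
#' `scale = FALSE`).
#'
#' @param x Named character vector of H/E/C strings, an `ss_dataset`, or a
#'   precomputed numeric feature matrix with row names.
#' @param labels Structural-class labels: named character vector (matched
#'   to sequences by name) or a vector parallel to `x`. Ignored when `x`
#'   is an `ss_dataset` carrying labels.
#' @param features Feature specification or preset name; see
#'   [feature_spec()]. Ignored when `x` is already a feature matrix.
#' @param pbf_k Truncation bound for the position-based statistic.
#' @param cost,gamma Candidate grids for the SVM parameters.
#' @param folds Cross-validation folds for parameter selection. Classes
#'   smaller than `folds` reduce the fold count with a warning.
#' @param scale Standardise feature columns before the kernel.
#' @param seed Integer seed controlling fold shuffling (the only
#'   stochastic element of fitting).
#' @return Object of class `psse_fit`: the fitted [e1071::svm] model plus
#'   the chosen parameters, the cross-validation accuracy surface, the
#'   (scaled) feature matrix, labels, and the scaling parameters.
#' @seealso [jackknife()], [predict.psse_fit()]
#' @export
psse_fit <- function(x, labels = NULL, features = "pbf11cbf", pbf_k = Inf,
                     cost = 2^(-5:5), gamma = 2^(-5:5), folds = 10L,
                     scale = TRUE, seed = 1L) {
  if (inherits(x, "ss_dataset")) {
    labels <- x$labels
    x <- x$sequences
  }
  if (is.matrix(x) && is.numeric(x)) {
    fm <- x
    spec <- attr(x, "spec")
    center <- attr(x, "center")
    scl <- attr(x, "scale")
    if (scale && is.null(center)) {
      center <- colMeans(fm)
      scl <- apply(fm, 2L, stats::sd)
      scl[scl == 0 | !is.finite(scl)] <- 1
      fm <- sweep(sweep(fm, 2L, center, "-"), 2L, scl, "/")
    }
  } else {
    spec <- if (is.character(features))
      feature_spec(features, pbf_k = pbf_k) else features
    fm <- assemble_features(x, spec, scale = scale)
    center <- attr(fm, "center")
    scl <- attr(fm, "scale")
  }
  if (is.null(labels))
    stop("`labels` are required", call. = FALSE)
  labels <- align_labels(fm, labels)
  y <- factor(labels)
  if (nlevels(y) < 2L)
    stop("need at least two structural classes to fit", call. = FALSE)
  sel <- svm_grid_search(fm, y, cost = cost, gamma = gamma,
                         folds = folds, seed = seed)
  model <- e1071::svm(fm, y, kernel = "radial", cost = sel$cost,
                      gamma = sel$gamma, scale = FALSE)
  structure(list(model = model, cost = sel$cost, gamma = sel$gamma,
                 cv_accuracy = sel$accuracy, grid = sel$grid,
                 features = fm, labels = y, spec = spec,
                 center = center, scale = scl, folds = sel$folds,
                 seed = seed, call = match.call()),
            class = "psse_fit")
}

align_labels <- function(fm, labels) {
  labels <- stats::setNames(normalize_class(labels), names(labels))
  if (!is.null(names(labels))) {
    orphans <- setdiff(rownames(fm), names(labels))
    if (length(orphans) > 0L)
      stop("sequences without labels: ",
           paste(utils::head(orphans, 5L), collapse = ", "),
           if (length(orphans) > 5L) ", ..." else "", call. = FALSE)
    labels <- labels[rownames(fm)]
  } else if (length(labels) != nrow(fm)) {
    stop("`labels` must be named or parallel to the sequences",
         call. = FALSE)
  }
  unname(labels)
}

# Plain shuffled k-fold assignment. Deliberately not stratified: exactly
# class-balanced training folds would mask the majority-class bias of
# over-regularised (tiny cost) candidates, which every leave-one-out
# training set exposes through its one-sample imbalance.
make_folds <- function(y, folds, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(folds), length(y)))
}

svm_grid_search <- function(fm, y, cost = 2^(-5:5), gamma = 2^(-5:5),
                            folds = 10L, seed = 1L) {
  stopifnot(length(cost) > 0L, length(gamma) > 0L, folds >= 2L)
  min_cls <- min(table(y))
  if (min_cls < folds) {
    folds <- max(2L, min_cls)
    warning("smallest class has fewer members than requested folds; ",
            "reduced to ", folds, "-fold cross-validation", call. = FALSE)
  }
  fold <- make_folds(y, folds, seed)
  cost <- sort(cost)
  gamma <- sort(gamma)
  grid <- matrix(NA_real_, length(cost), length(gamma),
                 dimnames = list(cost = format(cost, trim = TRUE),
                                 gamma = format(gamma, trim = TRUE)))
  best <- list(accuracy = -Inf)
  for (ci in seq_along(cost)) {
    for (gi in seq_along(gamma)) {
      correct <- 0L
      for (f in seq_len(folds)) {
        tr <- fold != f
        m <- e1071::svm(fm[tr, , drop = FALSE], droplevels(y[tr]),
                        kernel = "radial", cost = cost[ci],
                        gamma = gamma[gi], scale = FALSE)
        pred <- stats::predict(m, fm[!tr, , drop = FALSE])
        correct <- correct + sum(as.character(pred) ==
                                   as.character(y[!tr]))
      }
      acc <- correct / length(y)
      grid[ci, gi] <- acc
      # strict improvement only: earlier (smaller) cost, then gamma, wins ties
      if (acc > best$accuracy)
        best <- list(cost = cost[ci], gamma = gamma[gi], accuracy = acc)
    }
  }
  c(best, list(grid = grid, folds = folds))
}

#' @export
print.psse_fit <- function(x, ...) {
  cat("Structural-class SVM fit\n")
  cat("  features:", if (inherits(x$spec, "feature_spec")) x$spec$name
      else "precomputed matrix",
      sprintf("(%d columns, %d sequences)\n",
              ncol(x$features), nrow(x$features)))
  cat(sprintf("  chosen cost = %g, gamma = %g (%d-fold CV accuracy %.4f)\n",
              x$cost, x$gamma, x$folds, x$cv_accuracy))
  invisible(x)
}

#' @export
summary.psse_fit <- function(object, ...) {
  print(object)
  cat("  class sizes:\n")
  print(table(object$labels))
  cat("  training (resubstitution) accuracy:",
      sprintf("%.4f\n", mean(stats::predict(object$model, object$features)
                             == object$labels)))
  invisible(object)
}

#' Predict structural classes for new sequences
#'
#' Recomputes the fit's feature set on the new sequences, replays the
#' training standardisation, and applies the fitted SVM.
#'
#' @param object A [psse_fit()] object.
#' @param newdata Named character vector of H/E/C strings, an
#'   `ss_dataset`, or a feature matrix with the fit's columns. Omitted:
#'   fitted classes for the training sequences.
#' @param ... Unused.
#' @return Factor of predicted classes, named by sequence id.
#' @export
predict.psse_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    p <- stats::predict(object$model, object$features)
    return(stats::setNames(p, rownames(object$features)))
  }
  if (inherits(newdata, "ss_dataset")) newdata <- newdata$sequences
  fm <- if (is.matrix(newdata) && is.numeric(newdata)) newdata
        else assemble_features(newdata, object$spec, scale = FALSE)
  fm <- fm[, colnames(object$features), drop = FALSE]
  if (!is.null(object$center))
    fm <- sweep(sweep(fm, 2L, object$center, "-"), 2L, object$scale, "/")
  stats::setNames(stats::predict(object$model, fm), rownames(fm))
}
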