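#' Bagged classification trees over gene expression
#'
#' Fits an ensemble of unpruned binary classification trees, each on a
#' bootstrap sample of the columns (samples) of `x`, with every gene available
#' as a split candidate at every node (bagging, no feature subsampling).
#' Trees record the positive-class fraction of their in-bag observations in
#' each leaf, which is what [score_samples()] averages into a response score.
#' All randomness (bootstrap draws, split tie-breaks, importance permutations)
#' comes from an internal seeded stream, one substream per tree, so the fit is
#' bit-reproducible for a given `(x, labels, seed)` and independent of R's
#' global RNG.
#'
#' @param x numeric genes x samples matrix.
#' @param labels per-sample class labels (length `ncol(x)`).
#' @param positive_class label treated as the positive class (scores are the
#'   leaf fraction of this class).
#' @param n_trees number of trees (default 500).
#' @param seed integer seed.
#' @param min_node minimum observations per child node (default 1: trees grown
#'   to purity, the bagging convention for small-n classification).
#' @return an object of class `bagged_forest`.
#' @export
bagged_forest <- function(x, labels, positive_class, n_trees = 500, seed = 1,
                          min_node = 1) {
  if (ncol(x) != length(labels)) stop_("labels must match the matrix columns")
  labels <- as.character(labels)
  classes <- unique(labels)
  if (!positive_class %in% classes) stop_("positive_class '%s' not present", positive_class)
  if (length(classes) < 2L) stop_("training data contains a single class")
  y <- as.integer(labels == positive_class)
  if (sum(y) < 1L || sum(1 - y) < 1L) stop_("both classes must be non-empty")
  xt <- t(unclass(x))                    # samples in rows for the C++ core
  fit <- cpp_forest_fit(xt, y, as.integer(n_trees), as.double(seed),
                        as.integer(min_node))
  structure(list(trees = fit$trees, inbag = fit$inbag, genes = rownames(x),
                 y = y, x_train = xt, labels = labels,
                 positive_class = positive_class, n_trees = n_trees,
                 seed = seed),
            class = "bagged_forest")
}

#' @export
print.bagged_forest <- function(x, ...) {
  cat(sprintf("<bagged_forest: %d trees, %d genes, %d samples (%d positive '%s')>\n",
              x$n_trees, length(x$genes), length(x$y), sum(x$y), x$positive_class))
  cat(sprintf("  OOB error: %.4f\n", oob_error(x)))
  invisible(x)
}

# align newdata genes to the training gene order, samples in rows
forest_newdata <- function(object, newdata) {
  missing <- setdiff(object$genes, rownames(newdata))
  if (length(missing))
    stop_("gene(s) absent from data: %s", paste(missing, collapse = ", "))
  t(unclass(newdata)[object$genes, , drop = FALSE])
}

#' Predict leaf-fraction scores or classes from a bagged forest
#' @param object a [bagged_forest()].
#' @param newdata genes x samples matrix containing the training genes.
#' @param type `"score"` (mean leaf positive-class fraction, in \[0,1\]) or
#'   `"class"` (score > 0.5 cut).
#' @param ... unused.
#' @return named numeric scores or character labels.
#' @export
predict.bagged_forest <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  xt <- forest_newdata(object, newdata)
  sc <- cpp_forest_score(object$trees, xt)
  names(sc) <- rownames(xt)
  if (type == "score") return(sc)
  neg <- setdiff(unique(object$labels), object$positive_class)[1]
  setNames(ifelse(sc > 0.5, object$positive_class, neg), names(sc))
}

#' Out-of-bag misclassification error of a bagged forest
#' @param forest a [bagged_forest()].
#' @return fraction of samples (with at least one OOB tree) whose OOB score
#'   misclassifies them.
#' @export
oob_error <- function(forest) {
  cpp_forest_oob(forest$trees, forest$inbag, forest$x_train, forest$y)$oob_error
}

#' Out-of-bag permutation importance
#'
#' Mean decrease in OOB accuracy across trees when one gene's values are
#' permuted among the tree's OOB samples. Genes a tree never splits on
#' contribute exactly zero for that tree; importance can be negative for
#' genes whose splits hurt OOB accuracy.
#'
#' @param forest a [bagged_forest()].
#' @return named numeric vector of importances (one per training gene).
#' @export
permutation_importance <- function(forest) {
  imp <- cpp_forest_importance(forest$trees, forest$inbag, forest$x_train,
                               forest$y, as.double(forest$seed))
  setNames(imp, forest$genes)
}
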