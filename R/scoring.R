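#' Quantile normalize a target cohort onto a reference distribution
#'
#' Restricts both matrices to their shared (uppercased) gene symbols, builds
#' the reference quantile profile as the mean of the sorted reference columns,
#' and rank-maps every target column onto that profile. Tied target values
#' receive the mean of the profile values their positions span.
#'
#' @param target genes x samples matrix to normalize.
#' @param reference genes x samples matrix defining the distribution
#'   (typically the training cohort).
#' @return normalized target matrix restricted to the shared genes.
#' @export
quantile_normalize_to_reference <- function(target, reference) {
  rt <- toupper(rownames(target)); rr <- toupper(rownames(reference))
  shared <- intersect(rt, rr)
  if (length(shared) == 0L) stop_("no shared genes between target and reference")
  tm <- unclass(target)[match(shared, rt), , drop = FALSE]
  rm_ <- unclass(reference)[match(shared, rr), , drop = FALSE]
  rownames(tm) <- shared; rownames(rm_) <- shared

  profile <- rowMeans(apply(rm_, 2, sort))      # mean of sorted reference columns
  mapped <- apply(tm, 2, function(x) {
    o <- order(x)
    sx <- x[o]
    grp <- cumsum(c(TRUE, diff(sx) != 0))       # tie groups in sorted order
    out <- numeric(length(x))
    out[o] <- ave(profile, grp)                 # ties get the mean profile value
    out
  })
  rownames(mapped) <- shared
  expression_matrix(mapped, "normalized")
}

#' Restrict a signature to the genes a platform measures
#'
#' @param signature a [gene_set()].
#' @param platform_genes character vector of gene symbols available on the
#'   target platform.
#' @return the intersection as a `gene_set` (signature order preserved) with a
#'   `dropped` attribute listing the symbols lost.
#' @export
restrict_signature <- function(signature, platform_genes) {
  sig <- toupper(as.character(signature))
  plat <- toupper(as.character(platform_genes))
  kept <- sig[sig %in% plat]
  if (length(kept) == 0L) stop_("no signature gene is measured on the platform")
  out <- gene_set(kept, name = paste0(attr(signature, "name") %||% "signature", "_restricted"))
  attr(out, "dropped") <- setdiff(sig, plat)
  out
}

#' Train a response-scoring model
#'
#' Bagged classification trees over the signature genes, prototypical
#' responders (positive class) against all other training samples.
#'
#' @param train genes x samples training matrix (quantile-normalized scale
#'   shared with anything that will be scored).
#' @param meta sample sheet for the training samples (`sample_id`, `group`).
#' @param signature a [gene_set()]; all genes must be present in `train`.
#' @param n_trees trees in the ensemble (default 500).
#' @param seed integer seed.
#' @return an object of class `response_model`.
#' @export
train_response_model <- function(train, meta, signature, n_trees = 500, seed = 1) {
  sig <- as.character(signature)
  missing <- setdiff(sig, rownames(train))
  if (length(missing))
    stop_("signature gene(s) absent from training matrix: %s",
          paste(missing, collapse = ", "))
  meta <- meta[match(colnames(train), meta$sample_id), , drop = FALSE]
  labels <- ifelse(meta$group == "responder", "responder", "other")
  if (length(unique(labels)) < 2L) stop_("training data contains a single class")
  forest <- bagged_forest(unclass(train)[sig, , drop = FALSE], labels,
                          positive_class = "responder",
                          n_trees = n_trees, seed = seed)
  structure(list(forest = forest, genes_used = signature,
                 positive_class = "responder", n_trees = n_trees, seed = seed),
            class = "response_model")
}

#' @export
print.response_model <- function(x, ...) {
  cat(sprintf("<response_model: %d genes, %d trees, positive class '%s'>\n",
              length(x$genes_used), x$n_trees, x$positive_class))
  invisible(x)
}

#' Leaf-fraction response scores
#'
#' For every sample and every tree, the fraction of the reached leaf's
#' training observations belonging to the responder class, averaged over all
#' trees: a score in \[0, 1\].
#'
#' @param model a [train_response_model()] fit.
#' @param data genes x samples matrix on the model's scale (quantile
#'   normalize external cohorts to the training reference first).
#' @return named numeric vector of scores.
#' @export
score_samples <- function(model, data) {
  predict(model$forest, data, type = "score")
}

#' Split response scores into high and low groups
#'
#' @param scores named numeric score vector.
#' @param rule `"threshold"` (fixed cut) or `"median"` (cohort median as cut).
#' @param threshold cut value for the threshold rule (default 0.5).
#' @return named character vector, `"high"` iff score strictly exceeds the cut.
#' @export
dichotomize_scores <- function(scores, rule = c("threshold", "median"),
                               threshold = 0.5) {
  rule <- match.arg(rule)
  if (length(scores) == 0L) stop_("no scores supplied")
  cut <- if (rule == "median") median(scores) else threshold
  setNames(ifelse(scores > cut, "high", "low"), names(scores))
}
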