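#' Parameters for signature derivation
#'
#' @param fold_threshold minimum group-mean fold difference for the prefilter
#'   (default 2, i.e. "at least 2-fold in either direction").
#' @param n_trees trees per bagged ensemble (default 500).
#' @param oob_target out-of-bag error at or below which an all-positive
#'   importance fit counts as converged (default 0.10).
#' @param max_iterations cap on pruning iterations (default 100).
#' @param min_genes stop pruning when at most this many genes remain (default 5).
#' @param pseudocount added to group means before fold ratios (default 0.5).
#' @param cluster_sep_threshold minimum mean |standardized between-group
#'   difference| for a correlation cluster to survive refinement (default 1.0).
#' @param seed integer seed for all ensembles in the derivation.
#' @return a list of class `derivation_params`.
#' @export
derivation_params <- function(fold_threshold = 2, n_trees = 500,
                              oob_target = 0.10, max_iterations = 100,
                              min_genes = 5, pseudocount = 0.5,
                              cluster_sep_threshold = 1.0, seed = 1) {
  stopifnot(fold_threshold > 1, n_trees >= 1, oob_target > 0, oob_target < 1,
            max_iterations >= 1, min_genes >= 1, pseudocount >= 0)
  structure(list(fold_threshold = fold_threshold, n_trees = n_trees,
                 oob_target = oob_target, max_iterations = max_iterations,
                 min_genes = min_genes, pseudocount = pseudocount,
                 cluster_sep_threshold = cluster_sep_threshold, seed = seed),
            class = "derivation_params")
}

#' Median-of-ratios normalization of a count matrix
#'
#' Per-sample size factors are the median, over genes with a strictly positive
#' geometric mean across samples, of the gene's count divided by that
#' geometric mean; counts are divided by the size factor.
#'
#' @param mat genes x samples raw count matrix.
#' @return normalized matrix (`value_kind = "normalized"`) with a
#'   `size_factors` attribute.
#' @export
median_of_ratios_normalize <- function(mat) {
  m <- unclass(mat)
  zero_samples <- colSums(m) == 0
  if (any(zero_samples))
    stop_("sample(s) with all-zero counts: %s",
          paste(colnames(m)[zero_samples], collapse = ", "))
  loggm <- rowMeans(log(m))              # -Inf whenever a gene has any zero
  use <- is.finite(loggm)
  if (!any(use)) stop_("no gene has a positive geometric mean across samples")
  logratios <- log(m[use, , drop = FALSE]) - loggm[use]
  sf <- exp(apply(logratios, 2, median))
  out <- sweep(m, 2, sf, "/")
  out <- expression_matrix(out, "normalized")
  attr(out, "size_factors") <- setNames(sf, colnames(m))
  out
}

group_means <- function(mat, meta) {
  m <- unclass(mat)
  r <- meta$sample_id[meta$group == "responder"]
  n <- meta$sample_id[meta$group == "nonresponder"]
  if (length(r) == 0L || length(n) == 0L)
    stop_("both responder and nonresponder groups must be non-empty")
  list(responder = rowMeans(m[, r, drop = FALSE]),
       nonresponder = rowMeans(m[, n, drop = FALSE]))
}

#' Fold-change prefilter between responders and non-responders
#'
#' Retains genes whose pseudocounted group-mean ratio
#' `(mean_responder + c) / (mean_nonresponder + c)` is at least
#' `fold_threshold` or at most `1/fold_threshold`.
#'
#' @param mat normalized genes x samples matrix.
#' @param meta sample sheet with `sample_id` and `group` columns.
#' @param params a [derivation_params()].
#' @return a [gene_set()] of retained genes (may be empty only as an error).
#' @export
fold_filter <- function(mat, meta, params = derivation_params()) {
  gm <- group_means(mat, meta)
  ratio <- (gm$responder + params$pseudocount) / (gm$nonresponder + params$pseudocount)
  keep <- ratio >= params$fold_threshold | ratio <= 1 / params$fold_threshold
  nm <- sprintf("fold%g_filtered", params$fold_threshold)
  if (!any(keep))                        # a legitimate (if useless) outcome
    return(structure(character(0), name = nm, class = c("gene_set", "character")))
  gene_set(rownames(mat)[keep], name = nm)
}

#' Iterative bagged-tree importance pruning
#'
#' Fits a bagged-tree classifier of responders vs non-responders on the
#' current gene set, removes every gene with zero or negative OOB permutation
#' importance, and repeats until all remaining genes have positive importance
#' (converged when the OOB error is also at or below `oob_target`), the gene
#' set stops changing, at most `min_genes` genes remain, or `max_iterations`
#' is reached.
#'
#' @param mat normalized genes x samples matrix.
#' @param meta sample sheet (`sample_id`, `group` in
#'   responder/nonresponder).
#' @param params a [derivation_params()].
#' @param genes starting gene set; defaults to `fold_filter(mat, meta, params)`.
#' @return a `signature_trace`: iteration history, final gene set and
#'   importances, convergence flag.
#' @export
rf_iterative_select <- function(mat, meta, params = derivation_params(),
                                genes = NULL) {
  meta <- meta[meta$group %in% c("responder", "nonresponder"), , drop = FALSE]
  counts <- table(meta$group)
  if (length(counts) < 2L) stop_("one class is empty")
  if (any(counts < 2L)) stop_("need at least 2 samples per class")
  if (is.null(genes)) genes <- fold_filter(mat, meta, params)
  genes <- match_gene_rows(genes, mat)
  if (length(genes) == 0L) stop_("starting gene set is empty")
  m <- unclass(mat)[, meta$sample_id, drop = FALSE]

  iterations <- list(); dropped <- list()
  fit <- NULL; imp <- NULL; oob <- NA_real_; converged <- FALSE
  for (it in seq_len(params$max_iterations)) {
    fit <- bagged_forest(m[genes, , drop = FALSE], meta$group,
                         positive_class = "responder",
                         n_trees = params$n_trees,
                         seed = substream_seed(params$seed, it))
    imp <- permutation_importance(fit)
    oob <- oob_error(fit)
    drop <- names(imp)[imp <= 0]
    keep <- names(imp)[imp > 0]
    iterations[[it]] <- data.frame(iteration = it, n_genes = length(genes),
                                   oob_error = oob, n_dropped = length(drop))
    dropped[[it]] <- drop
    if (length(drop) == 0L) {            # all importances positive: stop
      converged <- oob <= params$oob_target
      break
    }
    if (length(keep) <= params$min_genes) {
      genes <- if (length(keep)) keep else
        names(sort(imp, decreasing = TRUE))[seq_len(min(params$min_genes, length(imp)))]
      fit <- bagged_forest(m[genes, , drop = FALSE], meta$group,
                           positive_class = "responder",
                           n_trees = params$n_trees,
                           seed = substream_seed(params$seed, it + 1L))
      imp <- permutation_importance(fit)
      oob <- oob_error(fit)
      converged <- all(imp > 0) && oob <= params$oob_target
      iterations[[it + 1L]] <- data.frame(iteration = it + 1L,
                                          n_genes = length(genes),
                                          oob_error = oob, n_dropped = 0L)
      dropped[[it + 1L]] <- character()
      break
    }
    genes <- keep
  }
  final <- if (any(imp > 0)) names(imp)[imp > 0] else names(imp)
  structure(list(iterations = do.call(rbind, iterations), dropped = dropped,
                 final_genes = gene_set(final, "rf_selected"),
                 final_importances = imp[final],
                 final_oob_error = oob, converged = converged,
                 forest = fit, params = params),
            class = "signature_trace")
}

#' @export
print.signature_trace <- function(x, ...) {
  cat(sprintf("<signature_trace: %d iteration(s), %d final gene(s), OOB %.3f%s>\n",
              nrow(x$iterations), length(x$final_genes), x$final_oob_error,
              if (x$converged) ", converged" else ""))
  print(x$iterations, row.names = FALSE)
  invisible(x)
}

# per-gene standardized between-group difference on the log scale
standardized_group_diff <- function(m, meta) {
  lg <- log2(m + 0.5)
  r <- meta$sample_id[meta$group == "responder"]
  n <- meta$sample_id[meta$group == "nonresponder"]
  mr <- rowMeans(lg[, r, drop = FALSE]); mn <- rowMeans(lg[, n, drop = FALSE])
  vr <- apply(lg[, r, drop = FALSE], 1, var); vn <- apply(lg[, n, drop = FALSE], 1, var)
  pooled <- sqrt(((length(r) - 1) * vr + (length(n) - 1) * vn) /
                   (length(r) + length(n) - 2))
  d <- (mr - mn) / pooled
  d[pooled == 0 & mr == mn] <- 0
  d[pooled == 0 & mr != mn] <- Inf * sign(mr - mn)[pooled == 0 & mr != mn]
  d
}

#' Correlation-cluster refinement of a gene signature
#'
#' Automated surrogate for heatmap-guided visual refinement: genes are
#' clustered by average-linkage hierarchical clustering on `1 - Pearson`
#' correlation distance (tree cut at height 0.5, i.e. within-cluster
#' correlation of at least 0.5); clusters whose mean absolute standardized
#' between-group difference falls below `cluster_sep_threshold` are
#' discarded; the survivors are passed once more through
#' [rf_iterative_select()].
#'
#' @param mat normalized genes x samples matrix.
#' @param meta sample sheet.
#' @param genes gene set to refine; returned unchanged when fewer than 2.
#' @param params a [derivation_params()].
#' @return refined `signature_trace` (or the input genes wrapped unchanged
#'   when refinement is not applicable).
#' @export
cluster_refine <- function(mat, meta, genes, params = derivation_params()) {
  genes <- match_gene_rows(genes, mat)
  if (length(genes) < 2L)
    return(structure(list(iterations = NULL, dropped = list(),
                          final_genes = gene_set(genes, "refined"),
                          final_importances = NULL, final_oob_error = NA_real_,
                          converged = NA, forest = NULL, params = params),
                     class = "signature_trace"))
  meta <- meta[meta$group %in% c("responder", "nonresponder"), , drop = FALSE]
  m <- unclass(mat)[genes, meta$sample_id, drop = FALSE]
  cc <- suppressWarnings(cor(t(log2(m + 0.5))))
  cc[is.na(cc)] <- 0                     # constant genes: no correlation signal
  hc <- hclust(as.dist(1 - cc), method = "average")
  cl <- cutree(hc, h = 0.5)
  d <- abs(standardized_group_diff(m, meta))
  d[!is.finite(d)] <- max(d[is.finite(d)], 1) + 1
  sep <- tapply(d, cl, mean)
  keep_cl <- names(sep)[sep >= params$cluster_sep_threshold]
  if (length(keep_cl) == 0L) keep_cl <- names(sep)[which.max(sep)]  # fallback: best cluster
  survivors <- genes[cl %in% as.integer(keep_cl)]
  # the second RF pass re-estimates importances with an independent substream
  params2 <- params
  params2$seed <- substream_seed(params$seed, 7919L)
  rf_iterative_select(mat, meta, params2, genes = survivors)
}

#' Fraction of variance on the first principal component
#'
#' PCA of the gene-centered signature submatrix with samples as observations;
#' returns the share of total variance carried by PC1.
#'
#' @param mat genes x samples matrix.
#' @param genes gene set (at least 2 genes present in `mat`).
#' @return fraction in \[0, 1\].
#' @export
pc1_variance <- function(mat, genes) {
  genes <- match_gene_rows(genes, mat)
  if (length(genes) < 2L) stop_("need at least 2 genes present in the matrix")
  if (ncol(mat) < 2L) stop_("need at least 2 samples")
  sub <- t(unclass(mat)[genes, , drop = FALSE])  # samples x genes
  p <- prcomp(sub, center = TRUE, scale. = FALSE)
  tot <- sum(p$sdev^2)
  if (tot == 0) stop_("zero total variance in the signature submatrix")
  p$sdev[1]^2 / tot
}

#' Full signature derivation pipeline
#'
#' Normalizes raw counts (median-of-ratios), restricts to one timepoint's
#' samples with responder/nonresponder labels, applies the fold-change
#' prefilter, iterative bagged-tree importance pruning and correlation-cluster
#' refinement, and reports the PC1 variance fraction of the final signature.
#'
#' @param mat genes x samples matrix (raw counts or already normalized).
#' @param meta sample sheet (`sample_id`, `patient_id`, `timepoint`, `group`).
#' @param timepoint `"surgical"` (post-treatment signature) or `"core"`
#'   (pre-treatment signature).
#' @param params a [derivation_params()].
#' @return a `signature_trace` with an added `pc1_fraction` element.
#' @export
derive_signature <- function(mat, meta, timepoint = c("surgical", "core"),
                             params = derivation_params()) {
  timepoint <- match.arg(timepoint)
  if (value_kind(mat) == "raw_counts") mat <- median_of_ratios_normalize(mat)
  meta <- meta[meta$timepoint == timepoint &
                 meta$group %in% c("responder", "nonresponder"), , drop = FALSE]
  if (nrow(meta) == 0L) stop_("no labeled samples at timepoint '%s'", timepoint)
  sub <- mat[, meta$sample_id, drop = FALSE]
  start <- fold_filter(sub, meta, params)
  trace <- rf_iterative_select(sub, meta, params, genes = start)
  trace <- cluster_refine(sub, meta, trace$final_genes, params)
  # PC1 share on the log scale, so one high-variance count gene cannot
  # dominate the decomposition
  logsub <- log2(unclass(sub) + 0.5)
  trace$pc1_fraction <- if (length(trace$final_genes) >= 2L)
    pc1_variance(logsub, trace$final_genes) else NA_real_
  trace$timepoint <- timepoint
  trace
}
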