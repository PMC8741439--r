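test_that("median-of-ratios size factors match the hand-evaluated toy case", {
  m <- matrix(c(4, 1, 16, 4), 2, 2,
              dimnames = list(c("G1", "G2"), c("A", "B")))
  norm <- median_of_ratios_normalize(m)
  sf <- attr(norm, "size_factors")
  expect_equal(unname(sf[2] / sf[1]), 4)                  # factors proportional to (1, 4)
  expect_equal(unname(unclass(norm)), matrix(c(8, 2, 8, 2), 2, 2),
               ignore_attr = TRUE)

  # sample B = 2 x sample A -> normalized columns equal
  m2 <- toy_matrix(50, 1, seed = 2)
  m2 <- cbind(A = m2[, 1], B = 2 * m2[, 1])
  n2 <- median_of_ratios_normalize(m2)
  expect_equal(unclass(n2)[, "A"], unclass(n2)[, "B"])

  # identical samples: size factors equal, values unchanged up to global scale
  m3 <- toy_matrix(30, 1, seed = 3)[, c(1, 1, 1)]
  colnames(m3) <- c("A", "B", "C")
  n3 <- median_of_ratios_normalize(m3)
  expect_equal(length(unique(round(attr(n3, "size_factors"), 12))), 1L)

  m4 <- cbind(m3, Z = 0)
  expect_error(median_of_ratios_normalize(m4), "all-zero")
})

test_that("fold_filter keeps strong fold changes, respects direction and threshold", {
  meta <- toy_meta(sprintf("S%02d", 1:8), n_resp = 4)
  m <- matrix(100, 6, 8, dimnames = list(sprintf("G%d", 1:6), meta$sample_id))
  resp <- meta$sample_id[meta$group == "responder"]
  m["G2", resp] <- 400      # 4-fold up in responders
  m["G3", resp] <- 110      # 1.1-fold: below threshold
  m["G4", resp] <- 25       # 4-fold down
  mm <- expression_matrix(m, "normalized")
  got <- fold_filter(mm, meta, derivation_params())
  expect_setequal(as.character(got), c("G2", "G4"))

  # symmetric in group labels (ratio inverts)
  meta_sw <- meta
  meta_sw$group <- ifelse(meta$group == "responder", "nonresponder", "responder")
  expect_setequal(as.character(fold_filter(mm, meta_sw, derivation_params())),
                  c("G2", "G4"))

  # near-1 threshold retains nearly everything; output monotone in threshold
  loose <- fold_filter(mm, meta, derivation_params(fold_threshold = 1.0001))
  expect_true(all(c("G2", "G3", "G4") %in% loose))
  for (th in c(1.5, 2, 3, 4.5)) {
    hi <- fold_filter(mm, meta, derivation_params(fold_threshold = th))
    expect_true(all(as.character(got) %in% as.character(loose)))
    expect_true(length(hi) <= length(loose))
  }

  # identical group means: empty set, not an error
  flat <- expression_matrix(matrix(100, 3, 8,
                                   dimnames = list(paste0("G", 1:3), meta$sample_id)),
                            "normalized")
  expect_length(fold_filter(flat, meta, derivation_params()), 0)
  expect_error(fold_filter(mm, meta[meta$group == "responder", ], derivation_params()),
               "non-empty")
})

test_that("rf_iterative_select keeps a perfect separator and terminates", {
  meta <- toy_meta(sprintf("S%02d", 1:13), n_resp = 3)
  set.seed(21)
  m <- matrix(rnorm(40 * 13, 100, 5), 40, 13,
              dimnames = list(sprintf("G%03d", 1:40), meta$sample_id))
  m["G007", ] <- ifelse(meta$group == "responder", 300, 50)
  mm <- expression_matrix(m, "normalized")
  tr <- rf_iterative_select(mm, meta, derivation_params(seed = 4),
                            genes = gene_set(rownames(m)))
  expect_true("G007" %in% as.character(tr$final_genes))
  expect_equal(tr$final_oob_error, 0)
  expect_true(tr$converged)
  expect_true(all(tr$final_importances > 0))
  # iteration gene counts strictly decreasing
  expect_true(all(diff(tr$iterations$n_genes) < 0))

  # bit-for-bit reproducible
  tr2 <- rf_iterative_select(mm, meta, derivation_params(seed = 4),
                             genes = gene_set(rownames(m)))
  expect_identical(as.character(tr$final_genes), as.character(tr2$final_genes))
  expect_identical(tr$iterations, tr2$iterations)
})

test_that("rf_iterative_select terminates on pure noise with chance-level OOB error", {
  meta <- toy_meta(sprintf("S%02d", 1:13), n_resp = 3)
  for (s in 1:3) {
    set.seed(s)
    m <- matrix(rnorm(60 * 13, 100, 10), 60, 13,
                dimnames = list(sprintf("G%03d", 1:60), meta$sample_id))
    mm <- expression_matrix(m, "normalized")
    tr <- rf_iterative_select(mm, meta, derivation_params(seed = s),
                              genes = gene_set(rownames(m)))
    expect_lte(nrow(tr$iterations), 100)
    # no infinite loop, and OOB error near the class prior (3/13), not near 0
    expect_gte(tr$final_oob_error, 0.05)
  }
})

test_that("cluster_refine discards a noise cluster but keeps the separating block", {
  meta <- toy_meta(sprintf("S%02d", 1:13), n_resp = 3)
  set.seed(31)
  resp <- meta$group == "responder"
  # block 1: 8 genes tracking the group labels (correlated via the group axis)
  sig <- t(sapply(1:8, function(i) ifelse(resp, 400, 100) * exp(rnorm(13, 0, 0.05))))
  # block 2: 8 genes sharing a latent factor orthogonal to the groups
  latent <- rnorm(13)
  noise <- t(sapply(1:8, function(i) 150 * exp(0.5 * latent + rnorm(13, 0, 0.05))))
  m <- rbind(sig, noise)
  dimnames(m) <- list(sprintf("G%03d", 1:16), meta$sample_id)
  mm <- expression_matrix(m, "normalized")
  out <- cluster_refine(mm, meta, gene_set(rownames(m)), derivation_params(seed = 5))
  fin <- as.character(out$final_genes)
  expect_true(all(fin %in% sprintf("G%03d", 1:8)))   # noise block removed
  expect_gte(length(fin), 4)

  # fewer than 2 genes: returned unchanged
  single <- cluster_refine(mm, meta, gene_set("G001"), derivation_params())
  expect_equal(as.character(single$final_genes), "G001")

  # threshold 0 discards nothing before the second RF pass
  p0 <- derivation_params(cluster_sep_threshold = 0, seed = 5)
  p0_seed <- p0; p0_seed$seed <- e2response:::substream_seed(5, 7919L)
  direct <- rf_iterative_select(mm, meta, p0_seed, genes = gene_set(rownames(m)))
  via <- cluster_refine(mm, meta, gene_set(rownames(m)), p0)
  expect_identical(as.character(via$final_genes), as.character(direct$final_genes))
})

test_that("pc1_variance matches an eigendecomposition oracle and its edge cases", {
  # rank-1 submatrix
  base <- outer(c(1, 2, 3, 4), c(2, 1, 4, 3, 5))
  dimnames(base) <- list(paste0("G", 1:4), paste0("S", 1:5))
  expect_equal(pc1_variance(base, gene_set(rownames(base))), 1)

  # two orthogonal equal-variance genes -> 0.5
  m2 <- rbind(G1 = c(1, -1, 1, -1), G2 = c(1, 1, -1, -1))
  colnames(m2) <- paste0("S", 1:4)
  expect_equal(pc1_variance(m2, gene_set(c("G1", "G2"))), 0.5)

  # random 5x8 matrix vs eigen() of the gene covariance
  set.seed(41)
  m <- matrix(rnorm(40), 5, 8, dimnames = list(paste0("G", 1:5), paste0("S", 1:8)))
  ev <- eigen(cov(t(m)), only.values = TRUE)$values
  expect_equal(pc1_variance(m, gene_set(rownames(m))), ev[1] / sum(ev))

  expect_error(pc1_variance(m, gene_set("G1")), "at least 2 genes")
  flat <- matrix(3, 3, 4, dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
  expect_error(pc1_variance(flat, gene_set(rownames(flat))), "zero total variance")
})
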