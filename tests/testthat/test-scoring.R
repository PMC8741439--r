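test_that("quantile normalization rank-maps onto the reference profile", {
  target <- matrix(c(5, 1, 3), 3, 1, dimnames = list(c("A", "B", "C"), "T1"))
  reference <- matrix(c(10, 20, 30), 3, 1, dimnames = list(c("A", "B", "C"), "R1"))
  got <- quantile_normalize_to_reference(target, reference)
  expect_equal(unname(unclass(got)[, 1]), c(30, 10, 20))

  # two-way tie: both tied values get the mean of the two profile slots
  t2 <- matrix(c(7, 2, 2, 9), 4, 1, dimnames = list(paste0("G", 1:4), "T1"))
  r2 <- matrix(c(100, 200, 300, 400), 4, 1, dimnames = list(paste0("G", 1:4), "R1"))
  got2 <- unclass(quantile_normalize_to_reference(t2, r2))[, 1]
  expect_equal(unname(got2), c(300, 150, 150, 400))

  # target already distributed like the profile: unchanged
  t3 <- matrix(c(30, 10, 20), 3, 1, dimnames = list(c("A", "B", "C"), "T1"))
  expect_equal(unclass(quantile_normalize_to_reference(t3, reference))[, 1],
               c(A = 30, B = 10, C = 20))

  expect_error(quantile_normalize_to_reference(
    matrix(1, 1, 1, dimnames = list("X", "T")), reference), "no shared genes")
})

test_that("after normalization every target column has exactly the reference quantiles", {
  set.seed(17)
  for (i in 1:10) {
    ng <- sample(20:60, 1)
    genes <- sprintf("G%03d", 1:ng)
    target <- matrix(rnorm(ng * 4, 50, 20), ng, 4,
                     dimnames = list(genes, paste0("T", 1:4)))
    reference <- matrix(rlnorm(ng * 3, 3, 1), ng, 3,
                        dimnames = list(genes, paste0("R", 1:3)))
    profile <- rowMeans(apply(reference, 2, sort))
    qn <- unclass(quantile_normalize_to_reference(target, reference))
    for (j in 1:4) expect_equal(unname(sort(qn[, j])), unname(profile))
  }
})

test_that("self-normalization agrees with the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(23)
  m <- matrix(rlnorm(200, 4, 1), 50, 4,
              dimnames = list(sprintf("G%03d", 1:50), paste0("S", 1:4)))
  ours <- unclass(quantile_normalize_to_reference(m, m))
  theirs <- limma::normalizeQuantiles(m, ties = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("restrict_signature intersects case-insensitively and reports drops", {
  core30 <- presto_signature("core30")
  core12 <- presto_signature("core12")
  got <- restrict_signature(core30, as.character(core12))
  expect_length(got, 12)
  expect_setequal(as.character(got), as.character(core12))
  expect_length(attr(got, "dropped"), 18)

  expect_equal(as.character(restrict_signature(core12, as.character(core30))),
               as.character(core12))
  expect_error(restrict_signature(gene_set("XXXX"), c("YYYY")), "no signature gene")
})

test_that("response models score responders above others and validate inputs", {
  set.seed(29)
  meta <- toy_meta(sprintf("S%02d", 1:13), n_resp = 3)
  m <- matrix(rlnorm(200 * 13, 5, 0.4), 200, 13,
              dimnames = list(sprintf("G%03d", 1:200), meta$sample_id))
  sig_genes <- sprintf("G%03d", 1:10)
  resp <- meta$group == "responder"
  m[sig_genes, resp] <- m[sig_genes, resp] * 4
  model <- train_response_model(m, meta, gene_set(sig_genes), n_trees = 300, seed = 8)
  sc <- score_samples(model, m)
  expect_true(min(sc[resp]) > max(sc[!resp]))
  expect_true(all(sc >= 0 & sc <= 1))

  expect_error(train_response_model(m, meta, gene_set("NOPE")), "NOPE")
  meta1 <- meta; meta1$group <- "nonresponder"
  expect_error(train_response_model(m, meta1, gene_set(sig_genes)), "single class")

  # a perfectly separating single gene: every splittable tree isolates it;
  # only bootstrap draws containing a single class (rare, balanced design)
  # could dilute the 1-vs-0 scores
  meta_b <- toy_meta(sprintf("S%02d", 1:12), n_resp = 6)
  resp_b <- meta_b$group == "responder"
  m1 <- matrix(ifelse(resp_b, 100, 10), 1, 12,
               dimnames = list("G001", meta_b$sample_id))
  mod1 <- train_response_model(m1, meta_b, gene_set("G001"), n_trees = 50, seed = 1)
  sc1 <- score_samples(mod1, m1)
  expect_equal(unname(sc1[resp_b]), rep(1, 6))
  expect_equal(unname(sc1[!resp_b]), rep(0, 6))
})

test_that("scores are invariant under joint per-gene affine maps, trees under any monotone map", {
  set.seed(37)
  meta <- toy_meta(sprintf("S%02d", 1:12), n_resp = 4)
  m <- matrix(rlnorm(30 * 12, 5, 0.5), 30, 12,
              dimnames = list(sprintf("G%03d", 1:30), meta$sample_id))
  sig <- gene_set(sprintf("G%03d", 1:6))
  m[as.character(sig), meta$group == "responder"] <-
    m[as.character(sig), meta$group == "responder"] * 3

  # affine per-gene rescaling moves thresholds exactly with the data:
  # scores are bit-identical
  scale <- runif(30, 0.5, 10); shift <- runif(30, -5, 5)
  m_aff <- m * scale + shift
  mod_raw <- train_response_model(m, meta, sig, n_trees = 100, seed = 5)
  mod_aff <- train_response_model(m_aff, meta, sig, n_trees = 100, seed = 5)
  expect_equal(score_samples(mod_raw, m), score_samples(mod_aff, m_aff))

  # a general monotone map (log) preserves every split decision on the data
  # the trees were grown from, hence identical tree structures; midpoint
  # thresholds may shift relative to held-out values, so only structure is
  # asserted
  mod_log <- train_response_model(log(m), meta, sig, n_trees = 100, seed = 5)
  expect_identical(lapply(mod_raw$forest$trees, `[[`, "feature"),
                   lapply(mod_log$forest$trees, `[[`, "feature"))
  expect_identical(lapply(mod_raw$forest$trees, `[[`, "frac"),
                   lapply(mod_log$forest$trees, `[[`, "frac"))
})

test_that("dichotomize_scores cuts strictly under both rules", {
  expect_equal(unname(dichotomize_scores(c(a = 0.9, b = 0.1))), c("high", "low"))
  expect_equal(unname(dichotomize_scores(c(a = 0.3, b = 0.3), rule = "median")),
               c("low", "low"))
  med <- dichotomize_scores(c(a = 0.2, b = 0.4, c = 0.6, d = 0.8), rule = "median")
  expect_equal(sum(med == "high"), 2L)
  expect_error(dichotomize_scores(numeric()), "no scores")
})
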