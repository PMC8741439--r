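rec <- presto_clinical()
ki67 <- paired_changes(rec, "ki67")
ror <- paired_changes(rec, "ror")

test_that("paired_changes builds one record per eligible patient", {
  expect_equal(nrow(ki67), 19L)
  expect_equal(nrow(ror), 13L)           # six patients lack a baseline ROR
  expect_equal(ki67$delta, ki67$post - ki67$baseline)
  expect_error(paired_changes(rec, "tumour"), "arg")

  flat <- paired_changes(toy_clinical("A", 40, 40), "ror")
  expect_equal(flat$delta, 0)
  expect_equal(flat$log_ratio, 0)
})

test_that("count_decreases is strict and partitions with ties and increases", {
  expect_equal(count_decreases(ki67), list(n_decrease = 13L, n_total = 19L))
  expect_equal(count_decreases(ror), list(n_decrease = 8L, n_total = 13L))
  expect_error(count_decreases(ror[0, ]), "no paired changes")

  zero <- paired_changes(toy_clinical(letters[1:4], rep(10, 4), rep(10, 4)), "ror")
  expect_equal(count_decreases(zero)$n_decrease, 0L)

  # decreases + ties + increases = total, over random datasets
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:15, 1)
    ch <- paired_changes(toy_clinical(paste0("p", 1:n),
                                      sample(10:60, n, TRUE),
                                      sample(10:60, n, TRUE)), "ror")
    expect_equal(count_decreases(ch)$n_decrease + sum(ch$delta == 0) +
                   sum(ch$delta > 0), n)
  }
})

test_that("geometric_mean_percent_change follows the log-mean formula", {
  # hand-derived: pairs 1->2, 4->2, 9->9 have log ratios ln2, -ln2, 0
  ch <- paired_changes(toy_clinical(c("a", "b", "c"), c(1, 4, 9), c(2, 2, 9)), "ror")
  expect_equal(geometric_mean_percent_change(ch), 0)

  doubled <- paired_changes(toy_clinical(c("a", "b"), c(3, 7), c(6, 14)), "ror")
  expect_equal(geometric_mean_percent_change(doubled), 100)

  bad <- paired_changes(toy_clinical(c("a", "b"), c(0, 5), c(2, 5)), "ror")
  expect_error(geometric_mean_percent_change(bad), "a")

  # invariance to patient order and to common positive rescaling
  set.seed(11)
  bx <- runif(8, 5, 50); sx <- runif(8, 5, 50)
  g1 <- geometric_mean_percent_change(
    paired_changes(toy_clinical(paste0("p", 1:8), bx, sx), "ror"))
  perm <- sample(8)
  g2 <- geometric_mean_percent_change(
    paired_changes(toy_clinical(paste0("q", 1:8), bx[perm], sx[perm]), "ror"))
  g3 <- geometric_mean_percent_change(
    paired_changes(toy_clinical(paste0("r", 1:8), 3.7 * bx, 3.7 * sx), "ror"))
  expect_equal(g1, g2)
  expect_equal(g1, g3)
})

test_that("paired_log_ttest matches numerical integration of the t density", {
  res <- paired_log_ttest(ki67)
  expect_equal(res$df, 18L)
  # oracle: two-tailed tail mass of the t density by numerical integration
  set.seed(7)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    ch <- paired_changes(toy_clinical(paste0("p", 1:n),
                                      runif(n, 5, 50), runif(n, 5, 50)), "ror")
    r <- paired_log_ttest(ch)
    p_int <- 2 * integrate(dt, abs(r$statistic), Inf, df = n - 1,
                           rel.tol = 1e-12)$value
    expect_equal(r$p_two_tailed, p_int, tolerance = 1e-10)
  }
  # degenerate difference vector (-1, 0, +1) in log space -> t = 0, p = 1
  ch0 <- paired_changes(toy_clinical(c("a", "b", "c"),
                                     c(exp(1), 1, 1), c(1, 1, exp(1))), "ror")
  r0 <- paired_log_ttest(ch0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_two_tailed, 1)

  same <- paired_changes(toy_clinical(c("a", "b"), c(2, 4), c(4, 8)), "ror")
  expect_error(paired_log_ttest(same), "zero variance")
  expect_error(paired_log_ttest(ch0[1, ]), "at least 2")
})

test_that("select_responders applies the one-sd-below-mean rule", {
  expect_equal(select_responders(ror), c("CCI-013", "CCI-006", "CCI-003"))
  # hand-derived threshold from the fixture deltas: mean -10, sd sqrt(3308/12)
  expect_equal(mean(ror$delta), -10)
  expect_equal(sd(ror$delta), sqrt(3308 / 12))
  expect_equal(sum(ror$delta < -10 - sqrt(3308 / 12)), 3L)

  eq <- paired_changes(toy_clinical(letters[1:5], rep(50, 5), rep(45, 5)), "ror")
  expect_length(select_responders(eq), 0)    # sd 0, strict inequality
  expect_error(select_responders(eq[1:2, ]), "at least 3")

  # shift invariance: the rule depends only on centered deltas
  shifted <- toy_clinical(rec$patient_id, rec$ror_bx + 7, rec$ror_sx + 7)
  expect_equal(select_responders(paired_changes(shifted, "ror")),
               select_responders(ror))
})

test_that("select_nonresponders takes the k smallest |delta| with id tie-break", {
  expect_equal(select_nonresponders(ror, 3), c("CCI-012", "CCI-014", "CCI-022"))
  expect_setequal(select_nonresponders(ror, nrow(ror)), ror$patient_id)
  expect_error(select_nonresponders(ror, 14), "exceeds")

  ties <- paired_changes(toy_clinical(c("b", "a", "c", "d"),
                                      c(50, 50, 50, 50), c(50, 50, 53, 45)), "ror")
  expect_equal(select_nonresponders(ties, 3), c("a", "b", "c"))
})

test_that("direction_kappa reproduces the fixture concordance and a brute-force oracle", {
  k <- direction_kappa(ki67, ror)
  expect_equal(k$n_pairs, 11L)            # two zero ROR changes excluded
  expect_equal(k$observed_agreement, 10 / 11)
  expect_equal(k$kappa, 32 / 43)          # hand-evaluated from the 2x2 table
  expect_equal(k$kappa, 0.7442, tolerance = 1e-4)

  # identical dichotomies give kappa 1
  same <- direction_kappa(ror, ror)
  expect_equal(same$kappa, 1)

  # random datasets vs the explicit 2x2 formula
  set.seed(13)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    ids <- paste0("p", 1:n)
    a <- paired_changes(toy_clinical(ids, sample(10:60, n, TRUE),
                                     sample(10:60, n, TRUE)), "ror")
    b <- paired_changes(toy_clinical(ids, sample(10:60, n, TRUE),
                                     sample(10:60, n, TRUE)), "ror")
    usable <- b$delta != 0
    if (sum(usable) < 2) next
    got <- direction_kappa(a, b)
    want <- kappa_bruteforce(a$delta[usable] > 0, b$delta[usable] > 0)
    expect_equal(got$kappa, want)
  }
  expect_error(direction_kappa(ki67[1, ], ror), "fewer than 2")
})
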