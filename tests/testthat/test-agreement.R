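test_that("consensus implements the at-least-3-of-4 rule", {
  expect_equal(consensus(c(1, 1, 1, 0)), 1)
  expect_true(is.na(consensus(c(1, 1, 0, 0))))
  expect_equal(consensus(c(2, 2, 2, 2)), 2)
  # missing raters leave both numerator and denominator
  expect_equal(consensus(c(1, 1, NA, NA)), 1)
  expect_true(is.na(consensus(c(1, 0, NA, NA))))
  expect_warning(res <- consensus(c(NA, NA, NA, NA)), "missing")
  expect_true(is.na(res))
  expect_equal(sentinel_reason(res), "all ratings missing")
  expect_error(consensus(c(1, 1), threshold = 0.5))
  # 2 raters at 0.75 require unanimity (ceil(0.75 * 2) = 2)
  expect_equal(consensus(c(1, 1)), 1)
  expect_true(is.na(consensus(c(1, 0))))
})

test_that("consensus_rate counts biopsies with a consensus", {
  r <- do.call(rbind, lapply(1:27, function(i) {
    vals <- if (i <= 24) c(1, 1, 1, 0) else c(1, 1, 0, 0)
    make_panel(biopsy_id = paste0("b", i), crypt_loss = vals)
  }))
  expect_equal(consensus_rate(r, "crypt_loss"), 100 * 24 / 27)

  unanimous <- do.call(rbind, lapply(1:5, function(i) {
    make_panel(biopsy_id = paste0("b", i), crypt_loss = 2)
  }))
  expect_equal(consensus_rate(unanimous, "crypt_loss"), 100)

  split2 <- do.call(rbind, lapply(1:5, function(i) {
    make_panel(biopsy_id = paste0("b", i), crypt_loss = c(0, 0, 1, 1))
  }))
  expect_equal(consensus_rate(split2, "crypt_loss"), 0)
  # after dichotomization 0/0/1/1 still splits 2-2, but 1/1/2/2 is unanimous
  split12 <- do.call(rbind, lapply(1:5, function(i) {
    make_panel(biopsy_id = paste0("b", i), crypt_loss = c(1, 1, 2, 2))
  }))
  expect_equal(consensus_rate(split12, "crypt_loss"), 0)
  expect_equal(consensus_rate(split12, "crypt_loss", dichotomize = TRUE), 100)
})

test_that("fleiss_kappa matches the direct-formula oracle", {
  set.seed(55)
  for (i in 1:25) {
    counts <- t(vapply(1:6, function(j) {
      as.integer(stats::rmultinom(1, 4, prob = runif(3, 0.2, 1)))
    }, integer(3)))
    k_pkg <- fleiss_kappa(counts)
    expect_equal(as.numeric(k_pkg), fleiss_oracle(counts), tolerance = 1e-12)
  }
})

test_that("fleiss_kappa is 1 under perfect agreement and ~0 at chance", {
  unanimous <- rbind(c(4, 0), c(0, 4), c(4, 0), c(0, 4))
  expect_equal(as.numeric(fleiss_kappa(unanimous)), 1)
  # ratings drawn independently of the subject -> kappa near 0 on average
  set.seed(58)
  k_hats <- vapply(1:30, function(rep) {
    chance <- t(vapply(1:200, function(i) {
      as.integer(stats::rmultinom(1, 4, prob = c(0.6, 0.4)))
    }, integer(2)))
    k_hat <- as.numeric(fleiss_kappa(chance))
    expect_equal(k_hat, fleiss_oracle(chance), tolerance = 1e-12)
    k_hat
  }, numeric(1))
  expect_lt(abs(mean(k_hats)), 0.02)
})

test_that("fleiss_kappa invariances and sentinels", {
  set.seed(56)
  counts <- t(vapply(1:8, function(j) {
    as.integer(stats::rmultinom(1, 4, prob = c(0.5, 0.3, 0.2)))
  }, integer(3)))
  # category relabeling and subject order do not change kappa
  expect_equal(as.numeric(fleiss_kappa(counts[, c(3, 1, 2)])),
               as.numeric(fleiss_kappa(counts)))
  expect_equal(as.numeric(fleiss_kappa(counts[sample(8), ])),
               as.numeric(fleiss_kappa(counts)))
  # all ratings in one category -> sentinel, not zero
  degenerate <- matrix(c(4, 0, 4, 0, 4, 0), ncol = 2, byrow = TRUE)
  res <- fleiss_kappa(degenerate)
  expect_true(is.na(res))
  expect_match(sentinel_reason(res), "single category")
  # subjects with missing raters are dropped and counted
  uneven <- rbind(c(4, 0), c(3, 0), c(0, 4))
  expect_equal(attr(fleiss_kappa(uneven), "n_dropped"), 1L)
})

test_that("icc_a1 matches the aov-based oracle", {
  set.seed(66)
  for (i in 1:25) {
    x <- matrix(rnorm(24, sd = runif(1, 0.5, 3)), nrow = 6)
    expect_equal(icc_a1(x), icc_oracle(x), tolerance = 1e-10)
  }
})

test_that("icc_a1 agreement behaviour", {
  # identical columns with between-subject spread -> exactly 1
  x <- matrix(rep(1:6, 4), nrow = 6)
  expect_equal(icc_a1(x), 1)
  # fixed rater offsets are penalized by the agreement definition
  x_off <- sweep(x, 2, c(0, 1, 2, 3), "+")
  expect_lt(icc_a1(x_off), 1)
  expect_equal(icc_a1(x_off), icc_oracle(x_off), tolerance = 1e-10)
  # invariance under a common affine transform
  set.seed(67)
  y <- matrix(rnorm(24), nrow = 6)
  expect_equal(icc_a1(2.5 * y + 7), icc_a1(y), tolerance = 1e-10)
  # zero variance -> sentinel
  res <- icc_a1(matrix(3, 5, 4))
  expect_true(is.na(res))
  expect_match(sentinel_reason(res), "variance")
  # listwise deletion of incomplete subjects
  ymiss <- y
  ymiss[2, 3] <- NA
  expect_equal(icc_a1(ymiss), icc_a1(y[-2, ]), tolerance = 1e-12)
})

test_that("pairwise_spearman handles ties, reversals and sentinels", {
  set.seed(77)
  a <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  m <- cbind(A = a, B = a, C = -a, D = runif(10))
  rho <- pairwise_spearman(m)
  expect_equal(rho["A", "B"], 1)
  expect_equal(rho["A", "C"], -1)
  expect_equal(rho, t(rho))
  expect_equal(unname(diag(rho)), rep(1, 4))
  expect_equal(rho["A", "D"], spearman_oracle(a, m[, "D"]),
               tolerance = 1e-12)
  # constant rater -> sentinel cell
  m2 <- cbind(A = a, E = rep(2, 10))
  expect_true(is.na(pairwise_spearman(m2)["A", "E"]))
  # fewer than 3 complete pairs -> sentinel cell
  m3 <- cbind(A = c(1, 2, NA, NA, NA), B = c(2, 1, NA, NA, NA))
  expect_true(is.na(pairwise_spearman(m3)["A", "B"]))
})

test_that("agreement_report summarises every parameter plus CAB", {
  co <- simulate_cohort(sim_config(n_biopsies = 40, seed = 5))
  rep <- agreement_report(co$ratings)
  expect_equal(rep$parameter,
               c(morphology_parameters(), "cab_count"))
  morph <- rep[rep$parameter != "cab_count", ]
  expect_true(all(morph$consensus_rate_pct >= 0 &
                    morph$consensus_rate_pct <= 100))
  expect_true(all(morph$fleiss_kappa <= 1, na.rm = TRUE))
  expect_true(all(rep$icc_a1 <= 1, na.rm = TRUE))
  expect_true(is.na(rep$fleiss_kappa[rep$parameter == "cab_count"]))
  expect_false(is.na(rep$icc_a1[rep$parameter == "cab_count"]))
})
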