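test_that("folded AUC: separation, folding, ties and the pair-count oracle", {
  a <- folded_auc(c(1, 2, 3), c(0, 0, 1))
  expect_equal(a$auc_raw, 1)
  expect_equal(a$direction, "proportional")

  b <- folded_auc(c(5, 1, 2, 3, 4, 0, 1, 2), c(1, 1, 0, 0, 1, 1, 0, 0))
  expect_equal(b$auc_folded, if (b$auc_raw >= 0.5) b$auc_raw else 1 - b$auc_raw)

  tied <- folded_auc(rep(3, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(tied$auc_raw, 0.5)
  expect_equal(tied$direction, "proportional")  # tie convention

  set.seed(131)
  for (rep in 1:25) {
    n1 <- sample(1:8, 1); n0 <- sample(1:8, 1)
    v <- c(sample(1:5, n1, TRUE), sample(1:5, n0, TRUE))
    lab <- c(rep(1, n1), rep(0, n0))
    expect_equal(folded_auc(v, lab)$auc_raw, oracle_auc(v, lab),
                 tolerance = 1e-12)
  }
  expect_error(folded_auc(1:4, rep(1, 4), "calcification"), "calcification")
})

test_that("folded AUC excludes NaN feature values pairwise", {
  v <- c(NaN, 1, 2, 3, 4)
  lab <- c(1, 0, 0, 1, 1)
  a <- folded_auc(v, lab)
  expect_equal(a$n0 + a$n1, 4)
  expect_equal(a$auc_raw, oracle_auc(v[-1], lab[-1]))
})

test_that("Noether test matches the closed form and its symmetries", {
  expect_equal(noether_test(0.5, 10, 12), 1)
  z <- (0.63 - 0.5) / sqrt((20 + 30 + 1) / (12 * 20 * 30))
  expect_equal(noether_test(0.63, 20, 30), 2 * (1 - pnorm(abs(z))),
               tolerance = 1e-10)
  expect_equal(noether_test(0.3, 15, 9), noether_test(0.7, 15, 9),
               tolerance = 1e-12)
  expect_error(noether_test(0.6, 0, 5), "degenerate")
})

test_that("categorical association: monotone rho, null KW, tie-corrected H", {
  ca <- categorical_association(c(1.1, 2.5, 3.7), c(1L, 2L, 3L))
  expect_equal(ca$rho, 1)

  idn <- categorical_association(c(5, 7, 5, 7), c(1L, 1L, 2L, 2L))
  expect_equal(idn$kw_statistic, 0)

  # tie-corrected H against the direct formula on a 3-group toy set
  v <- c(1, 2, 2, 3, 5, 5, 6, 8, 9)
  g <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  n <- length(v); r <- rank(v)
  H <- (12 / (n * (n + 1))) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri))^2)) - 3 * (n + 1)
  ties <- table(v)
  H <- H / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(categorical_association(v, as.integer(g))$kw_statistic, H,
               tolerance = 1e-10)
  expect_error(categorical_association(1:4, rep(2L, 4)), "2 distinct")
})

test_that("BH adjustment reproduces the step-up trace and edge cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.03), 0.03)
  set.seed(141)
  p <- runif(40)
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  q <- bh_adjust(c(0.5, NaN, 0.01))
  expect_true(is.na(q[2]) && !is.na(q[1]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("strength bins follow the printed cut-points", {
  expect_equal(classify_strength("auc", 0.76), "moderate")
  expect_equal(classify_strength("rho", -0.57), "moderate")
  expect_equal(classify_strength("auc", 0.50), "random")
  expect_equal(classify_strength("auc", 0.70), "weak")
  expect_equal(classify_strength("auc", 0.95), "excellent")
  expect_equal(classify_strength("rho", 0.5), "weak")
  expect_equal(classify_strength("rho", -0.95), "excellent")
  expect_error(classify_strength("auc", 0.4), "\\[0.5, 1\\]")
})

test_that("report shape, internal consistency and determinism", {
  set.seed(151)
  co <- sample_semantic_scores(40, seed = 6)
  tab <- cbind(subject_id = co$subject_id,
               as.data.frame(matrix(rnorm(40 * 5), 40,
                                    dimnames = list(NULL, paste0("f", 1:5)))))
  rep <- build_report(tab, co)
  expect_equal(sum(rep$statistic_type == "auc"), 5 * 3)
  expect_equal(sum(rep$statistic_type == "rho"), 5 * 6)

  # cell-level re-derivation of strength and significance
  for (i in seq_len(nrow(rep))) {
    r <- rep[i, ]
    expect_equal(r$strength,
                 classify_strength(ifelse(r$statistic_type == "auc",
                                          "auc", "rho"), r$estimate))
    expect_equal(r$significant, r$q <= attr(rep, "alpha"))
  }
  expect_identical(as.data.frame(build_report(tab, co)), as.data.frame(rep))

  co2 <- co
  co2$calcification <- 0L
  expect_warning(r2 <- build_report(tab, co2), "calcification")
  expect_false("calcification" %in% r2$semantic)
})

test_that("few usable observations give a not-evaluated cell", {
  co <- sample_semantic_scores(15, seed = 8)
  f <- rnorm(15)
  f[1:8] <- NaN  # only 7 usable < min_n = 10
  tab <- data.frame(subject_id = co$subject_id, sparse = f, dense = rnorm(15))
  rep <- build_report(tab, co)
  sp <- rep[rep$radiomic == "sparse", ]
  expect_true(all(is.na(sp$p)))
  expect_true(all(!sp$significant))
  expect_true(all(!is.na(rep[rep$radiomic == "dense", "p"])))
})

test_that("permutation null yields no systematic discoveries", {
  set.seed(161)
  n <- 60
  co <- sample_semantic_scores(n, seed = 16)
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    tab <- cbind(subject_id = co$subject_id,
                 as.data.frame(matrix(rnorm(n * 10), n,
                                      dimnames = list(NULL, paste0("f", 1:10)))))
    co_perm <- co
    co_perm[, -1] <- co[sample(n), -1]
    rep <- build_report(tab, co_perm)
    hits <- hits + any(rep$significant)
  }
  # per replicate the chance of any FDR hit across 9 columns is ~<= 0.37;
  # 20 replicates all hitting would be astronomically unlikely
  expect_lt(hits / n_rep, 0.75)
})
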