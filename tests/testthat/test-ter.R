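test_that("unreplicated TER fit equals the 2x2 log odds ratio", {
  d <- two_group_design(1, 1)
  rpf <- make_cm(matrix(c(100, 200), 1, 2), ids = "t1",
                 samples = c("a1", "b1"), read_type = "RPF")
  rna <- make_cm(matrix(c(100, 100), 1, 2), ids = "t1",
                 samples = c("a1", "b1"), read_type = "RNA")
  fit <- ter_test(rpf, rna, d, min_total = 0)
  expect_equal(unname(fit$coef[1, "group_B"]), log(2), tolerance = 1e-8)
  expect_equal(unname(fit$coef[1, "group_B"]),
               oracle_log_or(100, 100, 200, 100), tolerance = 1e-8)

  o <- ter_2x2(100, 100, 200, 100)
  expect_equal(o$log_or, log(2), tolerance = 1e-12)
  # Wald and chi-square p agree within a factor of two (both asymptotic)
  p_wald <- fit$p[1, "group_B"]
  expect_lt(max(p_wald / o$chisq_p, o$chisq_p / p_wald), 2)

  sym <- ter_2x2(50, 50, 50, 50)
  expect_equal(sym$log_or, 0)
  expect_equal(sym$fisher_p, 1)
  expect_equal(ter_2x2(0, 10, 10, 10)$log_or, NA_real_)
  expect_equal(ter_2x2(0, 10, 10, 10, pseudocount = 0.5)$log_or, log(21),
               tolerance = 1e-12)
})

test_that("identity, cancellation and monotonicity of the fitted contrast", {
  d <- two_group_design(2, 2)
  eq <- matrix(c(50, 60, 70, 80), 1, 4)
  fit <- ter_test(make_cm(eq, ids = "t1", samples = d$sample_ids, read_type = "RPF"),
                  make_cm(eq, ids = "t1", samples = d$sample_ids, read_type = "RNA"),
                  d)
  tab <- ter_table(fit, "group=A,B")
  expect_equal(tab$logTER, 0, tolerance = 1e-8)
  expect_equal(tab$TER, 1, tolerance = 1e-8)

  # increasing one group's RPF strictly increases its logTER contrast
  prev <- -Inf
  for (mult in c(1, 1.5, 2.5)) {
    rpf <- make_cm(matrix(c(50, 60, 70 * mult, 80 * mult), 1, 4), ids = "t1",
                   samples = d$sample_ids, read_type = "RPF")
    rna <- make_cm(matrix(c(50, 60, 70, 80), 1, 4), ids = "t1",
                   samples = d$sample_ids, read_type = "RNA")
    cur <- ter_table(ter_test(rpf, rna, d), "group=A,B")$logTER
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("predict_ter substitutes coefficients into the TER equation", {
  fit <- structure(list(
    coef = matrix(c(0.1, 0.5), 1, 2,
                  dimnames = list("t1", c("(Intercept)", "x"))),
    se = matrix(c(0.05, 0.1), 1, 2),
    vcov = array(diag(c(0.05, 0.1)^2), c(2, 2, 1),
                 dimnames = list(c("(Intercept)", "x"), c("(Intercept)", "x"), "t1")),
    dispersion = FALSE, df_resid = 0), class = "ter_fit")
  expect_equal(predict_ter(fit, c(x = 0), c(x = 1))$TER, exp(0.5),
               tolerance = 1e-12)
  expect_equal(predict_ter(fit, c(x = 2), c(x = 2))$TER, 1)
  expect_error(predict_ter(fit, c(bogus = 0), c(bogus = 1)), "unknown")

  fit2 <- fit
  fit2$coef <- matrix(c(0, 0.2, -0.2), 1, 3,
                      dimnames = list("t1", c("(Intercept)", "u", "v")))
  fit2$vcov <- array(diag(3) * 0.01, c(3, 3, 1),
                     dimnames = list(colnames(fit2$coef), colnames(fit2$coef), "t1"))
  expect_equal(predict_ter(fit2, c(u = 0, v = 0), c(u = 1, v = 1))$TER, 1,
               tolerance = 1e-12)
})

test_that("separation and untestable transcripts are flagged", {
  d <- two_group_design(2, 2)
  rpf <- make_cm(matrix(c(40, 50, 0, 0), 1, 4), ids = "t1",
                 samples = d$sample_ids, read_type = "RPF")
  rna <- make_cm(matrix(c(40, 50, 60, 70), 1, 4), ids = "t1",
                 samples = d$sample_ids, read_type = "RNA")
  fit <- ter_test(rpf, rna, d, pseudocount = 0)
  expect_equal(unname(fit$status["t1"]), "separation")
  expect_true(is.finite(fit$p[1, "group_B"]))   # LRT fallback p

  low <- make_cm(matrix(c(2, 3, 2, 3), 1, 4), ids = "t1",
                 samples = d$sample_ids, read_type = "RPF")
  rna_low <- make_cm(matrix(c(4, 3, 4, 3), 1, 4), ids = "t1",
                     samples = d$sample_ids, read_type = "RNA")
  fit_low <- ter_test(low, rna_low, d, min_total = 10)
  expect_equal(unname(fit_low$status["t1"]), "untestable")
  expect_true(is.na(ter_table(fit_low, "group=A,B")$p))
})

test_that("BH adjustment follows the step-up rule and propagates NA", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(adjust_pvalues(0.2), 0.2)
  got <- adjust_pvalues(c(0.01, NA, 0.04))
  expect_true(is.na(got[2]))
  expect_equal(got[c(1, 3)], p.adjust(c(0.01, 0.04), "BH"))
})

test_that("fitted beta matches the 2x2 oracle on random positive tables", {
  set.seed(41)
  d <- two_group_design(1, 1)
  for (i in 1:25) {
    cells <- rpois(4, 80) + 1
    rpf <- make_cm(matrix(cells[c(1, 3)], 1, 2), ids = "t1",
                   samples = d$sample_ids, read_type = "RPF")
    rna <- make_cm(matrix(cells[c(2, 4)], 1, 2), ids = "t1",
                   samples = d$sample_ids, read_type = "RNA")
    fit <- ter_test(rpf, rna, d, min_total = 0)
    expect_equal(unname(fit$coef[1, "group_B"]),
                 oracle_log_or(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-6)
  }
})

test_that("quasi-binomial treatment calibrates the test under NB replicates", {
  sim <- simulate_ribo(list(n_transcripts = 400L), seed = 43)
  fit <- ter_test(normalize_counts(sim$rpf), normalize_counts(sim$rna),
                  sim$design, dispersion = TRUE)
  tab <- ter_table(fit, "group=A,B")
  rej <- mean(tab$p < 0.05, na.rm = TRUE)
  expect_gt(rej, 0.015)
  expect_lt(rej, 0.10)
})
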