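make_pas <- function(counts, transcript = "tx1",
                     sites = sprintf("pA%d", seq_len(nrow(counts))),
                     samples = sprintf("s%d", seq_len(ncol(counts))),
                     ranks = seq_len(nrow(counts))) {
  df <- data.frame(transcript_id = transcript, site_id = sites,
                   rank = ranks, testable = nrow(counts) >= 2,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(counts))
  colnames(df)[-(1:4)] <- samples
  attr(df, "sample_ids") <- samples
  class(df) <- c("pas_counts", "data.frame")
  df
}

cond_design <- function(n1 = 1, n2 = 1) {
  design_matrix(c(paste0("s", seq_len(n1)), paste0("s", n1 + seq_len(n2))),
                data.frame(condition = rep(c("A", "B"), c(n1, n2)),
                           stringsAsFactors = FALSE))
}

test_that("overall deviance equals the hand-computed G statistic", {
  pas <- make_pas(rbind(c(80, 20), c(20, 80)))
  tab <- apa_test(pas, cond_design(), mode = "overall", normalize = FALSE)
  G <- oracle_g_stat(matrix(c(80, 20, 20, 80), 2, byrow = TRUE))
  expect_equal(tab$deviance, G, tolerance = 1e-6)
  expect_equal(tab$df, 1L)
  expect_equal(tab$p, pchisq(G, 1, lower.tail = FALSE), tolerance = 1e-6)

  # 3 sites, 1 binary covariate -> df = 2
  pas3 <- make_pas(rbind(c(30, 35), c(30, 30), c(40, 35)))
  expect_equal(apa_test(pas3, cond_design(), mode = "overall")$df, 2L)

  # identical usage proportions -> deviance ~ 0, p ~ 1
  pasnull <- make_pas(rbind(c(60, 30), c(40, 20)))
  tnull <- apa_test(pasnull, cond_design(), mode = "overall", normalize = FALSE)
  expect_lt(tnull$deviance, 1e-8)
  expect_gt(tnull$p, 0.999)
})

test_that("S=2 multinomial equals the binomial logistic fit", {
  set.seed(51)
  Y <- matrix(rpois(8, 60) + 1, 4, 2)
  X <- cbind("(Intercept)" = rep(1, 4), g = c(0, 0, 1, 1))
  mine <- fit_multinom_logit(Y, X)
  ref <- stats::glm(cbind(Y[, 2], Y[, 1]) ~ X[, "g"], family = binomial)
  expect_equal(as.vector(mine$coef), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(mine$vcov, unname(vcov(ref)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("multinomial fitter agrees with an independent implementation", {
  skip_if_not_installed("nnet")
  set.seed(52)
  Y <- matrix(rpois(12, 50) + 1, 4, 3)
  X <- cbind("(Intercept)" = rep(1, 4), g = c(0, 0, 1, 1))
  mine <- fit_multinom_logit(Y, X)
  nn <- nnet::multinom(Y ~ X[, "g"], trace = FALSE, reltol = 1e-14)
  expect_equal(as.vector(mine$coef), as.vector(t(coef(nn))), tolerance = 1e-6)
})

test_that("pairwise mode recovers the 2x2 odds-ratio oracle and its sign flips", {
  pas <- make_pas(rbind(c(80, 20), c(20, 80)))   # pA1 proximal, pA2 distal
  d <- cond_design()
  pw <- apa_test(pas, d, mode = "pairwise", normalize = FALSE)
  # model log(pA2/pA1): beta = ln((80/20)/(20/80)) = ln 16
  expect_equal(pw$estimate, log(16), tolerance = 1e-6)
  lap <- compute_logapar(pw, pas)
  expect_equal(lap$logAPAR, log(1 / 16), tolerance = 1e-6)

  # swapping condition labels flips the sign exactly
  d_sw <- design_matrix(c("s1", "s2"),
                        data.frame(condition = c("B", "A"),
                                   stringsAsFactors = FALSE))
  pw_sw <- apa_test(pas, d_sw, mode = "pairwise", normalize = FALSE)
  expect_equal(pw_sw$estimate, -pw$estimate, tolerance = 1e-8)
  expect_equal(pw_sw$p, pw$p, tolerance = 1e-8)

  # no usage change -> logAPAR 0
  paseq <- make_pas(rbind(c(50, 25), c(50, 25)))
  pweq <- apa_test(paseq, d, mode = "pairwise", normalize = FALSE)
  expect_equal(pweq$estimate, 0, tolerance = 1e-8)

  # S=3 -> three pair tests
  pas3 <- make_pas(rbind(c(30, 35), c(30, 30), c(40, 35)))
  pw3 <- apa_test(pas3, d, mode = "pairwise", normalize = FALSE)
  expect_equal(nrow(pw3), 3L)
})

test_that("reference mode honours the reference rule and matches pairwise at S=2", {
  counts <- rbind(c(80, 20), c(20, 80))
  d <- cond_design()
  # sites named so alphabetical and proximal rules disagree
  pas <- make_pas(counts, sites = c("pA2", "pA1"), ranks = c(1, 2))
  ref_alpha <- apa_test(pas, d, mode = "reference", normalize = FALSE)
  expect_equal(ref_alpha$ref_site, "pA1")
  ref_prox <- apa_test(pas, d, mode = "reference", reference = "proximal",
                       normalize = FALSE)
  expect_equal(ref_prox$ref_site, "pA2")
  expect_equal(ref_alpha$estimate, -ref_prox$estimate, tolerance = 1e-7)

  pw <- apa_test(pas, d, mode = "pairwise", normalize = FALSE)
  expect_equal(ref_alpha$estimate, pw$estimate, tolerance = 1e-7)
  expect_equal(ref_alpha$p, pw$p, tolerance = 1e-5)

  expect_error(apa_test(pas, d, mode = "reference",
                        reference = c(tx1 = "missing"), normalize = FALSE),
               "reference site")
})

test_that("untestable transcripts are flagged, not dropped", {
  pas1 <- make_pas(matrix(c(30, 40), 1, 2), sites = "pA1", ranks = 1)
  pas1$testable <- FALSE
  tab <- apa_test(pas1, cond_design(), mode = "overall")
  expect_equal(tab$status, "untestable")
  expect_true(is.na(tab$p))

  # all counts on one site -> untestable
  pasone <- make_pas(rbind(c(50, 60), c(0, 0)))
  tone <- apa_test(pasone, cond_design(), mode = "overall", normalize = FALSE)
  expect_equal(tone$status, "untestable")
})

test_that("null simulation calibrates and planted shifts are recovered", {
  simn <- simulate_apa(list(n_transcripts = 250L), seed = 53)
  tab <- apa_test(simn$pas, simn$design, mode = "overall")
  rej <- mean(tab$p < 0.05, na.rm = TRUE)
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.09)

  sims <- simulate_apa(list(n_transcripts = 120L, shift_fraction = 0.5),
                       seed = 54)
  pw <- apa_test(sims$pas, sims$design, mode = "pairwise")
  lap <- compute_logapar(pw, sims$pas, pairs = "extreme")
  sh <- sims$truth$shifted[match(lap$transcript_id, sims$truth$transcript_id)]
  expect_lt(abs(mean(lap$logAPAR[sh]) - 1), 0.15)
  expect_lt(abs(mean(lap$logAPAR[!sh])), 0.1)
})
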