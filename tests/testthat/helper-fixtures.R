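# Shared fixture builders and independent oracles used across the suite.

write_tsv_fixture <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

make_cm <- function(m, ids = sprintf("t%d", seq_len(nrow(m))),
                    samples = sprintf("s%d", seq_len(ncol(m))),
                    read_type = "RNA") {
  dimnames(m) <- list(ids, samples)
  count_matrix(m, read_type)
}

two_group_design <- function(n1, n2) {
  design_matrix(c(paste0("a", seq_len(n1)), paste0("b", seq_len(n2))),
                data.frame(group = rep(c("A", "B"), c(n1, n2)),
                           stringsAsFactors = FALSE))
}

# Independent oracle for the local smoother: per-codon weighted lm() fit.
oracle_smooth <- function(y, radius = 5L) {
  L <- length(y)
  vapply(seq_len(L), function(i) {
    j <- if (L < 2L * radius + 1L) seq_len(L)
         else max(1L, i - radius):min(L, i + radius)
    d <- j - i
    h <- max(radius, max(abs(d)))
    w <- (1 - (abs(d) / (h + 1))^3)^3
    fit <- stats::lm(y[j] ~ d, weights = w)
    max(0, unname(stats::predict(fit, newdata = data.frame(d = 0))))
  }, numeric(1L))
}

# 2x2 log odds ratio by direct arithmetic.
oracle_log_or <- function(rpf1, rna1, rpf2, rna2) {
  log((rpf2 / rna2) / (rpf1 / rna1))
}

# G statistic (2 sum o log(o/e)) for a 2x2 table under independence.
oracle_g_stat <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  2 * sum(ifelse(tab > 0, tab * log(tab / e), 0))
}

# Exact hypergeometric upper tail by combinatorial enumeration (small N).
oracle_hyper_upper <- function(k, K, N, n) {
  sum(vapply(k:min(K, n), function(x)
    choose(K, x) * choose(N - K, n - x), numeric(1L))) / choose(N, n)
}

# Exact two-sided rank-sum p by enumerating all group assignments (small n).
oracle_ranksum_p <- function(values, member) {
  n1 <- sum(member)
  ranks <- rank(values)
  obs <- sum(ranks[member]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(values), n1)
  ws <- apply(combs, 2L, function(ix) sum(ranks[ix]) - n1 * (n1 + 1) / 2)
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(obs - mu) - 1e-9)
}
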