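#' Equally populated binning of a per-transcript statistic
#'
#' Ranks transcripts by value (ties broken by stable transcript-ID order)
#' and assigns contiguous blocks so bin sizes differ by at most one (the
#' leading bins take the remainder).
#'
#' @param values Named numeric vector (transcript -> statistic, e.g. logTER
#'   or logAPAR); non-finite values are dropped.
#' @param nbins Number of bins (>= 2; default 10).
#' @return List with \code{bins} (named integer vector, 1 = lowest values),
#'   \code{breaks} (data.frame bin, lo, hi, n).
#' @export
bin_values <- function(values, nbins = 10L) {
  if (nbins < 2L) stop("nbins must be at least 2")
  values <- values[is.finite(values)]
  N <- length(values)
  if (N < nbins) stop("need at least nbins finite values")
  ord <- order(values, names(values))
  sizes <- rep(N %/% nbins, nbins)
  rem <- N %% nbins
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  bin <- integer(N)
  bin[ord] <- rep(seq_len(nbins), sizes)
  names(bin) <- names(values)
  breaks <- data.frame(
    bin = seq_len(nbins),
    lo = tapply(values, bin, min)[as.character(seq_len(nbins))],
    hi = tapply(values, bin, max)[as.character(seq_len(nbins))],
    n = sizes, row.names = NULL)
  list(bins = bin, breaks = breaks, values = values)
}

#' Per-bin target-set over/under-representation
#'
#' For each bin, tests whether members of a target set are over- or
#' under-represented, either by two one-sided hypergeometric tail tests (the
#' smaller tail is reported with its direction) or by logistic regression of
#' membership on a bin indicator (Wald p). BH correction is applied across
#' bins.
#'
#' @param binning Result of \code{\link{bin_values}}.
#' @param targets Character vector of target transcript IDs (must intersect
#'   the binned universe).
#' @param test \code{"hypergeometric"} (default) or \code{"logistic"}.
#' @return data.frame: bin, lo, hi, n, n_targets, expected, direction
#'   (enriched/depleted/none), p, padj.
#' @export
bin_enrichment <- function(binning, targets,
                           test = c("hypergeometric", "logistic")) {
  test <- match.arg(test)
  bins <- binning$bins
  member <- names(bins) %in% targets
  Ktot <- sum(member)
  if (Ktot == 0L) stop("target set does not intersect the binned universe")
  N <- length(bins)
  nb <- max(bins)
  res <- binning$breaks
  res$n_targets <- as.integer(tapply(member, bins, sum)[as.character(seq_len(nb))])
  res$n_targets[is.na(res$n_targets)] <- 0L
  res$expected <- res$n * Ktot / N
  p <- dir <- rep(NA, nb)
  for (b in seq_len(nb)) {
    k <- res$n_targets[b]; n <- res$n[b]
    if (test == "hypergeometric") {
      p_over <- stats::phyper(k - 1L, Ktot, N - Ktot, n, lower.tail = FALSE)
      p_under <- stats::phyper(k, Ktot, N - Ktot, n)
      p[b] <- min(1, min(p_over, p_under))
    } else {
      ind <- as.numeric(bins == b)
      fit <- suppressWarnings(stats::glm(member ~ ind, family = stats::binomial()))
      sm <- summary(fit)$coefficients
      p[b] <- if ("ind" %in% rownames(sm)) sm["ind", 4L] else NA_real_
    }
    dir[b] <- if (k > res$expected[b]) "enriched"
              else if (k < res$expected[b]) "depleted" else "none"
  }
  res$direction <- dir
  res$p <- as.numeric(p)
  res$padj <- adjust_pvalues(res$p)
  res
}

#' Mutual information between bin assignment and target membership
#'
#' Plug-in (empirical) mutual information, in bits, between the bin variable
#' and the binary membership indicator; zero-probability cells contribute 0.
#'
#' @inheritParams bin_enrichment
#' @return MI in bits (non-negative scalar).
#' @export
mutual_information <- function(binning, targets) {
  bins <- binning$bins
  member <- names(bins) %in% targets
  N <- length(bins)
  mi <- 0
  for (b in unique(bins)) for (m in c(TRUE, FALSE)) {
    pj <- sum(bins == b & member == m) / N
    if (pj > 0) {
      pb <- sum(bins == b) / N
      pm <- sum(member == m) / N
      mi <- mi + pj * log2(pj / (pb * pm))
    }
  }
  max(0, mi)
}

#' Permutation z-score for binned mutual information
#'
#' Membership labels are permuted over the universe (bin structure fixed)
#' \code{n_perm} times; the z-score standardizes the observed MI against the
#' permutation distribution.
#'
#' @inheritParams bin_enrichment
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Mandatory RNG seed (the global RNG state is restored on
#'   exit).
#' @return List: mi (bits), z, perm_mean, perm_sd, n_perm, seed. z is NA
#'   with a flag when the permutation sd is 0.
#' @export
mi_zscore <- function(binning, targets, n_perm = 1000L, seed) {
  if (missing(seed)) stop("mi_zscore requires an explicit seed")
  if (n_perm < 100L) stop("use at least 100 permutations")
  mi_obs <- mutual_information(binning, targets)
  bins <- binning$bins
  member <- names(bins) %in% targets
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    pm <- sample(member)
    mi_from_indicator(bins, pm)
  }, numeric(1L))
  s <- stats::sd(perm)
  list(mi = mi_obs,
       z = if (s == 0) NA_real_ else (mi_obs - mean(perm)) / s,
       perm_mean = mean(perm), perm_sd = s, n_perm = n_perm, seed = seed,
       degenerate = s == 0)
}

mi_from_indicator <- function(bins, member) {
  N <- length(bins)
  tab <- table(bins, member)
  pj <- tab / N
  pb <- rowSums(pj); pm <- colSums(pj)
  ex <- outer(pb, pm)
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / ex[nz]))
}

#' Rank-sum association between a statistic and a binary annotation
#'
#' Two-sided Wilcoxon rank-sum test comparing annotated against background
#' values (exact for small untied samples, otherwise the normal
#' approximation with tie correction, as implemented by
#' \code{\link[stats]{wilcox.test}}).
#'
#' @param values Numeric vector of the statistic.
#' @param annotation Logical (or 0/1) vector: TRUE = annotated group.
#' @return List: statistic (W for annotated vs background), p.
#' @export
rank_association <- function(values, annotation) {
  annotation <- as.logical(annotation)
  if (!any(annotation) || all(annotation))
    stop("both groups must be non-empty")
  wt <- stats::wilcox.test(values[annotation], values[!annotation])
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' One-call enrichment analysis
#'
#' Bins a statistic, runs the per-bin test, and computes MI with its
#' permutation z-score.
#'
#' @inheritParams bin_enrichment
#' @inheritParams mi_zscore
#' @param values Named numeric vector of the per-transcript statistic.
#' @param nbins Number of equally populated bins.
#' @return List: table (per-bin results), mi, z, n_perm, seed.
#' @export
enrichment_analysis <- function(values, targets, nbins = 10L,
                                test = c("hypergeometric", "logistic"),
                                n_perm = 1000L, seed) {
  binning <- bin_values(values, nbins)
  tab <- bin_enrichment(binning, targets, test)
  mz <- mi_zscore(binning, targets, n_perm, seed)
  tab$mi <- mz$mi
  tab$mi_z <- mz$z
  list(table = tab, mi = mz$mi, z = mz$z, n_perm = n_perm, seed = seed,
       binning = binning)
}
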