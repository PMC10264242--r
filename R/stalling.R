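#' Locally weighted smoothing of a codon-level profile
#'
#' Deterministic local linear (degree-1) regression with tricube weights over
#' a fixed codon window: the prediction at codon i is the weighted linear fit
#' over codons within +/- \code{radius}, with weights
#' \eqn{w(d) = (1 - (|d|/(r+1))^3)^3}. For transcripts shorter than
#' \code{2*radius + 1} codons every window uses all codons (the weight scale
#' widens to the largest distance present). Predictions are clipped below at
#' zero. Parameterizing by a codon radius rather than a span fraction keeps
#' the neighbourhood size constant across transcripts of different lengths.
#'
#' @param counts Numeric vector of per-codon counts (length >= 2; an
#'   all-zero vector is returned unchanged).
#' @param radius Window half-width in codons (default 5).
#' @return Numeric vector of smoothed counts, same length.
#' @export
smooth_profile <- function(counts, radius = 5L) {
  stopifnot(radius >= 1L)
  L <- length(counts)
  if (L < 2L || all(counts == 0)) return(counts)
  y <- as.numeric(counts)
  out <- numeric(L)
  if (L >= 2L * radius + 1L) {
    # interior windows are symmetric: the weighted-x moment vanishes and the
    # local-linear prediction reduces to a tricube-weighted moving average
    d <- (-radius):radius
    w <- (1 - (abs(d) / (radius + 1))^3)^3
    sm <- stats::filter(y, w / sum(w), sides = 2L)
    interior <- (radius + 1L):(L - radius)
    out[interior] <- sm[interior]
    edge <- c(seq_len(radius), seq(L - radius + 1L, L))
  } else {
    edge <- seq_len(L)
  }
  for (i in edge) {
    if (L >= 2L * radius + 1L) {
      j <- max(1L, i - radius):min(L, i + radius)
    } else {
      j <- seq_len(L)
    }
    d <- j - i
    h <- max(radius, max(abs(d)))
    w <- (1 - (abs(d) / (h + 1))^3)^3
    sw <- sum(w); swx <- sum(w * d); swx2 <- sum(w * d * d)
    swy <- sum(w * y[j]); swxy <- sum(w * d * y[j])
    den <- sw * swx2 - swx^2
    out[i] <- if (den > .Machine$double.eps * sw * swx2 + 1e-300 && length(j) > 1L)
      (swx2 * swy - swx * swxy) / den
    else swy / sw
  }
  pmax(out, 0)
}

#' Detect and correct ribosome stalling bias in codon profiles
#'
#' Stalling (suboptimal codons, structure, RBP obstruction) produces local
#' peaks of RPF reads that inflate a transcript's footprint total without
#' reflecting its overall translation rate. This routine smooths each
#' per-sample codon profile (\code{\link{smooth_profile}}), measures each
#' codon's excess over the transcript's background (the median of non-zero
#' smoothed counts), and summarizes the excess across samples as a per-codon
#' bias coefficient
#' \deqn{b_{ij} = \left(\prod_k y^l_{ijk} / M^l_{jk}\right)^{1/K},}
#' the geometric mean of smoothed-count/background ratios over the K pooled
#' samples. Smoothed counts are divided by the coefficient and re-summed to
#' give debiased per-transcript RPF counts suitable for the TER test.
#'
#' Codons where any pooled sample has a zero smoothed count (or a zero
#' background) keep \code{b = 1}: no correction is manufactured where there
#' are no reads. Transcripts whose background is zero in every sample are
#' flagged and passed through uncorrected.
#'
#' @param profiles A \code{codon_profiles} object (see
#'   \code{\link{read_codon_profiles}}).
#' @param radius Smoothing window half-width in codons (default 5).
#' @param groups Optional per-sample group labels (character vector named by
#'   sample, or in sample order). When given, bias coefficients are computed
#'   within each group (for studying group-specific stalling); by default all
#'   samples are pooled, the appropriate choice when the goal is an unbiased
#'   TER test.
#' @param clip_at_one If TRUE, coefficients below 1 are raised to 1 so that
#'   only excess peaks are corrected and valleys are left alone.
#' @return List with elements \code{counts} (debiased transcript x sample
#'   \code{count_matrix}, read_type RPF), \code{bias} (per transcript, a
#'   codon x group matrix of coefficients), \code{smoothed} (per-transcript
#'   smoothed profiles), \code{background} (per-transcript per-sample
#'   medians) and \code{flags} (per-transcript status:
#'   \code{"ok"} or \code{"no_background"}).
#' @export
correct_stalling <- function(profiles, radius = 5L, groups = NULL,
                             clip_at_one = FALSE) {
  stopifnot(inherits(profiles, "codon_profiles"))
  samples <- attr(profiles, "sample_ids")
  K <- length(samples)
  if (is.null(groups)) {
    grp <- rep("all", K)
  } else {
    grp <- if (!is.null(names(groups))) as.character(groups[samples])
           else as.character(groups)
    if (length(grp) != K || anyNA(grp))
      stop("groups must label every sample")
  }
  glev <- unique(grp)

  tx <- names(profiles)
  counts <- matrix(0, nrow = length(tx), ncol = K,
                   dimnames = list(tx, samples))
  smoothed <- vector("list", length(tx)); names(smoothed) <- tx
  bias <- vector("list", length(tx)); names(bias) <- tx
  background <- matrix(NA_real_, nrow = length(tx), ncol = K,
                       dimnames = list(tx, samples))
  flags <- setNames(rep("ok", length(tx)), tx)

  for (t in tx) {
    m <- profiles[[t]]
    sm <- apply(m, 2L, smooth_profile, radius = radius)
    if (is.null(dim(sm))) sm <- matrix(sm, ncol = K, dimnames = list(NULL, samples))
    smoothed[[t]] <- sm
    M <- apply(sm, 2L, function(v) {
      nz <- v[v > 0]
      if (length(nz) == 0L) 0 else stats::median(nz)
    })
    background[t, ] <- M
    b <- matrix(1, nrow = nrow(sm), ncol = length(glev),
                dimnames = list(NULL, glev))
    if (all(M == 0)) {
      flags[t] <- "no_background"
    } else {
      for (g in glev) {
        k <- which(grp == g & M > 0)
        if (length(k) == 0L) next
        ratio <- sweep(sm[, k, drop = FALSE], 2L, M[k], "/")
        ok <- rowSums(ratio == 0) == 0L
        b[ok, g] <- exp(rowMeans(log(ratio[ok, , drop = FALSE])))
      }
    }
    if (clip_at_one) b <- pmax(b, 1)
    bias[[t]] <- b
    deb <- sm / b[, match(grp, glev), drop = FALSE]
    counts[t, ] <- colSums(deb)
  }
  list(counts = count_matrix(counts, "RPF"),
       bias = bias, smoothed = smoothed,
       background = background, flags = flags,
       radius = radius, groups = grp)
}

#' Export stalling-bias coefficients as a long table
#'
#' @param fit Result of \code{\link{correct_stalling}}.
#' @return data.frame with columns transcript_id, codon_index (0-based),
#'   group, bias.
#' @export
stalling_bias_table <- function(fit) {
  rows <- lapply(names(fit$bias), function(t) {
    b <- fit$bias[[t]]
    data.frame(transcript_id = t,
               codon_index = rep(seq_len(nrow(b)) - 1L, ncol(b)),
               group = rep(colnames(b), each = nrow(b)),
               bias = as.vector(b), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
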