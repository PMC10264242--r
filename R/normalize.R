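#' Median-of-ratios size factors
#'
#' Library-size factors in the style standard for count matrices: a reference
#' pseudo-sample is formed as the per-transcript geometric mean across
#' samples (over transcripts with all-positive counts), and each sample's
#' factor is the median across those transcripts of count / reference.
#'
#' @param matrix A \code{count_matrix} (or plain numeric matrix).
#' @param on_fail What to do when no transcript has positive counts in every
#'   sample: \code{"error"} (default) or \code{"ones"} (return unit factors
#'   with a warning).
#' @return Named positive numeric vector of per-sample factors, with
#'   attribute \code{n_reference} (number of transcripts used).
#' @export
size_factors <- function(matrix, on_fail = c("error", "ones")) {
  on_fail <- match.arg(on_fail)
  m <- unclass(matrix)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    if (on_fail == "error")
      stop("no transcript has positive counts in all samples; ",
           "filter the matrix or use on_fail = \"ones\"")
    warning("no all-positive transcript; returning unit size factors")
    f <- rep(1, ncol(m))
    names(f) <- colnames(m)
    attr(f, "n_reference") <- 0L
    return(f)
  }
  mp <- m[pos, , drop = FALSE]
  ref <- exp(rowMeans(log(mp)))
  f <- apply(mp / ref, 2L, stats::median)
  names(f) <- colnames(m)
  attr(f, "n_reference") <- sum(pos)
  f
}

#' Divide a count matrix by its size factors
#'
#' @param matrix A \code{count_matrix}.
#' @param factors Named per-sample factors as returned by
#'   \code{\link{size_factors}}; must cover every sample.
#' @return A \code{count_matrix} of normalized (possibly non-integer) counts,
#'   with attributes \code{size_factors}.
#' @export
apply_size_factors <- function(matrix, factors) {
  miss <- setdiff(colnames(matrix), names(factors))
  if (length(miss) > 0L)
    stop("no size factor for sample(s): ", paste(miss, collapse = ", "))
  f <- factors[colnames(matrix)]
  if (any(f <= 0)) stop("size factors must be positive")
  out <- sweep(unclass(matrix), 2L, f, "/")
  out <- count_matrix(out, attr(matrix, "read_type"))
  attr(out, "size_factors") <- f
  out
}

#' Normalize a count matrix by median-of-ratios
#'
#' Convenience wrapper combining \code{\link{size_factors}} and
#' \code{\link{apply_size_factors}}.
#'
#' @inheritParams size_factors
#' @return Normalized \code{count_matrix}.
#' @export
normalize_counts <- function(matrix, on_fail = c("error", "ones")) {
  apply_size_factors(matrix, size_factors(matrix, on_fail))
}
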