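#' Differential poly(A)-site usage test
#'
#' Per-transcript multinomial logistic regression of poly(A)-site read
#' counts on sample covariates,
#' \deqn{\log(Alt.site / Ref.site) = \alpha + \sum_i \beta_i X_i,}
#' in three modes:
#' \describe{
#'   \item{overall}{one deviance (likelihood-ratio) test per transcript
#'     between the covariate model and the intercept-only model, with
#'     df = (S-1) x (number of non-intercept covariates). One test per
#'     transcript, so multiple-testing correction is not complicated by
#'     transcripts having unequal numbers of sites.}
#'   \item{reference}{one site per transcript is the reference (alphabetical
#'     by default, or the most proximal, or user-chosen) and every other site
#'     is tested against it; per non-reference site and covariate a Wald
#'     z-test is reported.}
#'   \item{pairwise}{every unordered pair of sites is compared by a binomial
#'     logistic fit restricted to that pair — the highest-resolution view.}
#' }
#'
#' Counts are normalized by median-of-ratios over the site x sample matrix
#' before fitting (within-transcript usage proportions are scale-invariant,
#' so this matters mainly when absolute usage is inspected); transcripts with
#' fewer than two sites carrying reads are flagged untestable.
#'
#' @param pas A \code{pas_counts} table (see \code{\link{read_pas_counts}}).
#' @param design A \code{design_matrix} covering the PAS samples.
#' @param mode \code{"overall"}, \code{"reference"} or \code{"pairwise"}.
#' @param reference Reference-site rule for mode \code{"reference"}:
#'   \code{"alphabetical"} (default), \code{"proximal"}, or a named character
#'   vector transcript_id -> site_id.
#' @param normalize Median-of-ratios normalize the site x sample counts
#'   first (default TRUE; falls back to unit factors when no site has
#'   positive counts in every sample).
#' @param log2_scale Report effect sizes in log2 rather than natural log.
#' @return An \code{apa_table} data.frame; columns depend on the mode and
#'   always include raw \code{p} and BH-adjusted \code{fdr} (computed across
#'   all test rows of the mode).
#' @export
apa_test <- function(pas, design, mode = c("overall", "reference", "pairwise"),
                     reference = "alphabetical", normalize = TRUE,
                     log2_scale = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(pas, "pas_counts"))
  samp <- attr(pas, "sample_ids")
  X <- design$X[match(samp, design$sample_ids), , drop = FALSE]
  if (anyNA(X)) stop("design does not cover all PAS samples")
  cnt <- as.matrix(pas[, samp, drop = FALSE])
  if (normalize) {
    f <- size_factors(count_matrix(structure(cnt,
           dimnames = list(paste(pas$transcript_id, pas$site_id), samp)), "PAS"),
           on_fail = "ones")
    cnt <- sweep(cnt, 2L, as.numeric(f[samp]), "/")
  }
  scale_div <- if (log2_scale) log(2) else 1

  rows <- list()
  for (tx in unique(pas$transcript_id)) {
    i <- which(pas$transcript_id == tx)
    Yt <- t(cnt[i, , drop = FALSE])            # samples x sites
    colnames(Yt) <- pas$site_id[i]
    ranks <- pas$rank[i]
    use <- colSums(Yt) > 0
    if (!pas$testable[i[1L]] || sum(use) < 2L ||
        sum(rowSums(Yt) > 0) < 2L) {
      rows[[length(rows) + 1L]] <- apa_untestable_row(tx, mode)
      next
    }
    Yt <- Yt[, use, drop = FALSE]
    ranks <- ranks[use]

    if (mode == "pairwise") {
      sites <- colnames(Yt)
      for (a in seq_len(ncol(Yt) - 1L)) for (b in seq((a + 1L), ncol(Yt))) {
        # orient alphabetically: reference = first site id, model log(alt/ref)
        pair <- sort(c(sites[a], sites[b]))
        y1 <- Yt[, pair[1L]]; y2 <- Yt[, pair[2L]]
        keep <- (y1 + y2) > 0
        Xk <- X[keep, , drop = FALSE]
        if (sum(keep) < 2L || qr(Xk)$rank < ncol(Xk)) next
        tot <- (y1 + y2)[keep]
        fit <- suppressWarnings(stats::glm.fit(Xk, y2[keep] / tot,
                 weights = tot, family = stats::binomial()))
        mu <- fit$fitted.values
        V <- tryCatch(solve(crossprod(Xk, Xk * (tot * mu * (1 - mu)))),
                      error = function(e) NULL)
        if (is.null(V)) next
        se <- sqrt(pmax(diag(V), 0))
        for (cx in which(colnames(X) != "(Intercept)")) {
          z <- fit$coefficients[cx] / se[cx]
          rows[[length(rows) + 1L]] <- data.frame(
            transcript_id = tx, ref_site = pair[1L], alt_site = pair[2L],
            term = colnames(X)[cx],
            estimate = fit$coefficients[cx] / scale_div,
            se = se[cx] / scale_div, z = z, p = 2 * stats::pnorm(-abs(z)),
            status = if (sum(keep) < length(y1)) "samples_dropped" else "ok",
            stringsAsFactors = FALSE)
        }
      }
    } else {
      ref_site <- apa_reference_site(colnames(Yt), ranks, reference, tx)
      ord <- c(ref_site, setdiff(colnames(Yt), ref_site))
      Yo <- Yt[, ord, drop = FALSE]
      full <- fit_multinom_logit(Yo, X)
      if (mode == "overall") {
        null <- fit_multinom_logit(Yo, X[, "(Intercept)", drop = FALSE])
        dev <- max(0, 2 * (full$loglik - null$loglik))
        df <- (ncol(Yo) - 1L) * (ncol(X) - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = tx, n_sites = ncol(Yo), ref_site = ref_site,
          deviance = dev, df = df,
          p = stats::pchisq(dev, df, lower.tail = FALSE),
          status = if (full$separated) "separation" else "ok",
          stringsAsFactors = FALSE)
      } else {
        p <- ncol(X)
        se_all <- sqrt(pmax(diag(full$vcov), 0))
        for (s in seq(2L, ncol(Yo))) {
          ix <- ((s - 2L) * p + 1L):((s - 1L) * p)
          for (cx in which(colnames(X) != "(Intercept)")) {
            b <- full$coef[cx, s - 1L]; se <- se_all[ix][cx]
            z <- if (se > 0) b / se else NA_real_
            rows[[length(rows) + 1L]] <- data.frame(
              transcript_id = tx, ref_site = ref_site,
              alt_site = colnames(Yo)[s], term = colnames(X)[cx],
              alpha = full$coef["(Intercept)", s - 1L],
              estimate = b / scale_div, se = se / scale_div, z = z,
              p = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
              status = if (full$separated) "separation"
                       else if (is.na(z)) "se_infinite" else "ok",
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- adjust_pvalues(out$p)
  attr(out, "mode") <- mode
  class(out) <- c("apa_table", "data.frame")
  out
}

apa_untestable_row <- function(tx, mode) {
  if (mode == "overall")
    data.frame(transcript_id = tx, n_sites = NA_integer_, ref_site = NA,
               deviance = NA_real_, df = NA_integer_, p = NA_real_,
               status = "untestable", stringsAsFactors = FALSE)
  else if (mode == "reference")
    data.frame(transcript_id = tx, ref_site = NA, alt_site = NA, term = NA,
               alpha = NA_real_, estimate = NA_real_, se = NA_real_,
               z = NA_real_, p = NA_real_, status = "untestable",
               stringsAsFactors = FALSE)
  else
    data.frame(transcript_id = tx, ref_site = NA, alt_site = NA, term = NA,
               estimate = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
               status = "untestable", stringsAsFactors = FALSE)
}

apa_reference_site <- function(sites, ranks, reference, tx) {
  if (length(reference) == 1L && reference == "alphabetical") {
    sort(sites)[1L]
  } else if (length(reference) == 1L && reference == "proximal") {
    sites[which.min(ranks)]
  } else {
    r <- reference[[tx]]
    if (is.null(r) || is.na(r) || !r %in% sites)
      stop("requested reference site not found for transcript ", tx)
    r
  }
}

#' logAPAR: log fold change in proximal-to-distal poly(A)-site usage
#'
#' Extracts, for each transcript, the condition effect on the odds
#' log(proximal / distal) from a pairwise \code{\link{apa_test}} result.
#' Positive logAPAR means relatively MORE proximal-site usage at the higher
#' value of the contrast covariate (its second level); 3' UTR lengthening
#' (a proximal-to-distal switch) therefore shows up as negative logAPAR.
#'
#' @param pairwise An \code{apa_table} from \code{apa_test(..., mode =
#'   "pairwise")}.
#' @param pas The \code{pas_counts} table (for site ranks).
#' @param term Design column holding the condition contrast; defaults to the
#'   only non-intercept term present.
#' @param pairs \code{"extreme"} (default: most proximal vs most distal
#'   site) or \code{"adjacent"} (every rank-adjacent pair).
#' @return data.frame: transcript_id, proximal_site, distal_site, logAPAR,
#'   se, p, fdr.
#' @export
compute_logapar <- function(pairwise, pas, term = NULL,
                            pairs = c("extreme", "adjacent")) {
  pairs <- match.arg(pairs)
  stopifnot(inherits(pairwise, "apa_table"))
  if (!all(c("ref_site", "alt_site") %in% colnames(pairwise)))
    stop("compute_logapar needs a pairwise apa_table")
  if (is.null(term)) {
    terms <- setdiff(unique(stats::na.omit(pairwise$term)), "(Intercept)")
    if (length(terms) != 1L)
      stop("specify 'term'; candidates: ", paste(terms, collapse = ", "))
    term <- terms
  }
  if (any(is.na(pas$rank))) stop("site ranks unknown; supply a BED file")
  rows <- list()
  for (tx in unique(pas$transcript_id[pas$testable])) {
    i <- which(pas$transcript_id == tx)
    ord <- i[order(pas$rank[i])]
    sel <- if (pairs == "extreme") {
      list(c(ord[1L], ord[length(ord)]))
    } else {
      lapply(seq_len(length(ord) - 1L), function(k) ord[c(k, k + 1L)])
    }
    for (pr in sel) {
      prox <- pas$site_id[pr[1L]]; dist <- pas$site_id[pr[2L]]
      hit <- which(pairwise$transcript_id == tx & pairwise$term == term &
                   ((pairwise$ref_site == prox & pairwise$alt_site == dist) |
                    (pairwise$ref_site == dist & pairwise$alt_site == prox)))
      if (length(hit) == 0L) next
      h <- pairwise[hit[1L], ]
      # pairwise fits model log(alt/ref); flip sign if proximal was the ref
      lap <- if (h$alt_site == prox) h$estimate else -h$estimate
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tx, proximal_site = prox, distal_site = dist,
        logAPAR = lap, se = h$se, p = h$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(transcript_id = character(),
    proximal_site = character(), distal_site = character(),
    logAPAR = numeric(), se = numeric(), p = numeric(), fdr = numeric()))
  out$fdr <- adjust_pvalues(out$p)
  out
}
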