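#' Per-transcript translation-efficiency-ratio (TER) test
#'
#' Models translation efficiency as the odds of drawing an RPF versus an RNA
#' read for a transcript in a sample, and tests how those odds depend on the
#' sample covariates via binomial logistic regression:
#' \deqn{\log TE = \log(RPF/RNA) = \alpha + \sum_i \beta_i X_i.}
#' The model is fitted separately per transcript; each sample contributes its
#' (normalized, optionally stalling-debiased) RPF count as "successes" and
#' RNA count as "failures". Real-valued counts are used as likelihood weights
#' without rounding. In the degenerate two-unreplicated-sample case the
#' fitted coefficient equals the log odds ratio of the 2x2 table (see
#' \code{\link{ter_2x2}}).
#'
#' With \code{dispersion = TRUE}, standard errors are inflated by the square
#' root of the Pearson chi-square / residual-df estimate (floored at 1) and
#' p-values use a t reference with the residual degrees of freedom — the
#' quasi-binomial treatment recommended for replicated designs, where
#' biological variability exceeds counting noise.
#'
#' @param rpf,rna \code{count_matrix} objects with matching transcripts and
#'   samples (normalize first; see \code{\link{normalize_counts}}).
#' @param design A \code{design_matrix} covering the samples.
#' @param min_total Transcripts whose RPF+RNA total falls below this in any
#'   sample are marked untestable (default 10).
#' @param pseudocount 0 (default), a positive constant added to every count,
#'   or \code{"auto"} to add 0.5 (Haldane) only when a transcript has a zero
#'   count somewhere.
#' @param dispersion Apply the quasi-binomial SE inflation / t reference.
#' @return A \code{ter_fit}: list with matrices \code{coef}, \code{se},
#'   \code{z}, \code{p} (transcripts x coefficients), \code{status} per
#'   transcript (\code{"ok"}, \code{"untestable"}, \code{"not_converged"},
#'   \code{"separation"}), per-transcript \code{phi}, the design, and mean
#'   normalized counts.
#' @export
ter_test <- function(rpf, rna, design, min_total = 10, pseudocount = 0,
                     dispersion = FALSE) {
  if (!identical(rownames(rpf), rownames(rna)))
    stop("RPF and RNA matrices must have identical transcripts in the same order")
  if (!identical(colnames(rpf), colnames(rna)))
    stop("RPF and RNA matrices must have identical samples in the same order")
  X <- design$X[match(colnames(rpf), design$sample_ids), , drop = FALSE]
  if (anyNA(X)) stop("design does not cover all samples in the count matrices")
  p <- ncol(X)
  K <- nrow(X)
  tx <- rownames(rpf)
  nt <- length(tx)

  coefm <- matrix(NA_real_, nt, p, dimnames = list(tx, colnames(X)))
  sem <- zm <- pm <- coefm
  vcov_arr <- array(NA_real_, c(p, p, nt),
                    dimnames = list(colnames(X), colnames(X), tx))
  status <- setNames(rep("ok", nt), tx)
  phi <- setNames(rep(1, nt), tx)
  df_resid <- K - p

  for (j in seq_len(nt)) {
    r <- as.numeric(rpf[j, ]); n <- as.numeric(rna[j, ])
    if (any(r + n < min_total)) { status[j] <- "untestable"; next }
    if (identical(pseudocount, "auto")) {
      if (any(r == 0) || any(n == 0)) { r <- r + 0.5; n <- n + 0.5 }
    } else if (pseudocount > 0) {
      r <- r + pseudocount; n <- n + pseudocount
    }
    tot <- r + n
    fit <- suppressWarnings(
      stats::glm.fit(X, r / tot, weights = tot, family = stats::binomial()))
    beta <- fit$coefficients
    mu <- fit$fitted.values
    w_info <- tot * mu * (1 - mu)
    XtWX <- crossprod(X, X * w_info)
    V <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(V) || anyNA(beta)) { status[j] <- "not_converged"; next }
    if (!fit$converged) status[j] <- "not_converged"
    disp <- 1
    if (dispersion && df_resid > 0) {
      pearson <- sum((r - tot * mu)^2 / pmax(tot * mu * (1 - mu), 1e-12))
      disp <- max(1, pearson / df_resid)
    }
    phi[j] <- disp
    se <- sqrt(pmax(diag(V), 0) * disp)
    z <- beta / se
    pv <- if (dispersion && df_resid > 0) 2 * stats::pt(-abs(z), df_resid)
          else 2 * stats::pnorm(-abs(z))
    if (any(abs(beta[-1L]) > 10) && status[j] == "ok") {
      status[j] <- "separation"
      # Wald collapses under separation: fall back to drop-one LRT p-values
      for (cix in seq_len(p)) {
        X0 <- X[, -cix, drop = FALSE]
        f0 <- if (ncol(X0) > 0)
          suppressWarnings(stats::glm.fit(X0, r / tot, weights = tot,
                                          family = stats::binomial()))
        else list(deviance = binom_null_deviance(r, tot))
        lrt <- max(0, f0$deviance - fit$deviance)
        pv[cix] <- stats::pchisq(lrt / disp, df = 1L, lower.tail = FALSE)
      }
    }
    coefm[j, ] <- beta; sem[j, ] <- se; zm[j, ] <- z; pm[j, ] <- pv
    vcov_arr[, , j] <- V * disp
  }

  structure(list(coef = coefm, se = sem, z = zm, p = pm, vcov = vcov_arr,
                 status = status, phi = phi, design = design,
                 dispersion = dispersion, df_resid = df_resid,
                 mean_rpf = rowMeans(unclass(rpf)),
                 mean_rna = rowMeans(unclass(rna))),
            class = "ter_fit")
}

binom_null_deviance <- function(r, tot) {
  mu <- sum(r) / sum(tot)
  y <- r / tot
  -2 * sum(tot * (y * log(ifelse(y > 0, mu / y, 1)) +
                  (1 - y) * log(ifelse(y < 1, (1 - mu) / (1 - y), 1))))
}

#' Predicted TER between two covariate settings
#'
#' Substitutes fitted coefficients into
#' \deqn{TER = TE_2/TE_1 = \exp\{\sum_i \beta_i (X_{i,2} - X_{i,1})\}.}
#'
#' @param fit A \code{ter_fit}.
#' @param x1,x2 Named numeric vectors of covariate values for the two
#'   settings (names matching design columns; omitted columns default to 0,
#'   and the intercept always cancels).
#' @return data.frame with transcript_id, logTER, TER, se, p (Wald test of
#'   the contrast, using the fit's dispersion treatment).
#' @export
predict_ter <- function(fit, x1, x2) {
  cols <- colnames(fit$coef)
  d <- setNames(numeric(length(cols)), cols)
  for (nm in names(x2)) {
    if (!nm %in% cols) stop("unknown design column in contrast: ", nm)
    d[nm] <- d[nm] + x2[[nm]]
  }
  for (nm in names(x1)) {
    if (!nm %in% cols) stop("unknown design column in contrast: ", nm)
    d[nm] <- d[nm] - x1[[nm]]
  }
  d["(Intercept)"] <- 0
  logter <- as.vector(fit$coef %*% d)
  se <- sqrt(apply(fit$vcov, 3L, function(V) drop(t(d) %*% V %*% d)))
  z <- logter / se
  p <- if (fit$dispersion && fit$df_resid > 0) 2 * stats::pt(-abs(z), fit$df_resid)
       else 2 * stats::pnorm(-abs(z))
  data.frame(transcript_id = rownames(fit$coef), logTER = logter,
             TER = exp(logter), se = se, p = p,
             stringsAsFactors = FALSE)
}

#' Build a contrast from a design's original covariates
#'
#' Translates \code{"group=A,B"}-style requests (compare level B to level A
#' of covariate \code{group}, or value v2 to v1 of a numeric covariate) into
#' the \code{x1}/\code{x2} vectors used by \code{\link{predict_ter}}.
#'
#' @param design A \code{design_matrix}.
#' @param spec String of the form \code{"column=value1,value2"}.
#' @return List with elements \code{x1} and \code{x2}.
#' @export
design_contrast <- function(design, spec) {
  m <- regmatches(spec, regexec("^([^=]+)=([^,]+),([^,]+)$", spec))[[1L]]
  if (length(m) != 4L)
    stop("contrast must look like 'column=value1,value2': ", spec)
  col <- m[2L]; v1 <- m[3L]; v2 <- m[4L]
  if (col %in% names(design$encoding)) {
    lev <- design$encoding[[col]]
    if (!v1 %in% lev || !v2 %in% lev)
      stop("level(s) not found for '", col, "': levels are ",
           paste(lev, collapse = ", "))
    mk <- function(v) {
      x <- setNames(numeric(length(lev) - 1L), paste(col, lev[-1L], sep = "_"))
      if (v != lev[1L]) x[paste(col, v, sep = "_")] <- 1
      x
    }
    list(x1 = mk(v1), x2 = mk(v2))
  } else if (col %in% colnames(design$X)) {
    list(x1 = setNames(as.numeric(v1), col), x2 = setNames(as.numeric(v2), col))
  } else {
    stop("unknown design column: ", col)
  }
}

#' TER results table for a contrast
#'
#' @param fit A \code{ter_fit}.
#' @param contrast Either a string (see \code{\link{design_contrast}}) or a
#'   list with \code{x1}, \code{x2}.
#' @return data.frame: transcript_id, logTER, TER, p, fdr (BH over testable
#'   transcripts), mean_rpf, mean_rna, status.
#' @export
ter_table <- function(fit, contrast) {
  if (is.character(contrast)) contrast <- design_contrast(fit$design, contrast)
  pr <- predict_ter(fit, contrast$x1, contrast$x2)
  ok <- fit$status != "untestable"
  pr$logTER[!ok] <- NA; pr$TER[!ok] <- NA; pr$p[!ok] <- NA
  data.frame(transcript_id = pr$transcript_id,
             logTER = pr$logTER, TER = pr$TER, p = pr$p,
             fdr = adjust_pvalues(pr$p),
             mean_rpf = fit$mean_rpf, mean_rna = fit$mean_rna,
             status = fit$status, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Exact 2x2 oracle for the unreplicated TER comparison
#'
#' For two unreplicated samples the TER test reduces to a 2x2 contingency
#' table with sample as exposure and read type (RPF vs RNA) as response; this
#' helper computes the log odds ratio together with chi-square and Fisher
#' exact p-values, and serves as a built-in QC reference for the regression.
#'
#' @param rpf1,rna1,rpf2,rna2 Non-negative counts of the four cells.
#' @param pseudocount Added to every cell when positive (Haldane 0.5 is the
#'   usual choice for zero cells); with 0 and a zero margin the odds ratio is
#'   NA.
#' @return List with log_or, chisq_p, fisher_p.
#' @export
ter_2x2 <- function(rpf1, rna1, rpf2, rna2, pseudocount = 0) {
  tab <- matrix(c(rpf1, rna1, rpf2, rna2), nrow = 2L, byrow = TRUE)
  a <- tab + pseudocount
  log_or <- if (any(a == 0)) NA_real_
            else log((a[2, 1] / a[2, 2]) / (a[1, 1] / a[1, 2]))
  chisq_p <- tryCatch(
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value),
    error = function(e) NA_real_)
  fisher_p <- tryCatch(stats::fisher.test(round(tab))$p.value,
                       error = function(e) NA_real_)
  list(log_or = log_or, chisq_p = chisq_p, fisher_p = fisher_p)
}

#' Benjamini-Hochberg adjustment with NA propagation
#'
#' @param p Vector of p-values (NAs allowed; they stay NA and are excluded
#'   from the adjustment).
#' @param method Passed to \code{\link[stats]{p.adjust}} (default "BH").
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = method)
  out
}
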