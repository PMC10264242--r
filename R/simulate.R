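#' Simulate paired RNA/RPF count matrices with known ground truth
#'
#' Generates the data structure assumed by the TER test: per-transcript RNA
#' counts are negative binomial around a log-normal baseline expression,
#' RPF counts are negative binomial around baseline x TE odds, with a
#' group-specific multiplicative TE effect (exp(logTER)) planted in a chosen
#' fraction of transcripts. Optionally, codon-resolution RPF profiles are
#' emitted, with multiplicative stalling peaks planted at random codons of
#' selected transcripts in one group; profiles and the RPF matrix are
#' consistent by construction (profile totals are the matrix counts, and
#' stalling inflates both by (L - m + fold*m)/L for m spiked codons).
#'
#' Negative binomial dispersion is parameterized as variance = mu + phi*mu^2.
#'
#' @param params List overriding any of the defaults:
#'   \describe{
#'     \item{n_transcripts}{2000}
#'     \item{n_per_group}{c(3, 3) samples in groups "A" and "B"}
#'     \item{depth}{per-sample relative library depths (default all 1)}
#'     \item{meanlog, sdlog}{log-normal baseline expression, default
#'       log(300), 0.5}
#'     \item{mu}{optional explicit per-transcript baseline means (overrides
#'       the log-normal draw; useful for matched twins)}
#'     \item{phi}{NB dispersion, default 0.1}
#'     \item{te_odds}{baseline RPF:RNA odds, default 1}
#'     \item{effect_fraction}{fraction of transcripts with a TE effect,
#'       default 0}
#'     \item{effect_logter}{planted logTER for the effect set, default
#'       log(2)}
#'     \item{stall_fraction}{fraction of transcripts given stalling peaks
#'       (in group "B" samples), default 0}
#'     \item{stall_codons}{number of spiked codons, default 5}
#'     \item{stall_fold}{peak fold, default 10}
#'     \item{codon_length}{CDS length in codons, default 200}
#'     \item{profiles}{emit codon profiles (default TRUE when
#'       stall_fraction > 0)}
#'   }
#' @param seed Mandatory RNG seed.
#' @return List: rna and rpf (\code{count_matrix}), profiles
#'   (\code{codon_profiles} or NULL), truth (data.frame transcript_id,
#'   true_logter, effect, spiked, spiked_codons, mu), design
#'   (\code{design_matrix} with column group).
#' @export
simulate_ribo <- function(params = list(), seed) {
  if (missing(seed)) stop("simulate_ribo requires an explicit seed")
  d <- list(n_transcripts = 2000L, n_per_group = c(3L, 3L), depth = NULL,
            meanlog = log(300), sdlog = 0.5, mu = NULL, phi = 0.1,
            te_odds = 1, effect_fraction = 0, effect_logter = log(2),
            stall_fraction = 0, stall_codons = 5L, stall_fold = 10,
            codon_length = 200L, profiles = NULL)
  unknown <- setdiff(names(params), names(d))
  if (length(unknown) > 0L)
    stop("unknown simulation parameter(s): ", paste(unknown, collapse = ", "))
  d[names(params)] <- params
  with(d, {
    stopifnot(phi > 0, te_odds > 0, effect_fraction >= 0, effect_fraction <= 1,
              stall_fraction >= 0, stall_fraction <= 1, stall_fold > 0,
              all(n_per_group >= 1))
  })
  if (is.null(d$profiles)) d$profiles <- d$stall_fraction > 0

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  nt <- d$n_transcripts
  K <- sum(d$n_per_group)
  group <- rep(c("A", "B"), d$n_per_group)
  samples <- paste0(group, unlist(lapply(d$n_per_group, seq_len)))
  depth <- if (is.null(d$depth)) rep(1, K) else rep_len(d$depth, K)
  tx <- sprintf("tx%04d", seq_len(nt))

  mu <- if (is.null(d$mu)) stats::rlnorm(nt, d$meanlog, d$sdlog) else rep_len(d$mu, nt)
  n_eff <- round(d$effect_fraction * nt)
  effect <- seq_len(nt) <= n_eff     # deterministic membership, random mu
  logter <- ifelse(effect, d$effect_logter, 0)
  n_sp <- round(d$stall_fraction * nt)
  spiked <- seq_len(nt) <= n_sp

  L <- rep_len(d$codon_length, nt)
  spike_pos <- lapply(seq_len(nt), function(j) {
    if (spiked[j]) sort(sample.int(L[j], d$stall_codons)) else integer(0)
  })

  rna <- matrix(0, nt, K, dimnames = list(tx, samples))
  rpf <- matrix(0, nt, K, dimnames = list(tx, samples))
  prof <- if (d$profiles) vector("list", nt)

  for (j in seq_len(nt)) {
    mu_rna <- mu[j] * depth
    rna[j, ] <- stats::rnbinom(K, mu = mu_rna, size = 1 / d$phi)
    te_mult <- ifelse(group == "B", exp(logter[j]), 1)
    stall_mult <- if (spiked[j]) {
      m <- length(spike_pos[[j]])
      ifelse(group == "B", (L[j] - m + d$stall_fold * m) / L[j], 1)
    } else rep(1, K)
    mu_rpf <- mu[j] * depth * d$te_odds * te_mult * stall_mult
    rpf[j, ] <- stats::rnbinom(K, mu = mu_rpf, size = 1 / d$phi)
    if (d$profiles) {
      w <- matrix(1, L[j], K)
      if (spiked[j]) w[spike_pos[[j]], group == "B"] <- d$stall_fold
      pm <- matrix(0, L[j], K, dimnames = list(NULL, samples))
      for (k in seq_len(K)) {
        if (rpf[j, k] > 0)
          pm[, k] <- stats::rmultinom(1L, rpf[j, k], w[, k])[, 1L]
      }
      prof[[j]] <- pm
    }
  }

  truth <- data.frame(transcript_id = tx, true_logter = logter,
                      effect = effect, spiked = spiked,
                      spiked_codons = vapply(spike_pos, function(x)
                        paste(x - 1L, collapse = ","), character(1L)),
                      mu = mu, stringsAsFactors = FALSE)
  design <- design_matrix(samples,
                          data.frame(group = group, stringsAsFactors = FALSE))
  profs <- if (d$profiles) { names(prof) <- tx; codon_profiles(prof) }
  list(rna = count_matrix(rna, "RNA"), rpf = count_matrix(rpf, "RPF"),
       profiles = profs, truth = truth, design = design, params = d)
}

#' Simulate poly(A)-site count tables with known ground truth
#'
#' Per transcript, baseline site-usage proportions are drawn from a
#' symmetric Dirichlet; in condition "B", a chosen fraction of transcripts
#' has a log-odds shift delta added to the proximal (rank-1) site. Per
#' sample, site counts are multinomial with total reads_per_site x S.
#'
#' @param params List overriding the defaults: n_transcripts (1000),
#'   sites_range (c(2, 4)), dirichlet_alpha (2), shift_fraction (0), delta
#'   (1), reads_per_site (500), n_per_condition (c(2, 2)).
#' @param seed Mandatory RNG seed.
#' @return List: pas (\code{pas_counts}), truth (data.frame transcript_id,
#'   delta, shifted, n_sites), design (\code{design_matrix} with column
#'   condition).
#' @export
simulate_apa <- function(params = list(), seed) {
  if (missing(seed)) stop("simulate_apa requires an explicit seed")
  d <- list(n_transcripts = 1000L, sites_range = c(2L, 4L),
            dirichlet_alpha = 2, shift_fraction = 0, delta = 1,
            reads_per_site = 500, n_per_condition = c(2L, 2L))
  unknown <- setdiff(names(params), names(d))
  if (length(unknown) > 0L)
    stop("unknown simulation parameter(s): ", paste(unknown, collapse = ", "))
  d[names(params)] <- params
  stopifnot(d$dirichlet_alpha > 0, d$reads_per_site > 0,
            d$shift_fraction >= 0, d$shift_fraction <= 1)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  nt <- d$n_transcripts
  cond <- rep(c("A", "B"), d$n_per_condition)
  samples <- paste0(cond, unlist(lapply(d$n_per_condition, seq_len)))
  K <- length(samples)
  tx <- sprintf("tx%04d", seq_len(nt))
  n_shift <- round(d$shift_fraction * nt)
  shifted <- seq_len(nt) <= n_shift

  S <- sample(seq(d$sites_range[1L], d$sites_range[2L]), nt, replace = TRUE)
  rows <- vector("list", nt)
  for (j in seq_len(nt)) {
    g <- stats::rgamma(S[j], shape = d$dirichlet_alpha)
    p_base <- g / sum(g)
    lo <- log(p_base)
    lo_b <- lo; if (shifted[j]) lo_b[1L] <- lo_b[1L] + d$delta
    p_b <- exp(lo_b) / sum(exp(lo_b))
    total <- d$reads_per_site * S[j]
    cnt <- matrix(0, S[j], K)
    for (k in seq_len(K)) {
      pk <- if (cond[k] == "B") p_b else p_base
      cnt[, k] <- stats::rmultinom(1L, total, pk)[, 1L]
    }
    rows[[j]] <- data.frame(transcript_id = tx[j],
                            site_id = sprintf("pA%d", seq_len(S[j])),
                            rank = seq_len(S[j]), testable = S[j] >= 2L,
                            stringsAsFactors = FALSE)
    rows[[j]] <- cbind(rows[[j]],
                       as.data.frame(cnt, col.names = samples))
  }
  pas <- do.call(rbind, rows)
  colnames(pas)[-(1:4)] <- samples
  attr(pas, "sample_ids") <- samples
  class(pas) <- c("pas_counts", "data.frame")

  truth <- data.frame(transcript_id = tx,
                      delta = ifelse(shifted, d$delta, 0),
                      shifted = shifted, n_sites = S, stringsAsFactors = FALSE)
  design <- design_matrix(samples,
                          data.frame(condition = cond, stringsAsFactors = FALSE))
  list(pas = pas, truth = truth, design = design, params = d)
}

#' Write simulated ribosome-profiling data as the TSV dialects read by the
#' package
#'
#' @param sim Result of \code{\link{simulate_ribo}} or
#'   \code{\link{simulate_apa}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr_cm <- function(m, path) {
    df <- data.frame(transcript_id = rownames(m), as.data.frame(unclass(m),
                     check.names = FALSE), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  if (!is.null(sim$rna)) {
    paths <- c(paths, wr_cm(sim$rna, file.path(dir, "rna.tsv")),
               wr_cm(sim$rpf, file.path(dir, "rpf.tsv")))
    if (!is.null(sim$profiles)) {
      long <- do.call(rbind, lapply(names(sim$profiles), function(t) {
        m <- sim$profiles[[t]]
        data.frame(transcript_id = t,
                   sample_id = rep(colnames(m), each = nrow(m)),
                   codon_index = rep(seq_len(nrow(m)) - 1L, ncol(m)),
                   count = as.vector(m), stringsAsFactors = FALSE)
      }))
      utils::write.table(long, file.path(dir, "codon_counts.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      paths <- c(paths, file.path(dir, "codon_counts.tsv"))
    }
  }
  if (!is.null(sim$pas)) {
    utils::write.table(as.data.frame(sim$pas)[, c("transcript_id", "site_id",
                       attr(sim$pas, "sample_ids"))],
                       file.path(dir, "pas.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, file.path(dir, "pas.tsv"))
  }
  dm <- data.frame(sample_id = sim$design$sample_ids,
                   sim$design$X[, -1L, drop = FALSE] != 0, check.names = FALSE)
  # re-emit the original categorical column when it was a two-level factor
  enc <- sim$design$encoding
  if (length(enc) == 1L) {
    col <- names(enc)[1L]
    lev <- enc[[col]]
    ind <- sim$design$X[, paste(col, lev[-1L], sep = "_"), drop = FALSE]
    val <- lev[1L + as.integer(ind %*% seq_along(lev[-1L]))]
    dm <- data.frame(sample_id = sim$design$sample_ids, v = val,
                     stringsAsFactors = FALSE)
    colnames(dm)[2L] <- col
  }
  utils::write.table(dm, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, file.path(dir, c("design.tsv", "truth.tsv")))
  invisible(paths)
}
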