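#' Read a transcript x sample count matrix
#'
#' Parses a tab-separated table whose first column holds transcript IDs and
#' whose header row holds sample IDs. Counts may be real-valued (e.g.
#' EM-apportioned or normalized counts); they must be non-negative.
#'
#' @param path Path to a tab-separated file.
#' @param read_type One of \code{"RPF"}, \code{"RNA"}, \code{"PAS"}; recorded
#'   on the returned object so downstream functions can check they are fed
#'   the intended assay.
#' @return A \code{count_matrix}: a numeric matrix (transcripts x samples,
#'   dimnames set) with attribute \code{read_type}.
#' @export
read_count_matrix <- function(path, read_type = c("RPF", "RNA", "PAS")) {
  read_type <- match.arg(read_type)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("count table must have an ID column plus at least one sample column")
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicated transcript ID(s): ", paste(unique(dup), collapse = ", "))
  samp <- colnames(df)[-1L]
  if (anyDuplicated(samp))
    stop("duplicated sample ID(s) in header")
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop("non-numeric count at transcript '", ids[bad],
           "', sample '", samp[j], "'")
    }
  }
  m <- as.matrix(body)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("missing count at transcript '", ids[idx[1L]],
         "', sample '", samp[idx[2L]], "'")
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop("negative count at transcript '", ids[idx[1L]],
         "', sample '", samp[idx[2L]], "'")
  }
  dimnames(m) <- list(ids, samp)
  count_matrix(m, read_type)
}

#' Construct a count matrix object
#'
#' @param m Numeric matrix with transcript row names and sample column names.
#' @param read_type Assay label: \code{"RPF"}, \code{"RNA"} or \code{"PAS"}.
#' @return A \code{count_matrix}.
#' @export
count_matrix <- function(m, read_type = c("RPF", "RNA", "PAS")) {
  read_type <- match.arg(read_type)
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix needs transcript row names and sample column names")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("row/column labels must be unique")
  if (any(m < 0)) stop("counts must be non-negative")
  structure(m, read_type = read_type, class = c("count_matrix", "matrix", "array"))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix [%s]: %d transcripts x %d samples\n",
              attr(x, "read_type"), nrow(x), ncol(x)))
  print(utils::head(unclass(x)), ...)
  invisible(x)
}

#' Read a sample design table
#'
#' First column: sample IDs; remaining columns: covariates. Character or
#' factor columns are expanded to 0/1 indicator columns, one per non-baseline
#' level, with the alphabetically first level as baseline (so the expansion
#' is deterministic). An intercept column is prepended.
#'
#' @param path Path to a tab-separated file.
#' @return A \code{design_matrix}: list with \code{sample_ids}, model matrix
#'   \code{X} (samples x columns, intercept first), and \code{encoding}
#'   (named list mapping each original categorical column to its level set).
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("design table must have a sample ID column plus covariates")
  design_matrix(df[[1L]], df[, -1L, drop = FALSE])
}

#' Build a design matrix from sample IDs and covariates
#'
#' @param sample_ids Character vector of sample IDs.
#' @param covariates data.frame of covariates (numeric, or categorical to be
#'   indicator-expanded with alphabetical baseline).
#' @param intercept Prepend an intercept column (default TRUE).
#' @return A \code{design_matrix}.
#' @export
design_matrix <- function(sample_ids, covariates, intercept = TRUE) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicated sample IDs in design")
  cols <- list()
  encoding <- list()
  for (nm in colnames(covariates)) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- as.numeric(v)
    } else {
      lev <- sort(unique(as.character(v)))
      encoding[[nm]] <- lev
      for (l in lev[-1L])
        cols[[paste(nm, l, sep = "_")]] <- as.numeric(v == l)
    }
  }
  X <- do.call(cbind, c(if (intercept) list("(Intercept)" = rep(1, length(sample_ids))),
                        cols))
  rownames(X) <- sample_ids
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1L, ncol(X))]]
    stop("design is rank-deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(sample_ids = sample_ids, X = X, encoding = encoding,
                 intercept = intercept),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d samples, columns: %s\n",
              length(x$sample_ids), paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

#' Read poly(A)-site counts
#'
#' Expects a tab-separated table with columns \code{transcript_id},
#' \code{site_id}, then one column per sample. Site ranks (1 = most proximal,
#' i.e. nearest the stop codon along the transcript) are taken from an
#' optional BED6 file of site positions, respecting strand; without a BED,
#' ranks follow lexicographic site-ID order and a warning is issued.
#'
#' @param path PAS count TSV.
#' @param bed_path Optional BED6 file (chrom, start, end, name = site_id,
#'   score, strand), 0-based half-open.
#' @return A \code{pas_counts} data.frame with columns \code{transcript_id},
#'   \code{site_id}, \code{rank}, \code{testable}, then sample columns;
#'   attribute \code{sample_ids}.
#' @export
read_pas_counts <- function(path, bed_path = NULL) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("PAS table needs transcript_id, site_id and at least one sample column")
  colnames(df)[1:2] <- c("transcript_id", "site_id")
  samp <- colnames(df)[-(1:2)]
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) stop("PAS counts must be numeric with no missing values")
  if (any(m < 0)) stop("PAS counts must be non-negative")
  key <- paste(df$transcript_id, df$site_id)
  if (anyDuplicated(key)) stop("duplicated (transcript_id, site_id) rows")

  if (!is.null(bed_path)) {
    bed <- utils::read.delim(bed_path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(bed) < 6L) stop("BED file must have 6 columns (BED6)")
    colnames(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
    missing_sites <- setdiff(bed$name, df$site_id)
    if (length(missing_sites) > 0L)
      stop("BED site_id(s) not present in PAS table: ",
           paste(missing_sites, collapse = ", "))
    pos <- bed$start[match(df$site_id, bed$name)]
    str <- bed$strand[match(df$site_id, bed$name)]
    if (anyNA(pos))
      stop("site(s) without a BED entry: ",
           paste(df$site_id[is.na(pos)], collapse = ", "))
    # transcript-relative coordinate: increases downstream along the
    # transcript, so on "-" the largest genomic coordinate is most proximal
    relpos <- ifelse(str == "-", -pos, pos)
  } else {
    warning("no BED supplied; PAS ranks assigned from lexicographic site_id order")
    relpos <- NULL
  }

  rank <- integer(nrow(df))
  for (tx in unique(df$transcript_id)) {
    i <- which(df$transcript_id == tx)
    if (is.null(relpos)) {
      rank[i] <- base::rank(df$site_id[i], ties.method = "first")
    } else {
      rank[i] <- base::rank(relpos[i], ties.method = "first")
    }
  }
  nsites <- table(df$transcript_id)
  testable <- as.integer(nsites[df$transcript_id]) >= 2L
  out <- data.frame(transcript_id = df$transcript_id, site_id = df$site_id,
                    rank = rank, testable = testable,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(m, check.names = FALSE))
  attr(out, "sample_ids") <- samp
  class(out) <- c("pas_counts", "data.frame")
  out
}

#' Read codon-level RPF profiles
#'
#' Long-format TSV with columns \code{transcript_id}, \code{sample_id},
#' \code{codon_index} (0-based from the CDS start) and \code{count}.
#'
#' @param path Path to the long TSV.
#' @return A \code{codon_profiles}: named list of codon x sample count
#'   matrices, all sharing the same sample columns.
#' @export
read_codon_profiles <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("transcript_id", "sample_id", "codon_index", "count")
  if (!all(need %in% colnames(df)))
    stop("codon profile table needs columns: ", paste(need, collapse = ", "))
  if (any(df$count < 0)) stop("codon counts must be non-negative")
  samples <- sort(unique(df$sample_id))
  out <- lapply(split(df, df$transcript_id), function(d) {
    L <- max(d$codon_index) + 1L
    m <- matrix(0, nrow = L, ncol = length(samples),
                dimnames = list(NULL, samples))
    m[cbind(d$codon_index + 1L, match(d$sample_id, samples))] <- d$count
    m
  })
  codon_profiles(out)
}

#' Construct a codon profile set
#'
#' @param profiles Named list of codon x sample numeric matrices; all
#'   matrices must share identical sample columns.
#' @return A \code{codon_profiles} object.
#' @export
codon_profiles <- function(profiles) {
  if (is.null(names(profiles)) || anyDuplicated(names(profiles)))
    stop("profiles must be a uniquely named list")
  samp <- colnames(profiles[[1L]])
  ok <- vapply(profiles, function(m)
    is.matrix(m) && identical(colnames(m), samp) && all(m >= 0), logical(1L))
  if (!all(ok)) stop("all profiles must share sample columns and be non-negative")
  structure(profiles, sample_ids = samp, class = "codon_profiles")
}

#' Write a results table as TSV
#'
#' Floating-point columns are written at 6 significant digits; missing values
#' as literal \code{NA}. Column order is the table's own order.
#'
#' @param table A data.frame of results.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_results_table <- function(table, path) {
  out <- as.data.frame(table, check.names = FALSE)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6L)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
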