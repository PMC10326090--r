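# Inter-rater agreement machinery: the >= 75% consensus rule, Fleiss kappa,
# the two-way agreement single-measure ICC, and pairwise Spearman
# correlations for the CAB counts. Undefined statistics come back as NA
# sentinels carrying a reason attribute, never as silent zeros.

stat_sentinel <- function(reason) structure(NA_real_, reason = reason)

#' Reason attached to an undefined statistic
#'
#' @param x A value returned by an agreement statistic.
#' @return The reason string, or `NULL` when the statistic was defined.
#' @export
sentinel_reason <- function(x) attr(x, "reason", exact = TRUE)

#' Consensus value among raters
#'
#' Returns the modal rating iff its share among the non-missing raters
#' reaches the threshold; with 4 raters and the default 0.75 this is the
#' "at least 3 of 4 observers assign the same value" rule.
#'
#' @param ratings Vector of one rating per rater; `NA` = rater missing.
#' @param threshold Required modal share, in (0.5, 1\].
#' @return The consensus value, `NA` when no consensus, or an `NA` sentinel
#'   (with a reason, see [sentinel_reason()]) when all ratings are missing.
#' @examples
#' consensus(c(1, 1, 1, 0))   # 1
#' consensus(c(1, 1, 0, 0))   # NA
#' @export
consensus <- function(ratings, threshold = 0.75) {
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold > 0.5, threshold <= 1)
  x <- ratings[!is.na(ratings)]
  if (!length(x)) {
    warning("consensus(): all ratings missing")
    return(stat_sentinel("all ratings missing"))
  }
  tb <- table(x)
  if (max(tb) / length(x) >= threshold) {
    as.numeric(names(tb)[which.max(tb)])
  } else {
    NA_real_
  }
}

# One column per rater, one row per biopsy, for a single parameter.
#' Biopsy-by-rater matrix for one parameter
#'
#' @param ratings Ratings table.
#' @param parameter Column to extract (`cab_count` or a morphology
#'   parameter).
#' @return Numeric matrix, biopsies in rows (order of first appearance),
#'   raters in columns; missing ratings are `NA`.
#' @export
rater_matrix <- function(ratings, parameter) {
  if (!parameter %in% names(ratings)) stop("no such column: ", parameter)
  b <- factor(ratings$biopsy_id, levels = unique(ratings$biopsy_id))
  r <- factor(ratings$rater_id, levels = unique(ratings$rater_id))
  m <- matrix(NA_real_, nlevels(b), nlevels(r),
              dimnames = list(levels(b), levels(r)))
  m[cbind(as.integer(b), as.integer(r))] <- ratings[[parameter]]
  m
}

#' Percentage of biopsies reaching consensus on a parameter
#'
#' @param ratings Ratings table.
#' @param parameter Morphology parameter name.
#' @param threshold Modal share required, default 0.75.
#' @param dichotomize Collapse the 0--2 scale to absent (0) / present (1--2)
#'   before testing consensus, the convention used when reporting the
#'   semi-quantitative parameters.
#' @return Percentage in \[0, 100\] over biopsies with at least two raters.
#' @export
consensus_rate <- function(ratings, parameter, threshold = 0.75,
                           dichotomize = FALSE) {
  m <- rater_matrix(ratings, parameter)
  if (dichotomize) {
    m[] <- ifelse(m == 0, 0, 1)
  }
  eligible <- rowSums(!is.na(m)) >= 2
  if (!any(eligible)) {
    stop("no biopsy has two or more raters for ", parameter)
  }
  cons <- apply(m[eligible, , drop = FALSE], 1, consensus,
                threshold = threshold)
  100 * mean(!is.na(cons))
}

#' Subject-by-category rating-count table
#'
#' @param ratings Ratings table.
#' @param parameter Morphology parameter name.
#' @param categories Category codes; defaults to the parameter's full range.
#' @return Integer matrix, one row per biopsy, one column per category;
#'   cell = number of raters assigning that category.
#' @export
rating_counts <- function(ratings, parameter,
                          categories = 0:morphology_max_level(parameter)) {
  m <- rater_matrix(ratings, parameter)
  counts <- vapply(categories,
                   function(cc) rowSums(m == cc, na.rm = TRUE),
                   numeric(nrow(m)))
  counts <- matrix(as.integer(counts), nrow = nrow(m),
                   dimnames = list(rownames(m), as.character(categories)))
  counts
}

#' Fleiss kappa for multiple raters
#'
#' Chance-corrected agreement for a fixed number of raters assigning
#' categories: kappa = (Pbar - Pe) / (1 - Pe), with Pbar the mean over
#' subjects of sum_c n_ic (n_ic - 1) / (k (k - 1)) and Pe the sum of squared
#' category shares. Subjects rated by fewer than the modal number of raters
#' are dropped (the estimator assumes constant k); the number dropped is
#' attached as attribute `n_dropped`.
#'
#' @param counts Subject-by-category matrix of rating counts, e.g. from
#'   [rating_counts()].
#' @return Kappa in \[-1, 1\], or an `NA` sentinel when undefined (all
#'   ratings in a single category, or fewer than 2 raters / 1 subject).
#' @export
fleiss_kappa <- function(counts) {
  counts <- as.matrix(counts)
  k <- max(rowSums(counts))
  keep <- rowSums(counts) == k
  m <- counts[keep, , drop = FALSE]
  n <- nrow(m)
  if (n < 1 || k < 2) {
    return(stat_sentinel("need >= 1 subject with >= 2 raters"))
  }
  p_c <- colSums(m) / (n * k)
  P_i <- (rowSums(m^2) - k) / (k * (k - 1))
  Pe <- sum(p_c^2)
  if (1 - Pe < .Machine$double.eps^0.5) {
    return(stat_sentinel("all ratings fall in a single category"))
  }
  structure((mean(P_i) - Pe) / (1 - Pe), n_dropped = sum(!keep))
}

#' Two-way agreement single-measure intraclass correlation, ICC(A,1)
#'
#' Absolute-agreement ICC for a two-way (subject x rater) layout, single
#' unit: (MSR - MSE) / (MSR + (k - 1) MSE + (k / n)(MSC - MSE)), where MSR,
#' MSC and MSE are the subject, rater and residual mean squares of the
#' two-way ANOVA decomposition. Subjects with any missing rating are
#' dropped (listwise deletion).
#'
#' @param ratings Numeric subjects-by-raters matrix.
#' @return ICC (at most 1), or an `NA` sentinel when undefined (fewer than
#'   2 complete subjects or raters, or zero total variance).
#' @export
icc_a1 <- function(ratings) {
  x <- as.matrix(ratings)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2 || k < 2) {
    return(stat_sentinel("need >= 2 complete subjects and >= 2 raters"))
  }
  grand <- mean(x)
  ssr <- k * sum((rowMeans(x) - grand)^2)
  ssc <- n * sum((colMeans(x) - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(denom) < .Machine$double.eps^0.5 * max(1, abs(grand))) {
    return(stat_sentinel("zero total variance"))
  }
  (msr - mse) / denom
}

#' Pairwise Spearman correlations between raters
#'
#' Rank correlation (average ranks for ties) between every pair of rater
#' columns, with pairwise deletion of missing values; used for the CAB
#' counts, whose agreement is not summarised by consensus.
#'
#' @param ratings Numeric subjects-by-raters matrix, e.g. from
#'   [rater_matrix()].
#' @return Symmetric k x k matrix with unit diagonal; a cell is `NA` when a
#'   pair has fewer than 3 complete observations or a constant vector.
#' @export
pairwise_spearman <- function(ratings) {
  m <- as.matrix(ratings)
  k <- ncol(m)
  rho <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  diag(rho) <- 1
  if (k < 2) return(rho)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      if (sum(ok) < 3) next
      xi <- m[ok, i]
      xj <- m[ok, j]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
      rho[i, j] <- rho[j, i] <-
        stats::cor(xi, xj, method = "spearman")
    }
  }
  rho
}

#' Per-parameter agreement report
#'
#' Summarises inter-rater reliability per parameter: the consensus rate
#' (semi-quantitative parameters dichotomized to absent/present first, per
#' the reporting convention), Fleiss kappa on the raw ordinal codes (all
#' parameters have at most 5 levels), and ICC(A,1). The CAB count row
#' reports ICC only (consensus and kappa are not meaningful for a count).
#'
#' @param ratings Ratings table.
#' @param threshold Consensus threshold, default 0.75.
#' @param dichotomize_semiquant Dichotomize 3-level parameters before the
#'   consensus rate (default `TRUE`).
#' @return Data frame `parameter`, `n_biopsies`, `consensus_rate_pct`,
#'   `fleiss_kappa`, `icc_a1`, `kappa_n_dropped`.
#' @export
agreement_report <- function(ratings, threshold = 0.75,
                             dichotomize_semiquant = TRUE) {
  params <- morphology_parameters()
  rows <- lapply(params, function(p) {
    m <- rater_matrix(ratings, p)
    n <- sum(rowSums(!is.na(m)) >= 2)
    dich <- dichotomize_semiquant && morphology_max_level(p) > 1
    kap <- fleiss_kappa(rating_counts(ratings, p))
    data.frame(
      parameter = p,
      n_biopsies = n,
      consensus_rate_pct = consensus_rate(ratings, p, threshold,
                                          dichotomize = dich),
      fleiss_kappa = as.numeric(kap),
      icc_a1 = as.numeric(icc_a1(m)),
      kappa_n_dropped = if (is.null(attr(kap, "n_dropped"))) NA_integer_
                        else attr(kap, "n_dropped"),
      stringsAsFactors = FALSE
    )
  })
  cabm <- rater_matrix(ratings, "cab_count")
  rows[[length(rows) + 1L]] <- data.frame(
    parameter = "cab_count",
    n_biopsies = sum(rowSums(!is.na(cabm)) >= 2),
    consensus_rate_pct = NA_real_,
    fleiss_kappa = NA_real_,
    icc_a1 = as.numeric(icc_a1(cabm)),
    kappa_n_dropped = NA_integer_,
    stringsAsFactors = FALSE
  )
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
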