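# Association of histology with ordinal clinical outcomes: the none /
# low-grade / high-grade clinical grouping, Kruskal-Wallis plus pairwise
# Mann-Whitney comparisons against a reference group, chi-square
# cross-tabulation with adjusted standardized residuals, Spearman
# correlation between measures, and the CAB count cut-off sweep.

STEROID_LEVELS <- c("not_applied", "responsive", "refractory", "intolerant")
SURVIVAL_LEVELS <- c("alive", "NRM", "RM")

#' Collapse a 0--4 clinical grade into none / low / high
#'
#' Grade 0 maps to `none` (no signs of GvHD), grades 1--2 to `low`
#' (low-grade) and grades 3--4 to `high` (high-grade); used for both the
#' overall Glucksberg grade and the GvHD stage of the lower GI tract.
#'
#' @param grade Integer vector with values in 0..4 (`NA` allowed).
#' @return Factor with levels `none`, `low`, `high`.
#' @export
clinical_grouping <- function(grade) {
  bad <- !is.na(grade) & !(grade %in% 0:4)
  if (any(bad)) {
    stop("clinical grades must lie in 0..4; got ",
         paste(unique(grade[bad]), collapse = ", "))
  }
  factor(ifelse(grade == 0, "none", ifelse(grade <= 2, "low", "high")),
         levels = c("none", "low", "high"))
}

#' Significance stars at 0.05 / 0.01 / 0.001
#'
#' @param p Numeric vector of p-values.
#' @return Character vector: `***`, `**`, `*` or `""`.
#' @export
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

# Mann-Whitney wrapper: exact enumeration for small tie-free samples,
# tie-corrected normal approximation (no continuity correction) otherwise.
mann_whitney <- function(x, y) {
  exact <- length(x) <= 8 && length(y) <= 8 && !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)
  )
}

#' Compare a measure across clinical groups
#'
#' Kruskal-Wallis test across all groups plus pairwise two-sided
#' Mann-Whitney tests of every non-reference group against the reference,
#' with per-group medians and ranges. Groups with no observations are
#' excluded with a warning. Stars come from the raw p-values; a
#' Bonferroni-adjusted column (over the pairwise tests) is reported
#' alongside.
#'
#' @param values Numeric measure, one per biopsy.
#' @param groups Group labels (factor preserves level order).
#' @param reference Reference group label.
#' @return List with `kruskal` (`statistic`, `df`, `p_value`) and `groups`,
#'   a data frame `group`, `n`, `median`, `min`, `max`, `p_value`,
#'   `p_bonferroni`, `stars` (`NA` p for the reference row).
#' @export
compare_groups <- function(values, groups, reference) {
  if (!is.factor(groups)) groups <- factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- groups[ok]
  empty <- setdiff(levels(groups), as.character(unique(groups)))
  if (length(empty)) {
    warning("excluding empty group(s): ", paste(empty, collapse = ", "))
  }
  groups <- droplevels(groups)
  levs <- levels(groups)
  if (length(levs) < 2) stop("need at least two non-empty groups")
  if (!reference %in% levs) stop("reference group '", reference, "' is empty")
  kw <- stats::kruskal.test(values, groups)
  ref_vals <- values[groups == reference]
  rows <- lapply(levs, function(g) {
    v <- values[groups == g]
    p <- if (g == reference) NA_real_ else mann_whitney(v, ref_vals)$p.value
    data.frame(group = g, n = length(v), median = stats::median(v),
               min = min(v), max = max(v), p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  n_tests <- sum(!is.na(res$p_value))
  res$p_bonferroni <- pmin(1, res$p_value * n_tests)
  res$stars <- p_stars(res$p_value)
  list(
    kruskal = list(statistic = unname(kw$statistic),
                   df = unname(kw$parameter), p_value = kw$p.value),
    groups = res
  )
}

#' Chi-square cross-tabulation with adjusted standardized residuals
#'
#' Pearson chi-square test of an R x C contingency table plus per-cell
#' post-hoc testing via adjusted standardized residuals
#' z = (O - E) / sqrt(E (1 - row/N) (1 - col/N)), each converted to a
#' two-sided normal p-value, with Bonferroni adjustment across the R x C
#' cells. Empty rows or columns are dropped with a warning.
#'
#' @param table Matrix (or table) of non-negative counts.
#' @return List: `statistic`, `df`, `p_value`, `expected`, `residuals`
#'   (adjusted standardized), `p_cells`, `p_cells_bonferroni`, `table`
#'   (after margin dropping).
#' @examples
#' chi2_beasley(matrix(c(10, 0, 0, 10), 2))
#' @export
chi2_beasley <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || sum(tab) < 1) {
    stop("counts must be non-negative with a positive total")
  }
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping empty row(s)/column(s) from the contingency table")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("need at least two non-empty rows and columns")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  z <- ct$stdres
  p_cells <- 2 * stats::pnorm(-abs(z))
  list(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    expected = ct$expected,
    residuals = z,
    p_cells = p_cells,
    p_cells_bonferroni = pmin(1, p_cells * length(p_cells)),
    table = tab
  )
}

#' Spearman correlation matrix between measures
#'
#' Rank correlations with pairwise deletion between histological measures
#' (grading systems, sum scores) and ordinal clinical grades.
#'
#' @param measures Data frame of numeric columns (an id column named
#'   `biopsy_id`, if present, is ignored).
#' @return Symmetric correlation matrix with unit diagonal; `NA` for pairs
#'   with fewer than 3 complete cases or a constant measure.
#' @export
correlate_measures <- function(measures) {
  m <- as.matrix(measures[setdiff(names(measures), "biopsy_id")])
  storage.mode(m) <- "double"
  rho <- suppressWarnings(
    stats::cor(m, method = "spearman", use = "pairwise.complete.obs")
  )
  npairs <- crossprod(!is.na(m))
  rho[npairs < 3] <- NA_real_
  const <- apply(m, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && all(x == x[1])
  })
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  diag(rho) <- 1
  rho
}

# The dichotomized clinical contrasts used in the cut-off sweep. The
# steroid contrast compares "not applied" against "refractory" only, so the
# other response levels come back NA there.
clinical_dichotomies <- function(clinical) {
  list(
    glucksberg_any  = clinical$glucksberg_overall >= 1,
    glucksberg_high = clinical$glucksberg_overall >= 3,
    gi_any          = clinical$gi_stage >= 1,
    deceased        = clinical$survival != "alive",
    steroid_refractory = ifelse(
      clinical$steroid_response %in% c("not_applied", "refractory"),
      clinical$steroid_response == "refractory", NA
    )
  )
}

#' Sweep CAB count cut-offs against dichotomized clinical outcomes
#'
#' For each cut-off c, biopsies are split into mean CAB < c versus >= c and
#' cross-tabulated against each dichotomized clinical outcome (any GvHD by
#' Glucksberg grade, high-grade Glucksberg, any lower-GI stage, death, and
#' steroid refractoriness among treated-or-untreated cases), with
#' [chi2_beasley()] results per table. Cut-offs for which one side of the
#' split (or the outcome) is empty are flagged as skipped.
#'
#' @param data Data frame with `mean_cab` plus the clinical columns
#'   `glucksberg_overall`, `gi_stage`, `steroid_response`, `survival`.
#' @param cutoffs Strictly positive, sorted cut-off values.
#' @return Data frame, one row per (cutoff, outcome): `cutoff`, `outcome`,
#'   `n_below`, `n_at_or_above`, `chi2`, `df`, `p_value`, `p_min_cell`,
#'   `skipped`. The 2 x 2 tables are attached as attribute `tables`.
#' @export
cab_cutoff_sweep <- function(data, cutoffs = c(0.5, 1, 2, 3, 5, 6, 7)) {
  if (any(cutoffs <= 0)) stop("cutoffs must be strictly positive")
  if (is.unsorted(cutoffs, strictly = TRUE)) {
    stop("cutoffs must be sorted and distinct")
  }
  outcomes <- clinical_dichotomies(data)
  rows <- list()
  tables <- list()
  for (cc in cutoffs) {
    for (oc in names(outcomes)) {
      y <- outcomes[[oc]]
      ok <- !is.na(data$mean_cab) & !is.na(y)
      below <- data$mean_cab[ok] < cc
      yy <- y[ok]
      row <- data.frame(cutoff = cc, outcome = oc,
                        n_below = sum(below), n_at_or_above = sum(!below),
                        chi2 = NA_real_, df = NA_real_, p_value = NA_real_,
                        p_min_cell = NA_real_, skipped = TRUE,
                        stringsAsFactors = FALSE)
      if (length(unique(below)) == 2 && length(unique(yy)) == 2) {
        tab <- table(
          cab = factor(below, c(TRUE, FALSE),
                       labels = c("below_cutoff", "at_or_above")),
          outcome = factor(yy, c(FALSE, TRUE), labels = c("no", "yes"))
        )
        res <- chi2_beasley(tab)
        row$chi2 <- res$statistic
        row$df <- res$df
        row$p_value <- res$p_value
        row$p_min_cell <- min(res$p_cells_bonferroni)
        row$skipped <- FALSE
        tables[[paste(cc, oc, sep = "|")]] <- tab
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(res, tables = tables)
}

#' Table-2-style association report
#'
#' Relates each histological measure to each clinical axis: overall
#' Glucksberg grade and lower-GI GvHD stage (grouped none / low-grade /
#' high-grade, reference `none`), steroid response (reference
#' `not_applied`; `intolerant` cases are excluded from the summary), and
#' survival (reference `alive`). Emits per-group medians and ranges with
#' Kruskal-Wallis and reference-pairwise Mann-Whitney results.
#'
#' @param measures Data frame keyed by `biopsy_id` whose remaining numeric
#'   columns are the measures (panel means, mean grades, sum scores).
#' @param clinical Clinical table (see [read_clinical()]).
#' @return Data frame, one row per measure x axis x group: `measure`,
#'   `axis`, `group`, `n`, `median`, `min`, `max`, `kruskal_p`, `p_value`,
#'   `p_bonferroni`, `stars`.
#' @export
association_report <- function(measures, clinical) {
  merged <- merge(measures, clinical, by = "biopsy_id")
  if (!nrow(merged)) stop("no biopsy ids shared between measures and clinical")
  steroid <- factor(merged$steroid_response,
                    levels = c("not_applied", "responsive", "refractory"))
  axes <- list(
    glucksberg = list(groups = clinical_grouping(merged$glucksberg_overall),
                      reference = "none"),
    gi_stage = list(groups = clinical_grouping(merged$gi_stage),
                    reference = "none"),
    steroid_response = list(groups = steroid, reference = "not_applied"),
    survival = list(groups = factor(merged$survival, SURVIVAL_LEVELS),
                    reference = "alive")
  )
  measure_cols <- setdiff(names(measures), "biopsy_id")
  rows <- list()
  for (mc in measure_cols) {
    for (ax in names(axes)) {
      cg <- tryCatch(
        compare_groups(merged[[mc]], axes[[ax]]$groups, axes[[ax]]$reference),
        error = function(e) NULL
      )
      if (is.null(cg)) next
      g <- cg$groups
      g$measure <- mc
      g$axis <- ax
      g$kruskal_p <- cg$kruskal$p_value
      rows[[length(rows) + 1L]] <- g
    }
  }
  res <- do.call(rbind, rows)
  res <- res[, c("measure", "axis", "group", "n", "median", "min", "max",
                 "kruskal_p", "p_value", "p_bonferroni", "stars")]
  rownames(res) <- NULL
  res
}
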