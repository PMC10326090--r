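# Ordinal morphology parameters and their maximum codes. Crypt destruction
# and crypt loss are semi-quantitative (0 = none, 1 = individual
# non-contiguous crypts, 2 = >= 2 neighbouring crypts); the remaining four
# are absent/present indicators (granulocyte increase uses the
# >= 5 cells per high-power-field rule).
MORPH_LEVELS <- c(
  crypt_destruction        = 2L,
  crypt_loss               = 2L,
  epithelial_denudation    = 1L,
  architectural_distortion = 1L,
  eosinophils_increased    = 1L,
  neutrophils_increased    = 1L
)

RATINGS_COLUMNS <- c("biopsy_id", "rater_id", "cab_count", names(MORPH_LEVELS))

#' Ordinal morphology parameters
#'
#' Names of the six ordinal morphology parameters scored per rater, in the
#' canonical column order. Crypt destruction and crypt loss run 0--2, the
#' other four are binary 0/1.
#'
#' @return Character vector of parameter names.
#' @export
morphology_parameters <- function() names(MORPH_LEVELS)

#' Maximum ordinal code of a morphology parameter
#'
#' @param parameter One of [morphology_parameters()].
#' @return Integer maximum (1 or 2); the minimum is always 0.
#' @export
morphology_max_level <- function(parameter) {
  if (!parameter %in% names(MORPH_LEVELS)) {
    stop("unknown morphology parameter: ", parameter)
  }
  MORPH_LEVELS[[parameter]]
}

#' Validate one rater assessment
#'
#' Checks a single observer's readout of one biopsy against the scale
#' definitions: the crypt apoptotic body (CAB) count must be a non-negative
#' real (counts per 10 contiguous crypts in the hot-spot) and each ordinal
#' parameter, when present, must lie in its coded range. Missing fields are
#' allowed and are not violations.
#'
#' @param a A list or one-row data frame with (a subset of) the fields
#'   `cab_count` and the [morphology_parameters()].
#' @return Character vector of violation messages; empty when valid. The
#'   input is never modified.
#' @examples
#' validate_assessment(list(cab_count = 3, crypt_loss = 1))  # character(0)
#' validate_assessment(list(crypt_destruction = 3))
#' @export
validate_assessment <- function(a) {
  violations <- character(0)
  cab <- a[["cab_count"]]
  if (!is.null(cab) && length(cab) == 1 && !is.na(cab)) {
    if (!is.numeric(cab) || cab < 0) {
      violations <- c(violations, "cab_count: must be a non-negative number")
    }
  }
  for (p in names(MORPH_LEVELS)) {
    x <- a[[p]]
    if (is.null(x) || length(x) != 1 || is.na(x)) next
    if (!is.numeric(x) || !(x %in% 0:MORPH_LEVELS[[p]])) {
      violations <- c(violations, sprintf(
        "%s: value %s outside the coded range 0..%d",
        p, format(x), MORPH_LEVELS[[p]]
      ))
    }
  }
  violations
}

#' Validate a ratings table
#'
#' Applies [validate_assessment()] row-wise and additionally flags duplicate
#' (biopsy, rater) pairs.
#'
#' @param ratings Data frame in the ratings layout (see [read_ratings()]).
#' @return Data frame with columns `row`, `message`; zero rows when clean.
#' @export
validate_ratings <- function(ratings) {
  out <- list()
  for (i in seq_len(nrow(ratings))) {
    v <- validate_assessment(as.list(ratings[i, , drop = FALSE]))
    if (length(v)) out[[length(out) + 1L]] <- data.frame(row = i, message = v)
  }
  key <- paste(ratings$biopsy_id, ratings$rater_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    out[[length(out) + 1L]] <- data.frame(
      row = dup, message = "duplicate (biopsy_id, rater_id) pair"
    )
  }
  if (!length(out)) {
    return(data.frame(row = integer(0), message = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$row), , drop = FALSE]
}

#' Bin a mean CAB count into the 4-level CAB score
#'
#' The CAB score bins the mean crypt-apoptotic-body count per 10 contiguous
#' crypts: 0 for counts below 1 ("no"), 1 for 1 to below 5, 2 for 5 to below
#' 10, 3 for 10 or more. Means over several observers may be fractional;
#' values below one apoptotic body per 10 crypts are treated as "no".
#'
#' @param mean_cab Non-negative numeric vector; `NA` passes through.
#' @return Integer vector of scores in 0..3, monotone in `mean_cab`.
#' @examples
#' cab_score(c(0, 0.5, 1, 4.9, 5, 9.9, 10, 12.5))
#' @export
cab_score <- function(mean_cab) {
  if (!is.numeric(mean_cab)) stop("mean_cab must be numeric")
  if (any(mean_cab < 0, na.rm = TRUE)) stop("mean_cab must be non-negative")
  out <- findInterval(mean_cab, c(1, 5, 10))
  out[is.na(mean_cab)] <- NA_integer_
  as.integer(out)
}

#' Per-biopsy panel means across raters
#'
#' Aggregates a ratings table to one row per biopsy: the arithmetic mean of
#' the CAB count and of each ordinal parameter over the raters that scored
#' it (missing ratings are excluded field-wise), the CAB score bin derived
#' from the mean CAB count, and the number of contributing raters per field.
#'
#' @param ratings Data frame in the ratings layout with at least one row.
#' @return Data frame with one row per biopsy: `biopsy_id`, `n_raters`,
#'   `mean_cab`, `mean_<parameter>` for each morphology parameter,
#'   `cab_score`, and `n_cab` / `n_<parameter>` rater counts. Biopsies keep
#'   their order of first appearance.
#' @examples
#' r <- data.frame(biopsy_id = "b1", rater_id = 1:4,
#'                 cab_count = c(4, 6, 8, 10), crypt_destruction = 0,
#'                 crypt_loss = c(1, 2, NA, 1), epithelial_denudation = 0,
#'                 architectural_distortion = 0, eosinophils_increased = 0,
#'                 neutrophils_increased = 0)
#' panel_means(r)[, c("mean_cab", "cab_score", "mean_crypt_loss")]
#' @export
panel_means <- function(ratings) {
  if (is.null(ratings) || nrow(ratings) < 1) {
    stop("panel_means() requires at least one assessment")
  }
  fields <- c("cab_count", names(MORPH_LEVELS))
  short <- c(cab_count = "cab", stats::setNames(names(MORPH_LEVELS),
                                                names(MORPH_LEVELS)))
  groups <- split(
    ratings,
    factor(ratings$biopsy_id, levels = unique(ratings$biopsy_id))
  )
  rows <- lapply(groups, function(d) {
    means <- vapply(fields, function(f) {
      x <- d[[f]]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, numeric(1))
    ns <- vapply(fields, function(f) sum(!is.na(d[[f]])), integer(1))
    out <- data.frame(biopsy_id = d$biopsy_id[1], n_raters = nrow(d),
                      stringsAsFactors = FALSE)
    out[paste0("mean_", short[fields])] <- as.list(unname(means))
    out$cab_score <- cab_score(means[["cab_count"]])
    out[paste0("n_", short[fields])] <- as.list(unname(ns))
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Dichotomize a semi-quantitative score into absent/present
#'
#' Grade 0 is rated as absent and grades 1--2 as present; used when
#' summarising consensus on the semi-quantitative parameters.
#'
#' @param value Numeric vector with values in 0, 1, 2 (`NA` allowed).
#' @return Factor with levels `absent`, `present`.
#' @export
dichotomize <- function(value) {
  bad <- !is.na(value) & !(value %in% 0:2)
  if (any(bad)) {
    stop("dichotomize() expects ordinal scores in 0..2; got ",
         paste(unique(value[bad]), collapse = ", "))
  }
  factor(ifelse(value == 0, "absent", "present"),
         levels = c("absent", "present"))
}
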