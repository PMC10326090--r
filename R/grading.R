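# The four grading systems below are deliberately functions of morphology
# alone (no clinical input). Each rule is written as "take the highest grade
# whose trigger fires", which makes monotonicity in every component
# immediate. An NA in any consumed component propagates to an NA grade.

.recycle_grade_args <- function(...) {
  args <- list(...)
  n <- max(vapply(args, length, integer(1)))
  lapply(args, rep_len, n)
}

#' Adapted Lerner grade
#'
#' Four-tier histological GvHD grade driven by apoptosis and destructive
#' crypt change: 0 no findings; 1 crypt apoptotic bodies (CAB) only;
#' 2 crypt destruction; 3 focal crypt loss (< 50% of the mucosa involved);
#' 4 diffuse crypt loss (>= 50%) or epithelial denudation.
#'
#' When no extent fraction is supplied, crypt loss score 1 (individual
#' crypts) is treated as focal and score 2 (>= 2 neighbouring crypts) as
#' diffuse. When `crypt_loss_extent` is given, loss is diffuse iff the
#' involved fraction is >= 0.5.
#'
#' @param cab_count CAB count per 10 contiguous crypts (non-negative).
#' @param crypt_destruction,crypt_loss Ordinal 0--2.
#' @param epithelial_denudation Binary 0/1.
#' @param crypt_loss_extent Optional fraction of mucosa with crypt loss,
#'   in \[0, 1\].
#' @return Integer grades in 0..4; non-decreasing in every component.
#' @examples
#' lerner_grade(6, 0, 0, 0)              # 1: apoptosis only
#' lerner_grade(6, 0, 2, 0, 0.6)         # 4: diffuse loss
#' @export
lerner_grade <- function(cab_count, crypt_destruction, crypt_loss,
                         epithelial_denudation, crypt_loss_extent = NULL) {
  if (!is.null(crypt_loss_extent) &&
      any(crypt_loss_extent < 0 | crypt_loss_extent > 1, na.rm = TRUE)) {
    stop("crypt_loss_extent must lie in [0, 1]")
  }
  a <- .recycle_grade_args(cab = cab_count, de = crypt_destruction,
                           lo = crypt_loss, den = epithelial_denudation)
  g <- ifelse(a$cab > 0, 1L, 0L)
  g <- pmax(g, ifelse(a$de >= 1, 2L, 0L))
  if (is.null(crypt_loss_extent)) {
    diffuse <- a$lo == 2
  } else {
    ext <- rep_len(crypt_loss_extent, length(a$lo))
    diffuse <- a$lo >= 1 & ext >= 0.5
  }
  focal <- a$lo >= 1 & !diffuse
  g <- pmax(g, ifelse(focal, 3L, 0L), ifelse(diffuse, 4L, 0L))
  g <- pmax(g, ifelse(a$den >= 1, 4L, 0L))
  as.integer(g)
}

#' Adapted Sale grade
#'
#' 0 no findings; 1 CAB only; 2 destruction or loss of individual crypts
#' (score 1); 3 contiguous (>= 2 neighbouring crypts) destruction or loss
#' (score 2); 4 epithelial denudation. Crypt loss and crypt destruction
#' both feed grades 2 and 3.
#'
#' @inheritParams lerner_grade
#' @return Integer grades in 0..4; non-decreasing in every component.
#' @export
sale_grade <- function(cab_count, crypt_destruction, crypt_loss,
                       epithelial_denudation) {
  a <- .recycle_grade_args(cab = cab_count, de = crypt_destruction,
                           lo = crypt_loss, den = epithelial_denudation)
  g <- ifelse(a$cab > 0, 1L, 0L)
  g <- pmax(g, ifelse(a$de >= 1 | a$lo >= 1, 2L, 0L))
  g <- pmax(g, ifelse(a$de >= 2 | a$lo >= 2, 3L, 0L))
  g <- pmax(g, ifelse(a$den >= 1, 4L, 0L))
  as.integer(g)
}

#' Adapted Melson grade
#'
#' Shares the adapted rule skeleton of [sale_grade()] (crypt loss and crypt
#' destruction for grades 2 and 3); the two systems differ in their
#' descriptive labels, not in the numeric mapping used here.
#'
#' @inheritParams lerner_grade
#' @return Integer grades in 0..4; non-decreasing in every component.
#' @export
melson_grade <- function(cab_count, crypt_destruction, crypt_loss,
                         epithelial_denudation) {
  sale_grade(cab_count, crypt_destruction, crypt_loss, epithelial_denudation)
}

#' NIH histology category
#'
#' Simplified classification based on histology alone: 0 = no GvHD (no CAB,
#' no destructive change), 1 = possible (sparse apoptosis, below the CAB
#' score bin 2, without destructive change), 2 = likely (CAB score >= 2 or
#' any crypt destruction, crypt loss or denudation).
#'
#' @inheritParams lerner_grade
#' @return Integer categories 0 (no), 1 (possible), 2 (likely).
#' @export
nih_category <- function(cab_count, crypt_destruction, crypt_loss,
                         epithelial_denudation) {
  a <- .recycle_grade_args(cab = cab_count, de = crypt_destruction,
                           lo = crypt_loss, den = epithelial_denudation)
  bin <- cab_score(a$cab)
  g <- ifelse(a$cab > 0, 1L, 0L)
  g <- pmax(g, ifelse(bin >= 2 | a$de >= 1 | a$lo >= 1 | a$den >= 1, 2L, 0L))
  as.integer(g)
}

#' Grade every assessment in a ratings table
#'
#' Applies all four grading systems per (biopsy, rater) row.
#'
#' @param ratings Data frame in the ratings layout (see [read_ratings()]).
#' @param crypt_loss_extent Optional per-row extent fraction for the Lerner
#'   focal/diffuse split.
#' @return Data frame `biopsy_id`, `rater_id`, `lerner`, `sale`, `melson`,
#'   `nih`.
#' @export
grade_assessments <- function(ratings, crypt_loss_extent = NULL) {
  data.frame(
    biopsy_id = ratings$biopsy_id,
    rater_id = ratings$rater_id,
    lerner = lerner_grade(ratings$cab_count, ratings$crypt_destruction,
                          ratings$crypt_loss, ratings$epithelial_denudation,
                          crypt_loss_extent),
    sale = sale_grade(ratings$cab_count, ratings$crypt_destruction,
                      ratings$crypt_loss, ratings$epithelial_denudation),
    melson = melson_grade(ratings$cab_count, ratings$crypt_destruction,
                          ratings$crypt_loss, ratings$epithelial_denudation),
    nih = nih_category(ratings$cab_count, ratings$crypt_destruction,
                       ratings$crypt_loss, ratings$epithelial_denudation),
    stringsAsFactors = FALSE
  )
}

#' Mean grade per biopsy across raters
#'
#' Averages the per-rater grades of [grade_assessments()] over the observers
#' of each biopsy (missing grades excluded), the form in which grading
#' systems are related to clinical findings.
#'
#' @param grades Output of [grade_assessments()].
#' @return Data frame `biopsy_id`, `lerner`, `sale`, `melson`, `nih` of mean
#'   grades.
#' @export
panel_grades <- function(grades) {
  groups <- split(grades,
                  factor(grades$biopsy_id, levels = unique(grades$biopsy_id)))
  rows <- lapply(groups, function(d) {
    data.frame(
      biopsy_id = d$biopsy_id[1],
      lerner = mean(d$lerner, na.rm = TRUE),
      sale = mean(d$sale, na.rm = TRUE),
      melson = mean(d$melson, na.rm = TRUE),
      nih = mean(d$nih, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  for (col in c("lerner", "sale", "melson", "nih")) {
    res[[col]][is.nan(res[[col]])] <- NA_real_
  }
  rownames(res) <- NULL
  res
}

#' Additive severity sum score
#'
#' Sum score 1 adds the CAB score bin (from the panel mean CAB count) and
#' the mean crypt loss score; sum score 2 additionally adds the mean crypt
#' destruction and epithelial denudation scores; sum score 3 further adds
#' the mean architectural distortion and the mean eosinophil and neutrophil
#' increase scores. Attainable ranges are 0--5, 0--8 and 0--11.
#'
#' @param panel Data frame from [panel_means()].
#' @param variant 1, 2 or 3.
#' @return Numeric vector of scores, one per panel row.
#' @examples
#' r <- data.frame(biopsy_id = "b", rater_id = 1:2, cab_count = 6,
#'                 crypt_destruction = 1, crypt_loss = c(0, 1),
#'                 epithelial_denudation = c(0, 1),
#'                 architectural_distortion = 0, eosinophils_increased = 0,
#'                 neutrophils_increased = 0)
#' sum_score(panel_means(r), 2)
#' @export
sum_score <- function(panel, variant) {
  if (!length(variant) == 1 || !variant %in% 1:3) {
    stop("variant must be 1, 2 or 3")
  }
  s <- panel$cab_score + panel$mean_crypt_loss
  if (variant >= 2) {
    s <- s + panel$mean_crypt_destruction + panel$mean_epithelial_denudation
  }
  if (variant == 3) {
    s <- s + panel$mean_architectural_distortion +
      panel$mean_eosinophils_increased + panel$mean_neutrophils_increased
  }
  s
}

#' All three sum scores per biopsy
#'
#' @param panel Data frame from [panel_means()].
#' @return Data frame `biopsy_id`, `s1`, `s2`, `s3`.
#' @export
sum_scores <- function(panel) {
  data.frame(
    biopsy_id = panel$biopsy_id,
    s1 = sum_score(panel, 1),
    s2 = sum_score(panel, 2),
    s3 = sum_score(panel, 3),
    stringsAsFactors = FALSE
  )
}
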