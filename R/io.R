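# CSV input/output and the end-to-end pipeline. Dialect: comma-separated,
# UTF-8, "." decimal, empty cell = missing. Range-violating cells are set
# to NA and collected into a line-numbered problem report rather than
# aborting the read; a wrong header is a hard failure.

CLINICAL_COLUMNS <- c("biopsy_id", "glucksberg_overall", "gi_stage",
                      "steroid_response", "survival",
                      "days_post_transplant")

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("", "NA"), fileEncoding = "UTF-8")
}

.require_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
}

# Coerce a column to numeric, recording unparseable cells (1-based data
# line numbers, header = line 1).
.coerce_numeric <- function(df, col, problems) {
  raw <- df[[col]]
  num <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & is.na(num))
  if (length(bad)) {
    problems[[length(problems) + 1L]] <- data.frame(
      line = bad + 1L, field = col,
      message = paste0("not a number: ", raw[bad]),
      stringsAsFactors = FALSE
    )
  }
  list(values = num, problems = problems)
}

.finish_problems <- function(problems) {
  if (!length(problems)) {
    return(data.frame(line = integer(0), field = character(0),
                      message = character(0)))
  }
  res <- do.call(rbind, problems)
  res[order(res$line), , drop = FALSE]
}

#' Read a ratings CSV
#'
#' Expects the columns `biopsy_id,rater_id,cab_count` plus the six
#' morphology parameters; a missing column is a hard failure. Cells that
#' are not numbers or violate a scale range are set to `NA` and reported,
#' with their line numbers, in the attribute `problems`.
#'
#' @param path Path to the CSV file.
#' @return Data frame of typed assessments with attribute `problems` (a
#'   data frame `line`, `field`, `message`).
#' @export
read_ratings <- function(path) {
  df <- .read_csv(path)
  .require_columns(df, RATINGS_COLUMNS, path)
  df <- df[RATINGS_COLUMNS]
  df$biopsy_id <- as.character(df$biopsy_id)
  df$rater_id <- as.character(df$rater_id)
  problems <- list()
  for (col in c("cab_count", morphology_parameters())) {
    co <- .coerce_numeric(df, col, problems)
    df[[col]] <- co$values
    problems <- co$problems
    if (col == "cab_count") {
      bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
      msg <- "negative CAB count"
    } else {
      bad <- which(!is.na(df[[col]]) &
                     !(df[[col]] %in% 0:morphology_max_level(col)))
      msg <- paste0("outside the coded range 0..",
                    morphology_max_level(col))
    }
    if (length(bad)) {
      problems[[length(problems) + 1L]] <- data.frame(
        line = bad + 1L, field = col, message = msg,
        stringsAsFactors = FALSE
      )
      df[[col]][bad] <- NA
    }
  }
  structure(df, problems = .finish_problems(problems))
}

#' Read a clinical CSV
#'
#' Expects `biopsy_id,glucksberg_overall,gi_stage,steroid_response,`
#' `survival,days_post_transplant`. Ordinal grades outside 0..4 and unknown
#' category labels are set to `NA` and reported in attribute `problems`.
#'
#' @param path Path to the CSV file.
#' @return Typed clinical data frame with attribute `problems`.
#' @export
read_clinical <- function(path) {
  df <- .read_csv(path)
  .require_columns(df, CLINICAL_COLUMNS, path)
  df <- df[CLINICAL_COLUMNS]
  df$biopsy_id <- as.character(df$biopsy_id)
  problems <- list()
  for (col in c("glucksberg_overall", "gi_stage", "days_post_transplant")) {
    co <- .coerce_numeric(df, col, problems)
    df[[col]] <- co$values
    problems <- co$problems
  }
  for (col in c("glucksberg_overall", "gi_stage")) {
    bad <- which(!is.na(df[[col]]) & !(df[[col]] %in% 0:4))
    if (length(bad)) {
      problems[[length(problems) + 1L]] <- data.frame(
        line = bad + 1L, field = col, message = "grade outside 0..4",
        stringsAsFactors = FALSE
      )
      df[[col]][bad] <- NA
    }
  }
  for (spec in list(list(col = "steroid_response", levels = STEROID_LEVELS),
                    list(col = "survival", levels = SURVIVAL_LEVELS))) {
    bad <- which(!is.na(df[[spec$col]]) & !(df[[spec$col]] %in% spec$levels))
    if (length(bad)) {
      problems[[length(problems) + 1L]] <- data.frame(
        line = bad + 1L, field = spec$col,
        message = paste0("unknown level: ", df[[spec$col]][bad]),
        stringsAsFactors = FALSE
      )
      df[[spec$col]][bad] <- NA
    }
  }
  structure(df, problems = .finish_problems(problems))
}

#' Write a synthetic cohort to CSV files
#'
#' Emits `ratings.csv`, `clinical.csv` and `truth.csv` into a directory.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("ratings.csv", "clinical.csv", "truth.csv"))
  utils::write.csv(cohort$ratings, paths[1], row.names = FALSE, na = "")
  utils::write.csv(cohort$clinical, paths[2], row.names = FALSE, na = "")
  utils::write.csv(cohort$truth, paths[3], row.names = FALSE, na = "")
  invisible(paths)
}

#' Pipeline configuration
#'
#' @param ratings Path to the ratings CSV (required).
#' @param clinical Optional path to the clinical CSV; when absent the
#'   association stages are skipped.
#' @param out_dir Output directory for the report CSVs.
#' @param consensus_threshold Modal share required for consensus, in
#'   (0.5, 1\].
#' @param cutoffs CAB cut-off list for the sweep (positive, sorted).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(ratings, clinical = NULL, out_dir,
                            consensus_threshold = 0.75,
                            cutoffs = c(0.5, 1, 2, 3, 5, 6, 7)) {
  stopifnot(consensus_threshold > 0.5, consensus_threshold <= 1,
            all(cutoffs > 0), !is.unsorted(cutoffs, strictly = TRUE))
  structure(list(ratings = ratings, clinical = clinical, out_dir = out_dir,
                 consensus_threshold = consensus_threshold,
                 cutoffs = cutoffs),
            class = "pipeline_config")
}

#' Run the full scoring pipeline
#'
#' Reads the ratings (and, when given, clinical) tables, computes per-rater
#' grades, panel means, sum scores, the agreement report and the pairwise
#' Spearman matrix for CAB counts, and — when clinical data are present —
#' the association report and the CAB cut-off sweep. All reports are
#' written as CSV into the output directory; inputs are never modified.
#' Ratings biopsies absent from the clinical table are excluded from the
#' association stages with a logged message.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every computed report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  ratings <- read_ratings(config$ratings)
  problems <- attr(ratings, "problems")
  if (nrow(problems)) {
    message("ratings: ", nrow(problems), " cell-level problem(s) recorded")
    utils::write.csv(problems, file.path(out, "ratings_problems.csv"),
                     row.names = FALSE)
  }
  message("ratings: ", length(unique(ratings$biopsy_id)), " biopsies, ",
          length(unique(ratings$rater_id)), " raters")

  grades <- grade_assessments(ratings)
  panel <- panel_means(ratings)
  scores <- sum_scores(panel)
  agreement <- agreement_report(ratings, config$consensus_threshold)
  spearman_cab <- pairwise_spearman(rater_matrix(ratings, "cab_count"))

  utils::write.csv(grades, file.path(out, "grades.csv"),
                   row.names = FALSE, na = "")
  scores_out <- scores
  for (col in c("s1", "s2", "s3")) {
    scores_out[[col]] <- round(scores_out[[col]], 4)
  }
  utils::write.csv(scores_out, file.path(out, "sum_scores.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(agreement, file.path(out, "agreement.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(data.frame(rater_id = rownames(spearman_cab),
                              spearman_cab, check.names = FALSE),
                   file.path(out, "spearman_cab.csv"), row.names = FALSE,
                   na = "")

  result <- list(ratings = ratings, grades = grades, panel = panel,
                 sum_scores = scores, agreement = agreement,
                 spearman_cab = spearman_cab)

  if (is.null(config$clinical)) {
    message("no clinical table given; association stages skipped")
    return(invisible(result))
  }

  clinical <- read_clinical(config$clinical)
  unmatched <- setdiff(panel$biopsy_id, clinical$biopsy_id)
  if (length(unmatched)) {
    warning(length(unmatched),
            " biopsy id(s) missing from the clinical table were excluded",
            " from the association stages")
  }
  measures <- merge(
    panel[, c("biopsy_id", "mean_cab", "mean_crypt_destruction",
              "mean_crypt_loss", "mean_epithelial_denudation")],
    merge(panel_grades(grades), scores, by = "biopsy_id"),
    by = "biopsy_id"
  )
  association <- association_report(measures, clinical)
  sweep_data <- merge(panel[, c("biopsy_id", "mean_cab")], clinical,
                      by = "biopsy_id")
  cutoff_sweep <- cab_cutoff_sweep(sweep_data, config$cutoffs)
  for (ax in unique(association$axis)) {
    message("association axis ", ax, ": n = ",
            sum(association$n[association$axis == ax &
                                association$measure ==
                                association$measure[1]]))
  }
  utils::write.csv(association, file.path(out, "association.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(as.data.frame(cutoff_sweep),
                   file.path(out, "cutoff_sweep.csv"),
                   row.names = FALSE, na = "")

  result$clinical <- clinical
  result$association <- association
  result$cutoff_sweep <- cutoff_sweep
  invisible(result)
}
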