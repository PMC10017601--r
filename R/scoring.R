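#' Composite FCD score from the two wall scores
#'
#' The tympanic facial canal is scored on ultra-high-resolution CT by the
#' appearance of its lateral and inferior walls. Each wall receives an
#' ordinal score: 0 = no evident bony covering, 1 = discontinuous bony
#' covering with linear deficiency, 2 = discontinuous bony covering with
#' dotted deficiency, 3 = continuous bony covering. The composite FCD
#' score is their sum, ranging 0 (both walls bare) to 6 (both walls with
#' continuous covering); low scores indicate dehiscence.
#'
#' @param L integer vector of lateral-wall scores in 0..3.
#' @param I integer vector of inferior-wall scores in 0..3 (recycled
#'   against `L` only when lengths match).
#' @return integer vector of composite scores in 0..6.
#' @examples
#' fcd_score(3, 3)  # 6, the maximum
#' fcd_score(1, 2)  # 3, classified dehiscent at the default cutoff
#' @seealso [classify_fcd()], [dehiscent_combinations()]
#' @export
fcd_score <- function(L, I) {
  L <- check_wall_score(L, "L")
  I <- check_wall_score(I, "I")
  if (length(L) != length(I)) fcd_stop("'L' and 'I' must have equal length")
  L + I
}

#' Classify an ear from its composite FCD score
#'
#' An ear is called dehiscent on imaging when its composite score falls
#' strictly below the cutoff (`score < cutoff`); the study's optimal
#' operating point is the strict cutoff 4, i.e. scores 0-3 are read as
#' dehiscent and 4-6 as intact.
#'
#' @param score integer vector of composite scores in 0..6.
#' @param cutoff single integer in 0..7; `cutoff = 0` classifies nothing
#'   as dehiscent, `cutoff = 7` everything.
#' @return factor with levels `c("dehiscent", "intact")`.
#' @export
classify_fcd <- function(score, cutoff = 4L) {
  if (anyNA(score) || !is.numeric(score) || any(score != as.integer(score)) ||
      any(score < 0L) || any(score > 6L)) {
    fcd_stop("'score' must contain integer composite scores in 0..6")
  }
  cutoff <- check_cutoff(cutoff)
  factor(ifelse(score < cutoff, "dehiscent", "intact"),
         levels = c("dehiscent", "intact"))
}

#' Wall-score combinations classified dehiscent at a cutoff
#'
#' Enumerates every pair of lateral and inferior wall scores whose sum
#' falls strictly below the cutoff. At the study cutoff of 4 this yields
#' the 10 imaging patterns highly indicative of dehiscence.
#'
#' @param cutoff single integer in 0..7.
#' @return data.frame with columns `L`, `I`, `total`, ordered by `total`
#'   then `L`.
#' @examples
#' nrow(dehiscent_combinations(4))  # 10
#' @export
dehiscent_combinations <- function(cutoff = 4L) {
  cutoff <- check_cutoff(cutoff)
  grid <- expand.grid(L = 0:3, I = 0:3)
  grid$total <- grid$L + grid$I
  keep <- grid[grid$total < cutoff, , drop = FALSE]
  keep <- keep[order(keep$total, keep$L), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Merge two observers' wall scores into a consensus score
#'
#' When the two independent reads agree, the consensus is the shared
#' value; when they disagree, the jointly adjudicated re-read value must
#' be supplied (the study re-evaluated discrepant cases to consensus).
#'
#' @param obs1,obs2 integer vectors of wall scores in 0..3.
#' @param adjudicated integer vector of adjudicated scores, `NA` where the
#'   observers agree (or everywhere, if no ear is discrepant).
#' @return integer vector of consensus wall scores.
#' @export
consensus_merge <- function(obs1, obs2, adjudicated = NA_integer_) {
  obs1 <- check_wall_score(obs1, "obs1")
  obs2 <- check_wall_score(obs2, "obs2")
  if (length(obs1) != length(obs2)) {
    fcd_stop("'obs1' and 'obs2' must have equal length")
  }
  adjudicated <- rep_len(as.integer(adjudicated), length(obs1))
  discrepant <- obs1 != obs2
  if (any(discrepant & is.na(adjudicated))) {
    fcd_stop("missing consensus: observers disagree at position(s) ",
             paste(which(discrepant & is.na(adjudicated)), collapse = ", "),
             " and no adjudicated score was supplied")
  }
  bad <- !is.na(adjudicated) & (adjudicated < 0L | adjudicated > 3L)
  if (any(bad)) fcd_stop("'adjudicated' must contain scores in {0, 1, 2, 3}")
  ifelse(discrepant, adjudicated, obs1)
}

# ---- cohort I/O -----------------------------------------------------------

ratings_cols <- c("ear_id", "laterality", "observer",
                  "lateral_score", "inferior_score")

#' Read a long-format ratings CSV
#'
#' One row per ear per observer; columns `ear_id`, `laterality`
#' (left/right), `observer` (1, 2 or "consensus"), `lateral_score`,
#' `inferior_score`. UTF-8, header required.
#'
#' @param path path to the CSV file.
#' @return data.frame with validated columns.
#' @export
read_ratings_csv <- function(path) {
  if (!file.exists(path)) fcd_stop("ratings file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(ratings_cols, names(df))
  if (length(missing)) {
    fcd_stop("ratings CSV lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) fcd_stop("ratings CSV has no data rows")
  df$observer <- as.character(df$observer)
  bad_obs <- !df$observer %in% c("1", "2", "consensus")
  if (any(bad_obs)) {
    fcd_stop("ratings CSV line(s) ", paste(which(bad_obs) + 1L, collapse = ", "),
             ": observer must be 1, 2 or 'consensus'")
  }
  for (col in c("lateral_score", "inferior_score")) {
    v <- df[[col]]
    bad <- is.na(v) | !is.numeric(v) | v != floor(v) | v < 0 | v > 3
    if (any(bad)) {
      fcd_stop("ratings CSV line(s) ", paste(which(bad) + 1L, collapse = ", "),
               ": ", col, " must be an integer in 0..3")
    }
    df[[col]] <- as.integer(v)
  }
  bad_lat <- !df$laterality %in% c("left", "right")
  if (any(bad_lat)) {
    fcd_stop("ratings CSV line(s) ", paste(which(bad_lat) + 1L, collapse = ", "),
             ": laterality must be 'left' or 'right'")
  }
  dup <- duplicated(df[c("ear_id", "observer")])
  if (any(dup)) {
    fcd_stop("duplicate ear_id x observer row(s) at line(s) ",
             paste(which(dup) + 1L, collapse = ", "))
  }
  df
}

#' Read a gold-standard CSV of surgical findings
#'
#' Columns `ear_id` and `surgical_finding` (dehiscent/intact/unknown).
#'
#' @param path path to the CSV file.
#' @return data.frame with validated columns.
#' @export
read_gold_csv <- function(path) {
  if (!file.exists(path)) fcd_stop("gold-standard file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("ear_id", "surgical_finding"), names(df))
  if (length(missing)) {
    fcd_stop("gold CSV lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad <- !df$surgical_finding %in% c("dehiscent", "intact", "unknown")
  if (any(bad)) {
    fcd_stop("gold CSV line(s) ", paste(which(bad) + 1L, collapse = ", "),
             ": surgical_finding must be dehiscent, intact or unknown")
  }
  if (anyDuplicated(df$ear_id)) fcd_stop("gold CSV has duplicate ear_id values")
  df
}

#' Assemble per-ear records from long ratings and the gold standard
#'
#' Pivots the long ratings table to one row per ear, derives the
#' consensus from agreement where the observers concur, and requires an
#' explicit consensus row for discrepant ears. The ear (one operated ear
#' per patient) is the unit of analysis; `ear_id` must be unique.
#'
#' @param ratings data.frame from [read_ratings_csv()].
#' @param gold optional data.frame from [read_gold_csv()]; ears absent
#'   from it get `surgical_finding = "unknown"`.
#' @return data.frame, one row per ear: `ear_id`, `laterality`, `obs1_L`,
#'   `obs1_I`, `obs2_L`, `obs2_I`, `consensus_L`, `consensus_I`,
#'   `surgical_finding`.
#' @export
assemble_cohort <- function(ratings, gold = NULL) {
  split_obs <- function(which) {
    sub <- ratings[ratings$observer == which, , drop = FALSE]
    sub[order(sub$ear_id), , drop = FALSE]
  }
  o1 <- split_obs("1"); o2 <- split_obs("2"); oc <- split_obs("consensus")
  if (nrow(o1) == 0L || nrow(o2) == 0L) {
    fcd_stop("both observers 1 and 2 must be present in the ratings")
  }
  if (!identical(o1$ear_id, o2$ear_id)) {
    fcd_stop("observers 1 and 2 cover different ear_id sets")
  }
  rec <- data.frame(ear_id = o1$ear_id, laterality = o1$laterality,
                    obs1_L = o1$lateral_score, obs1_I = o1$inferior_score,
                    obs2_L = o2$lateral_score, obs2_I = o2$inferior_score,
                    stringsAsFactors = FALSE)
  adj_L <- adj_I <- rep(NA_integer_, nrow(rec))
  if (nrow(oc) > 0L) {
    idx <- match(rec$ear_id, oc$ear_id)
    adj_L[!is.na(idx)] <- oc$lateral_score[idx[!is.na(idx)]]
    adj_I[!is.na(idx)] <- oc$inferior_score[idx[!is.na(idx)]]
  }
  rec$consensus_L <- consensus_merge(rec$obs1_L, rec$obs2_L, adj_L)
  rec$consensus_I <- consensus_merge(rec$obs1_I, rec$obs2_I, adj_I)
  rec$surgical_finding <- "unknown"
  if (!is.null(gold)) {
    idx <- match(rec$ear_id, gold$ear_id)
    rec$surgical_finding[!is.na(idx)] <- gold$surgical_finding[idx[!is.na(idx)]]
  }
  rec
}

#' Split a cohort by surgical finding, dropping unknowns with a message
#'
#' Operations that need the gold standard exclude ears with an unknown
#' surgical finding; the number excluded is reported via `message()`.
#'
#' @param cohort data.frame from [assemble_cohort()].
#' @return list with elements `dehiscent` and `intact` (data.frames).
#' @export
split_by_finding <- function(cohort) {
  unknown <- sum(cohort$surgical_finding == "unknown")
  if (unknown > 0L) {
    message(unknown, " ear(s) with unknown surgical finding excluded")
  }
  list(dehiscent = cohort[cohort$surgical_finding == "dehiscent", , drop = FALSE],
       intact = cohort[cohort$surgical_finding == "intact", , drop = FALSE])
}
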