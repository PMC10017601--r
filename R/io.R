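#' Convert a per-ear cohort to the long-format ratings table
#'
#' Emits one row per ear per read (observer 1, observer 2, consensus) in
#' the schema read back by [read_ratings_csv()].
#'
#' @param cohort data.frame in the layout of [assemble_cohort()].
#' @return data.frame with columns `ear_id`, `laterality`, `observer`,
#'   `lateral_score`, `inferior_score`.
#' @export
cohort_to_ratings <- function(cohort) {
  one <- function(observer, L, I) {
    data.frame(ear_id = cohort$ear_id, laterality = cohort$laterality,
               observer = observer, lateral_score = L, inferior_score = I,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("1", cohort$obs1_L, cohort$obs1_I),
               one("2", cohort$obs2_L, cohort$obs2_I),
               one("consensus", cohort$consensus_L, cohort$consensus_I))
  out[order(out$ear_id, out$observer), , drop = FALSE]
}

#' Write a cohort as ratings and gold-standard CSV files
#'
#' @param cohort data.frame in the layout of [assemble_cohort()].
#' @param ratings_path,gold_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_cohort_csv <- function(cohort, ratings_path, gold_path) {
  utils::write.csv(cohort_to_ratings(cohort), ratings_path, row.names = FALSE,
                   quote = FALSE)
  gold <- cohort[, c("ear_id", "surgical_finding")]
  utils::write.csv(gold[order(gold$ear_id), ], gold_path, row.names = FALSE,
                   quote = FALSE)
  invisible(c(ratings = ratings_path, gold = gold_path))
}
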