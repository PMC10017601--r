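#' Cross-tabulate two observers' categorical ratings
#'
#' Builds the k x k contingency table of paired ratings with rows indexed
#' by observer 2 and columns by observer 1, over a fixed ordered category
#' set (wall scores 0..3 by default).
#'
#' @param obs1,obs2 paired rating vectors of equal, positive length.
#' @param categories ordered vector of admissible categories.
#' @return integer matrix with `dimnames = list(obs2 = ..., obs1 = ...)`.
#' @export
score_crosstab <- function(obs1, obs2, categories = 0:3) {
  if (length(obs1) != length(obs2)) {
    fcd_stop("'obs1' and 'obs2' must have equal length")
  }
  if (length(obs1) == 0L) fcd_stop("ratings must be non-empty")
  if (!all(obs1 %in% categories) || !all(obs2 %in% categories)) {
    fcd_stop("ratings contain values outside 'categories'")
  }
  f1 <- factor(obs1, levels = categories)
  f2 <- factor(obs2, levels = categories)
  tab <- table(obs2 = f2, obs1 = f1)
  m <- matrix(as.integer(tab), nrow = length(categories),
              dimnames = list(obs2 = as.character(categories),
                              obs1 = as.character(categories)))
  m
}

#' Cohen's kappa with asymptotic confidence interval
#'
#' Chance-corrected agreement for a square two-observer contingency
#' table: \eqn{\kappa = (p_o - p_e) / (1 - p_e)}, where \eqn{p_o} is the
#' observed agreement (diagonal mass) and \eqn{p_e} the agreement
#' expected under independence of the margins. The standard error is the
#' large-sample formula of Fleiss, Cohen & Everitt (1969) — the variance
#' SPSS reports — and the 95% CI is \eqn{\kappa \pm 1.96\,se}, clipped to
#' \eqn{[-1, 1]}. The kappa is unweighted.
#'
#' @param tab square non-negative integer matrix of paired counts, e.g.
#'   from [score_crosstab()].
#' @param conf_level confidence level for the interval.
#' @return object of class `"kappa_result"`: a list with `kappa`,
#'   `p_observed`, `p_expected`, `se`, `ci_low`, `ci_high`, `strength`,
#'   `n`.
#' @references Fleiss JL, Cohen J, Everitt BS (1969). Large sample
#'   standard errors of kappa and weighted kappa. Psychological Bulletin
#'   72(5), 323-327.
#' @export
cohen_kappa <- function(tab, conf_level = 0.95) {
  if (!is.matrix(tab) || nrow(tab) != ncol(tab)) {
    fcd_stop("'tab' must be a square matrix")
  }
  if (any(tab < 0) || any(tab != floor(tab))) {
    fcd_stop("'tab' must contain non-negative integer counts")
  }
  n <- sum(tab)
  if (n <= 0) fcd_stop("'tab' must have a positive grand total")
  p <- tab / n
  prow <- rowSums(p)  # observer 2 margin
  pcol <- colSums(p)  # observer 1 margin
  po <- sum(diag(p))
  pe <- sum(prow * pcol)
  if (1 - pe < .Machine$double.eps) {
    fcd_stop("degenerate table: all mass in a single category (p_expected = 1)")
  }
  kappa <- (po - pe) / (1 - pe)

  # Fleiss-Cohen-Everitt (1969) asymptotic variance of unweighted kappa.
  k <- nrow(p)
  a <- 0
  for (i in seq_len(k)) {
    a <- a + p[i, i] * ((1 - pe) - (pcol[i] + prow[i]) * (1 - po))^2
  }
  b <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) b <- b + p[i, j] * (pcol[i] + prow[j])^2
    }
  }
  b <- b * (1 - po)^2
  cc <- (po * pe - 2 * pe + po)^2
  # rounding can push the variance a hair below zero at perfect agreement
  se <- as.numeric(sqrt(max(0, a + b - cc) / (n * (1 - pe)^4)))

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  res <- list(kappa = kappa, p_observed = po, p_expected = pe, se = se,
              ci_low = max(-1, kappa - z * se),
              ci_high = min(1, kappa + z * se),
              strength = agreement_strength(kappa), n = n,
              conf_level = conf_level)
  class(res) <- "kappa_result"
  res
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %s (%s agreement)\n",
              fmt_stat(x$kappa), x$strength))
  cat(sprintf("  %d%% CI: %s-%s  (se %s, n = %d)\n",
              round(100 * x$conf_level), fmt_stat(x$ci_low),
              fmt_stat(x$ci_high), fmt_stat(x$se), x$n))
  cat(sprintf("  observed agreement %s, expected %s\n",
              fmt_stat(x$p_observed), fmt_stat(x$p_expected)))
  invisible(x)
}

#' Strength-of-agreement band for a kappa value
#'
#' Bands follow the conventional closed 2-decimal ranges: slight
#' 0.00-0.20, fair 0.21-0.40, moderate 0.41-0.60, good 0.61-0.80,
#' excellent 0.81-1.00. Kappa is rounded half-up to 2 decimals first so
#' the printed band edges partition without gaps; negative kappa maps to
#' `"below_slight"`.
#'
#' @param kappa numeric in \eqn{[-1, 1]}.
#' @return character scalar, one of `below_slight`, `slight`, `fair`,
#'   `moderate`, `good`, `excellent`.
#' @export
agreement_strength <- function(kappa) {
  if (length(kappa) != 1L || is.na(kappa) || kappa < -1 || kappa > 1) {
    fcd_stop("'kappa' must be a single value in [-1, 1]")
  }
  rk <- round_half_up(kappa, 2)
  if (rk < 0) "below_slight"
  else if (rk <= 0.20) "slight"
  else if (rk <= 0.40) "fair"
  else if (rk <= 0.60) "moderate"
  else if (rk <= 0.80) "good"
  else "excellent"
}

#' Per-wall agreement report for a cohort
#'
#' Convenience wrapper: cross-tabulates the two observers per wall and
#' returns the kappa results.
#'
#' @param cohort data.frame from [assemble_cohort()].
#' @return list with elements `lateral` and `inferior`, each a
#'   `kappa_result`.
#' @export
agreement_report <- function(cohort) {
  list(lateral = cohen_kappa(score_crosstab(cohort$obs1_L, cohort$obs2_L)),
       inferior = cohen_kappa(score_crosstab(cohort$obs1_I, cohort$obs2_I)))
}
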