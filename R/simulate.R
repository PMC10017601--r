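#' Specify a generative model for a synthetic scored cohort
#'
#' The generator states the world the analysis assumes: each ear is
#' dehiscent with probability `prevalence`; conditional on that latent
#' truth, the lateral and inferior wall scores are drawn independently
#' from truth-specific categorical distributions (defaults are the
#' study's empirical per-group proportions); each observer reports the
#' latent wall score unchanged with probability `1 - epsilon_obs`, else
#' moves it to an adjacent ordinal category (split evenly between the
#' two neighbours; at the edge categories 0 and 3 the whole error mass
#' goes to the single neighbour); the consensus read is generated the
#' same way with `epsilon_consensus`; the surgical probe reports the
#' truth flipped with probability `probe_error` (default 0: surgery is
#' treated as the gold standard).
#'
#' @param n_ears number of ears to simulate.
#' @param prevalence probability an ear is truly dehiscent (default
#'   29/40, the study prevalence).
#' @param pi_L_pos,pi_L_neg,pi_I_pos,pi_I_neg length-4 probability
#'   vectors over wall scores 0..3 given dehiscent (`pos`) / intact
#'   (`neg`) truth; defaults are the study's per-group proportions.
#' @param epsilon_obs per-observer adjacency-error rate in \[0, 1).
#' @param epsilon_consensus error rate of the consensus read.
#' @param probe_error probability the surgical probe misclassifies the
#'   ear.
#' @param seed integer seed making the cohort fully reproducible.
#' @return object of class `"cohort_model"`.
#' @export
cohort_model <- function(n_ears = 40L, prevalence = 29 / 40,
                         pi_L_pos = c(2, 22, 3, 2) / 29,
                         pi_L_neg = c(0, 1, 4, 6) / 11,
                         pi_I_pos = c(10, 15, 4, 0) / 29,
                         pi_I_neg = c(0, 4, 5, 2) / 11,
                         epsilon_obs = 0.15, epsilon_consensus = 0.05,
                         probe_error = 0, seed = 1L) {
  if (n_ears < 1) fcd_stop("'n_ears' must be positive")
  if (prevalence <= 0 || prevalence > 1) {
    fcd_stop("'prevalence' must lie in (0, 1]")
  }
  for (nm in c("pi_L_pos", "pi_L_neg", "pi_I_pos", "pi_I_neg")) {
    v <- get(nm)
    if (length(v) != 4L || any(v < 0) || abs(sum(v) - 1) > 1e-12) {
      fcd_stop("'", nm, "' must be a length-4 probability vector summing to 1")
    }
  }
  for (nm in c("epsilon_obs", "epsilon_consensus", "probe_error")) {
    v <- get(nm)
    if (v < 0 || v >= 1) fcd_stop("'", nm, "' must lie in [0, 1)")
  }
  structure(list(n_ears = as.integer(n_ears), prevalence = prevalence,
                 pi_L_pos = pi_L_pos, pi_L_neg = pi_L_neg,
                 pi_I_pos = pi_I_pos, pi_I_neg = pi_I_neg,
                 epsilon_obs = epsilon_obs,
                 epsilon_consensus = epsilon_consensus,
                 probe_error = probe_error, seed = as.integer(seed)),
            class = "cohort_model")
}

# Adjacency-weighted confusion kernel over ordinal scores 0..3.
# K[s+1, j+1] = P(reported = j | latent = s).
confusion_kernel <- function(eps) {
  K <- diag(4) * (1 - eps)
  K[1, 2] <- eps
  K[4, 3] <- eps
  for (s in 2:3) {
    K[s, s - 1] <- eps / 2
    K[s, s + 1] <- eps / 2
  }
  K
}

sample_categorical <- function(n, prob, values = 0:3) {
  values[1L + findInterval(stats::runif(n), cumsum(prob),
                           rightmost.closed = TRUE)]
}

confuse <- function(latent, eps) {
  K <- confusion_kernel(eps)
  out <- integer(length(latent))
  for (s in 0:3) {
    idx <- latent == s
    if (any(idx)) out[idx] <- sample_categorical(sum(idx), K[s + 1, ])
  }
  out
}

#' Simulate a synthetic scored cohort
#'
#' Draws a cohort from a [cohort_model()]; the latent truth and latent
#' wall scores are retained so closed-form oracles can be checked
#' against the realized data. Identical seeds give identical cohorts.
#'
#' @param model object from [cohort_model()].
#' @return object of class `"synthetic_cohort"`: list with `records`
#'   (data.frame in the [assemble_cohort()] layout plus `truth`,
#'   `latent_L`, `latent_I`) and `model`.
#' @export
simulate_cohort <- function(model) {
  stopifnot(inherits(model, "cohort_model"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(model$seed)

  n <- model$n_ears
  truth <- ifelse(stats::runif(n) < model$prevalence, "dehiscent", "intact")
  pos <- truth == "dehiscent"
  latent_L <- latent_I <- integer(n)
  latent_L[pos] <- sample_categorical(sum(pos), model$pi_L_pos)
  latent_L[!pos] <- sample_categorical(sum(!pos), model$pi_L_neg)
  latent_I[pos] <- sample_categorical(sum(pos), model$pi_I_pos)
  latent_I[!pos] <- sample_categorical(sum(!pos), model$pi_I_neg)

  rec <- data.frame(
    ear_id = sprintf("ear%0*d", nchar(n), seq_len(n)),
    laterality = sample(c("left", "right"), n, replace = TRUE),
    obs1_L = confuse(latent_L, model$epsilon_obs),
    obs1_I = confuse(latent_I, model$epsilon_obs),
    obs2_L = confuse(latent_L, model$epsilon_obs),
    obs2_I = confuse(latent_I, model$epsilon_obs),
    consensus_L = confuse(latent_L, model$epsilon_consensus),
    consensus_I = confuse(latent_I, model$epsilon_consensus),
    surgical_finding = ifelse(stats::runif(n) < model$probe_error,
                              ifelse(truth == "dehiscent", "intact", "dehiscent"),
                              truth),
    truth = truth, latent_L = latent_L, latent_I = latent_I,
    stringsAsFactors = FALSE)
  structure(list(records = rec, model = model), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d ears (seed %d), %d dehiscent by surgery\n",
              nrow(x$records), x$model$seed,
              sum(x$records$surgical_finding == "dehiscent")))
  invisible(x)
}

truth_vectors <- function(model, wall) {
  wall <- match.arg(wall, c("lateral", "inferior"))
  if (wall == "lateral") list(pos = model$pi_L_pos, neg = model$pi_L_neg)
  else list(pos = model$pi_I_pos, neg = model$pi_I_neg)
}

#' Large-sample Cohen's kappa implied by a cohort model
#'
#' Exact population kappa of the two observers' wall scores under the
#' model. Both observers perturb the same latent wall score, so the
#' joint observer distribution conditions on that latent score:
#' \eqn{P(o_1, o_2) = \sum_t P(t) \sum_s \pi_t(s) K(s, o_1) K(s, o_2)},
#' with \eqn{K} the adjacency confusion kernel; kappa follows from this
#' joint by the standard formula.
#'
#' @param model object from [cohort_model()].
#' @param wall `"lateral"` or `"inferior"`.
#' @return numeric kappa.
#' @export
theoretical_kappa <- function(model, wall = c("lateral", "inferior")) {
  stopifnot(inherits(model, "cohort_model"))
  tv <- truth_vectors(model, match.arg(wall))
  K <- confusion_kernel(model$epsilon_obs)
  joint <- matrix(0, 4, 4)
  mix <- list(list(w = model$prevalence, pi = tv$pos),
              list(w = 1 - model$prevalence, pi = tv$neg))
  for (m in mix) {
    for (s in 1:4) joint <- joint + m$w * m$pi[s] * outer(K[s, ], K[s, ])
  }
  po <- sum(diag(joint))
  pe <- sum(rowSums(joint) * colSums(joint))
  if (1 - pe < .Machine$double.eps) {
    fcd_stop("degenerate model: observers confined to a single category")
  }
  (po - pe) / (1 - pe)
}

# Truth-conditional distribution of the consensus composite score 0..6.
total_score_dists <- function(model) {
  Kc <- t(confusion_kernel(model$epsilon_consensus))
  conv <- function(pL, pI) {
    qL <- as.numeric(Kc %*% pL)
    qI <- as.numeric(Kc %*% pI)
    tot <- numeric(7)
    for (a in 0:3) for (b in 0:3) tot[a + b + 1] <- tot[a + b + 1] + qL[a + 1] * qI[b + 1]
    tot
  }
  list(pos = conv(model$pi_L_pos, model$pi_I_pos),
       neg = conv(model$pi_L_neg, model$pi_I_neg))
}

#' Large-sample AUC of the consensus composite score implied by a model
#'
#' Exact AUC of the consensus total score for the latent truth: the
#' truth-conditional wall-score vectors are passed through the consensus
#' confusion kernel, convolved into total-score distributions, and the
#' tie-corrected rank AUC (lower score indicates dehiscence) is computed
#' in closed form.
#'
#' @param model object from [cohort_model()].
#' @return numeric AUC.
#' @export
theoretical_auc <- function(model) {
  stopifnot(inherits(model, "cohort_model"))
  d <- total_score_dists(model)
  auc <- 0
  for (a in 0:6) {
    for (b in 0:6) {
      if (a < b) auc <- auc + d$pos[a + 1] * d$neg[b + 1]
      else if (a == b) auc <- auc + d$pos[a + 1] * d$neg[b + 1] / 2
    }
  }
  auc
}

#' Theoretical sensitivity and specificity of the consensus score
#'
#' Closed-form operating characteristics of the strict-cutoff classifier
#' on the consensus composite score under a cohort model, plus the
#' model's own Youden-optimal cutoff. Used by parameter-recovery tests.
#'
#' @param model object from [cohort_model()].
#' @return data.frame with columns `cutoff`, `sensitivity`,
#'   `specificity`, `youden` for strict cutoffs 0..7.
#' @export
theoretical_metrics <- function(model) {
  d <- total_score_dists(model)
  sens <- c(0, cumsum(d$pos))
  fpr <- c(0, cumsum(d$neg))
  data.frame(cutoff = 0:7, sensitivity = sens, specificity = 1 - fpr,
             youden = sens - fpr)
}
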