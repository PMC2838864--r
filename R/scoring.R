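#' Biological score-modifier parameters
#'
#' Three modifiers adjust the log maximum-likelihood ratio into the final
#' splice score; none of them touches the p-value. Each modifier is
#' multiplied by the gene's average paired-observation count (`Avg_Obs`)
#' when `normalize_by_avg_obs` is on: log-likelihood ratios scale roughly
#' linearly with the number of effective observations, so this keeps the
#' modifiers' relative influence constant across sample sizes.
#'
#' * multiprobeset: a Bonferroni-style penalty of `-ln(2^(n-1) - 1)`, the
#'   number of distinct ways the gene's n probesets can be split into two
#'   groups (zero for two-probeset genes).
#' * cutoff: a logistic penalty on the gene's inter-group change. Full
#'   magnitude `full_penalty` (nats) at `|AvgChange| = 0`, exactly half at
#'   the `min_fold_change` threshold, vanishing above it; `sharpness`
#'   controls the steepness of the transition.
#' * centering: `centering_bonus` when the two group means move in opposite
#'   directions (a qualitative isoform switch), `centering_penalty` when
#'   they move together; a group mean of exactly zero gives no modifier.
#'
#' @param min_fold_change log2 threshold below which genes are penalized,
#'   default 1.0 (two-fold).
#' @param sharpness positive logistic steepness, default 8.
#' @param full_penalty magnitude of the cutoff penalty in nats, default 2.
#' @param centering_bonus opposite-direction bonus per normalizer unit,
#'   default +0.5.
#' @param centering_penalty same-direction penalty per normalizer unit,
#'   default -0.5.
#' @param normalize_by_avg_obs multiply modifiers by `Avg_Obs`?
#' @param enable_multiprobeset,enable_cutoff,enable_centering per-modifier
#'   switches.
#' @return an object of class `modifier_config`.
#' @export
modifier_config <- function(min_fold_change = 1.0, sharpness = 8,
                            full_penalty = 2, centering_bonus = 0.5,
                            centering_penalty = -0.5,
                            normalize_by_avg_obs = TRUE,
                            enable_multiprobeset = TRUE,
                            enable_cutoff = TRUE,
                            enable_centering = TRUE) {
  stopifnot(sharpness > 0, min_fold_change >= 0, full_penalty >= 0)
  structure(list(min_fold_change = min_fold_change, sharpness = sharpness,
                 full_penalty = full_penalty,
                 centering_bonus = centering_bonus,
                 centering_penalty = centering_penalty,
                 normalize_by_avg_obs = normalize_by_avg_obs,
                 enable_multiprobeset = enable_multiprobeset,
                 enable_cutoff = enable_cutoff,
                 enable_centering = enable_centering),
            class = "modifier_config")
}

normalizer <- function(avg_obs, config) {
  if (config$normalize_by_avg_obs) avg_obs else 1
}

#' Multiple-probeset modifier
#'
#' Bonferroni-style correction for the `2^(n-1) - 1` distinct two-group
#' hypotheses an n-probeset gene can generate, applied additively in log
#' space (equivalent to dividing the likelihood ratio by the hypothesis
#' count). Zero at n = 2 and monotone nonincreasing in n.
#'
#' @param n_probesets number of probesets in the gene (>= 2).
#' @param avg_obs the gene's average paired-observation count.
#' @param config a [modifier_config()].
#' @return a nonpositive modifier value.
#' @export
multiprobeset_modifier <- function(n_probesets, avg_obs = 1,
                                   config = modifier_config()) {
  stopifnot(n_probesets >= 2)
  # log(2^(n-1) - 1) computed in log space to stay finite for large n
  logcount <- (n_probesets - 1) * log(2) + log1p(-2^-(n_probesets - 1))
  -logcount * normalizer(avg_obs, config)
}

#' Expression-cutoff modifier
#'
#' Smoothed penalty on genes whose predicted inter-group log2 change
#' (`AvgChange = mu_A - mu_B`) falls below the minimum fold-change
#' threshold: a logistic step in `|AvgChange|` centred at the threshold
#' with slope `sharpness`, reaching half its full magnitude exactly at the
#' threshold and vanishing above it.
#'
#' @param avg_change the gene's `mu_A - mu_B`.
#' @param avg_obs the gene's average paired-observation count.
#' @param config a [modifier_config()].
#' @return a nonpositive modifier value in `(-full_penalty * normalizer, 0)`.
#' @export
expression_cutoff_modifier <- function(avg_change, avg_obs = 1,
                                       config = modifier_config()) {
  -config$full_penalty * normalizer(avg_obs, config) /
    (1 + exp(config$sharpness * (abs(avg_change) - config$min_fold_change)))
}

#' Centering modifier
#'
#' Rewards genes whose probeset groups move in opposite directions (one
#' isoform up, the other down) -- behaviour that cannot be produced by
#' whole-transcript regulation -- and penalizes genes whose groups move
#' together. A group mean of exactly zero is the declared boundary: no
#' modifier.
#'
#' @param mu_A,mu_B group mean log2 fold changes.
#' @param avg_obs the gene's average paired-observation count.
#' @param config a [modifier_config()].
#' @return the modifier value (bonus, penalty, or 0).
#' @export
centering_modifier <- function(mu_A, mu_B, avg_obs = 1,
                               config = modifier_config()) {
  if (mu_A == 0 || mu_B == 0) return(0)
  if (sign(mu_A) != sign(mu_B)) {
    config$centering_bonus * normalizer(avg_obs, config)
  } else {
    config$centering_penalty * normalizer(avg_obs, config)
  }
}

#' Score and rank fitted genes
#'
#' Adds the three modifiers to each gene's log maximum-likelihood ratio to
#' form the splice score, ranks genes by descending score (ties: ascending
#' p-value, then gene symbol), and flags ideal candidates: statistically
#' significant discordance (`p < alpha`) with a positive splice score.
#' Modifiers never alter the p-values.
#'
#' @param fits the `fits` data frame from [fit_all_genes()].
#' @param config a [modifier_config()].
#' @param alpha significance threshold for the ideal-candidate flag,
#'   default 0.01.
#' @return `fits` with `mod_multiprobeset`, `mod_cutoff`, `mod_centering`,
#'   `splice_score`, `rank`, and `ideal_candidate` columns, sorted by rank.
#' @export
score_and_rank <- function(fits, config = modifier_config(), alpha = 0.01) {
  n <- nrow(fits)
  if (n == 0) {
    fits$mod_multiprobeset <- numeric(0); fits$mod_cutoff <- numeric(0)
    fits$mod_centering <- numeric(0); fits$splice_score <- numeric(0)
    fits$rank <- integer(0); fits$ideal_candidate <- logical(0)
    return(fits)
  }
  fits$mod_multiprobeset <- if (config$enable_multiprobeset) {
    vapply(seq_len(n), function(i)
      multiprobeset_modifier(fits$n_probesets[i], fits$avg_obs[i], config),
      numeric(1))
  } else 0
  fits$mod_cutoff <- if (config$enable_cutoff) {
    vapply(seq_len(n), function(i)
      expression_cutoff_modifier(fits$avg_change[i], fits$avg_obs[i], config),
      numeric(1))
  } else 0
  fits$mod_centering <- if (config$enable_centering) {
    vapply(seq_len(n), function(i)
      centering_modifier(fits$mu_A[i], fits$mu_B[i], fits$avg_obs[i], config),
      numeric(1))
  } else 0
  fits$splice_score <- fits$log_mlr + fits$mod_multiprobeset +
    fits$mod_cutoff + fits$mod_centering
  ord <- order(-fits$splice_score, fits$p_value, fits$gene_symbol)
  fits <- fits[ord, , drop = FALSE]
  rownames(fits) <- NULL
  fits$rank <- seq_len(n)
  fits$ideal_candidate <- fits$p_value < alpha & fits$splice_score > 0
  fits
}
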