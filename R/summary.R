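#' Probeset weighting parameters
#'
#' `wt_scale` is the power applied to the gene-rescaled normalized
#' t-statistic; raising it focuses the mixture fit on the most significant
#' probesets at the cost of information from less reliable ones.
#' `alpha_tnorm` is the two-tailed reference level at which the normalized
#' t-statistic equals one.
#'
#' @param wt_scale positive power, default 2.
#' @param alpha_tnorm two-tailed reference level, default 0.05.
#' @return an object of class `weight_config`.
#' @export
weight_config <- function(wt_scale = 2, alpha_tnorm = 0.05) {
  stopifnot(wt_scale > 0, alpha_tnorm > 0, alpha_tnorm < 1)
  structure(list(wt_scale = wt_scale, alpha_tnorm = alpha_tnorm),
            class = "weight_config")
}

#' Differential-expression summary for one probeset
#'
#' Pooled-variance (homoskedastic) two-sample t-test on log2 intensities.
#' Degenerate cases: zero pooled variance with unequal means gives a
#' sign-matched infinite t and p = 0; with equal means, t = 0 and p = 1.
#'
#' @param control_values,treatment_values numeric log2 intensities, each of
#'   length >= 2.
#' @return a list with `log2fc` (treatment mean minus control mean),
#'   `t_stat`, `p_value` (two-tailed), `df`, and `n_avg_obs` (the average of
#'   the two group sizes).
#' @export
summarize_probeset <- function(control_values, treatment_values) {
  nc <- length(control_values); nt <- length(treatment_values)
  if (nc < 2 || nt < 2) stopf("each group needs >= 2 observations (got %d, %d)", nc, nt)
  mc <- mean(control_values); mt <- mean(treatment_values)
  df <- nc + nt - 2L
  sp2 <- ((nc - 1) * stats::var(control_values) +
          (nt - 1) * stats::var(treatment_values)) / df
  fc <- mt - mc
  if (sp2 <= 0) {
    t <- if (fc == 0) 0 else sign(fc) * Inf
    p <- if (fc == 0) 1 else 0
  } else {
    t <- fc / sqrt(sp2 * (1 / nc + 1 / nt))
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(log2fc = fc, t_stat = t, p_value = p, df = df,
       n_avg_obs = (nc + nt) / 2)
}

#' Normalized t-statistic
#'
#' `|t| / t_crit`, where `t_crit` is the two-tailed critical value of the t
#' distribution at level `alpha_tnorm` and `df` degrees of freedom; equals
#' one exactly for a change significant at that level, so weighting by it
#' counts a significant probeset once.
#'
#' @param t_stat the probeset t-statistic.
#' @param df degrees of freedom (>= 1).
#' @param alpha_tnorm two-tailed reference level.
#' @return nonnegative normalized t.
#' @export
compute_tnorm <- function(t_stat, df, alpha_tnorm = 0.05) {
  stopifnot(all(df >= 1))
  abs(t_stat) / stats::qt(1 - alpha_tnorm / 2, df)
}

#' Rescale probeset weights within one gene
#'
#' Implements the three-stage weighting: when the gene's maximum normalized
#' t exceeds one, all members are divided by that maximum (so no probeset is
#' counted more than once); the result is raised to `wt_scale`; and the
#' effective weight multiplies in the average paired-observation count, so a
#' probeset contributes at most one unit per effective pair of observations.
#'
#' @param summaries data frame with columns `t_norm` and `n_avg_obs`, one
#'   row per probeset of a single gene (>= 1 row).
#' @param config a [weight_config()].
#' @return `summaries` with `scaled_weight` (in `[0, 1]`) and
#'   `effective_weight` columns added/overwritten.
#' @export
scale_gene_weights <- function(summaries, config = weight_config()) {
  if (nrow(summaries) < 1) stopf("no probeset summaries supplied")
  tn <- summaries$t_norm
  M <- max(tn)
  if (is.infinite(M)) {
    base <- ifelse(is.infinite(tn), 1, 0)
  } else if (M > 1) {
    base <- tn / M
  } else {
    base <- pmin(tn, 1)
  }
  summaries$scaled_weight <- base^config$wt_scale
  summaries$effective_weight <- summaries$scaled_weight * summaries$n_avg_obs
  summaries
}

#' Per-probeset differential-expression table
#'
#' Step one of the analysis: every probeset in the (filtered) matrix gets a
#' log2 fold change, homoskedastic t-statistic, two-tailed p-value, and the
#' three-stage weight, with the within-gene rescaling applied over the
#' probesets present in the matrix. Probesets without a gene annotation are
#' weighted as singleton groups.
#'
#' @param mat log2 expression matrix (after filtering).
#' @param design a [group_design()].
#' @param annotation optional `probeset_annotation` data frame used to
#'   attach gene symbols.
#' @param config a [weight_config()].
#' @return a data frame with one row per probeset.
#' @export
probeset_summary_table <- function(mat, design, annotation = NULL,
                                   config = weight_config()) {
  check_design(design, mat)
  cmat <- mat[, design$control, drop = FALSE]
  tmat <- mat[, design$treatment, drop = FALSE]
  nc <- ncol(cmat); nt <- ncol(tmat)
  df <- nc + nt - 2L
  mc <- rowMeans(cmat); mt <- rowMeans(tmat)
  vc <- apply(cmat, 1, stats::var); vt <- apply(tmat, 1, stats::var)
  sp2 <- ((nc - 1) * vc + (nt - 1) * vt) / df
  fc <- mt - mc
  se <- sqrt(sp2 * (1 / nc + 1 / nt))
  t <- ifelse(sp2 > 0, fc / se, ifelse(fc == 0, 0, sign(fc) * Inf))
  p <- ifelse(is.infinite(t), 0, 2 * stats::pt(-abs(t), df))
  out <- data.frame(probeset_id = rownames(mat),
                    gene_symbol = NA_character_,
                    log2fc = fc, t_stat = t, df = df, p_value = p,
                    n_avg_obs = (nc + nt) / 2,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    idx <- match(out$probeset_id, annotation$probeset_id)
    out$gene_symbol <- annotation$gene_symbol[idx]
  }
  out$t_norm <- compute_tnorm(out$t_stat, out$df, config$alpha_tnorm)
  # within-gene rescale; unannotated probesets form singleton groups
  key <- ifelse(is.na(out$gene_symbol),
                paste0(".solo.", out$probeset_id), out$gene_symbol)
  pieces <- split(seq_len(nrow(out)), key)
  out$scaled_weight <- NA_real_
  out$effective_weight <- NA_real_
  for (ix in pieces) {
    out[ix, c("scaled_weight", "effective_weight")] <-
      scale_gene_weights(out[ix, , drop = FALSE],
                         config)[, c("scaled_weight", "effective_weight")]
  }
  out
}
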