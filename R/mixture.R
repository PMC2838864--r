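#' Mixture-fit parameters
#'
#' `sigma_floor` bounds every fitted standard deviation from below (0.10 in
#' log2-fold-change units, the scale being modelled) to prevent over-fitting
#' of small probeset groups. Genes with up to `max_probesets_exhaustive`
#' probesets are fitted by exhaustive bipartition enumeration (at the
#' platform-typical 2-8 probesets per gene this is at most 2^(n-1)-1 <= 2047
#' candidate fits and removes any local-optimum risk); larger genes use
#' classification EM from `em_restarts` deterministic splits of the
#' value-sorted probeset list.
#'
#' @param sigma_floor minimum fitted standard deviation, default 0.10.
#' @param max_probesets_exhaustive exhaustive-enumeration cutoff, default 12.
#' @param em_restarts number of deterministic sorted-split initializations.
#' @param em_max_iter maximum reassignment sweeps per restart.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(sigma_floor = 0.10, max_probesets_exhaustive = 12,
                       em_restarts = 5, em_max_iter = 500) {
  stopifnot(sigma_floor > 0, max_probesets_exhaustive >= 2,
            em_restarts >= 1, em_max_iter >= 1)
  structure(list(sigma_floor = sigma_floor,
                 max_probesets_exhaustive = max_probesets_exhaustive,
                 em_restarts = em_restarts, em_max_iter = em_max_iter),
            class = "fit_config")
}

#' Weighted Gaussian log-likelihood
#'
#' `sum_i w_i * log N(x_i; mu, sigma)`. The weights are the effective
#' probeset weights: they state how many effective paired observations each
#' probeset's fold change represents.
#'
#' @param values numeric vector of probeset log2 fold changes.
#' @param weights nonnegative weights, same length.
#' @param mu,sigma Gaussian parameters (`sigma > 0`).
#' @return the weighted log-likelihood.
#' @export
weighted_gaussian_loglik <- function(values, weights, mu, sigma) {
  stopifnot(length(values) == length(weights), all(weights >= 0), sigma > 0)
  sum(weights * stats::dnorm(values, mu, sigma, log = TRUE))
}

# group parameters: weighted mean and floored weighted SD
group_params <- function(values, weights, config) {
  m <- weighted_moments(values, weights)
  list(mu = m$mu, sigma = max(m$sd, config$sigma_floor))
}

#' One-component fit of a gene's probeset fold changes
#'
#' @param values,weights probeset log2 fold changes and effective weights
#'   (>= 2 probesets; total weight must be positive).
#' @param config a [fit_config()].
#' @return a list with `mu`, `sigma` (floored), and `loglik`.
#' @export
fit_single <- function(values, weights, config = fit_config()) {
  if (length(values) < 2) stopf("single-component fit needs >= 2 probesets")
  if (sum(weights) <= 0) stopf("all probeset weights are zero; gene is untestable")
  p <- group_params(values, weights, config)
  list(mu = p$mu, sigma = p$sigma,
       loglik = weighted_gaussian_loglik(values, weights, p$mu, p$sigma))
}

# loglik of a hard two-group assignment (logical vector: TRUE = group 1)
partition_loglik <- function(values, weights, in1, config) {
  p1 <- group_params(values[in1], weights[in1], config)
  p2 <- group_params(values[!in1], weights[!in1], config)
  ll <- weighted_gaussian_loglik(values[in1], weights[in1], p1$mu, p1$sigma) +
        weighted_gaussian_loglik(values[!in1], weights[!in1], p2$mu, p2$sigma)
  list(loglik = ll, p1 = p1, p2 = p2)
}

# Tie-break key for competing partitions with (numerically) equal
# likelihood: fewer singleton groups first, then the lexicographically
# smallest membership of the A (higher-mean) group.
partition_key <- function(in1, p1, p2) {
  a_first <- if (p1$mu > p2$mu) in1
             else if (p2$mu > p1$mu) !in1
             else if (in1[1]) in1 else !in1   # equal means: group of probeset 1
  n1 <- sum(in1)
  singletons <- (n1 == 1) + (length(in1) - n1 == 1)
  list(singletons = singletons, a = which(a_first))
}

# TRUE if key a beats key b under the tie rules
key_beats <- function(a, b) {
  if (a$singletons != b$singletons) return(a$singletons < b$singletons)
  la <- length(a$a); lb <- length(b$a)
  for (i in seq_len(min(la, lb))) {
    if (a$a[i] != b$a[i]) return(a$a[i] < b$a[i])
  }
  la < lb
}

#' Two-component hard-assignment fit
#'
#' Splits a gene's probesets into two nonempty groups maximizing the summed
#' weighted Gaussian log-likelihood, each group parameterized by its
#' weighted mean and floored weighted SD. Genes with up to
#' `max_probesets_exhaustive` probesets are solved by enumerating all
#' 2^(n-1)-1 bipartitions; larger genes by iterative reassignment
#' (classification EM) from deterministic splits of the value-sorted list.
#' Ties are broken toward fewer singleton groups, then the lexicographically
#' smallest A-group membership. The higher-mean group is labelled A ("up").
#'
#' @param values,weights probeset log2 fold changes and effective weights.
#' @param config a [fit_config()].
#' @return a list with `assignment` (character vector of `"A"`/`"B"`),
#'   `mu_A`, `mu_B`, `sigma_A`, `sigma_B`, and `loglik`.
#' @export
fit_two_group <- function(values, weights, config = fit_config()) {
  n <- length(values)
  if (n < 2) stopf("two-component fit needs >= 2 probesets")
  if (sum(weights) <= 0) stopf("all probeset weights are zero; gene is untestable")
  if (n <= config$max_probesets_exhaustive) {
    best <- exhaustive_two_group(values, weights, config)
  } else {
    best <- em_two_group(values, weights, config)
  }
  finish_two_group(values, best$in1, best$fit)
}

exhaustive_two_group <- function(values, weights, config, tol = 1e-9) {
  n <- length(values)
  bits <- 2^(0:(n - 2))
  best <- NULL
  for (m in seq_len(2^(n - 1) - 1)) {
    in1 <- c(TRUE, bitwAnd(m, bits) == 0)  # probeset 1 anchored in group 1
    fit <- partition_loglik(values, weights, in1, config)
    if (is.null(best) || fit$loglik > best$fit$loglik + tol) {
      best <- list(in1 = in1, fit = fit,
                   key = partition_key(in1, fit$p1, fit$p2))
    } else if (fit$loglik >= best$fit$loglik - tol) {
      key <- partition_key(in1, fit$p1, fit$p2)
      if (key_beats(key, best$key)) {
        best <- list(in1 = in1, fit = fit, key = key)
      }
    }
  }
  best
}

em_two_group <- function(values, weights, config, tol = 1e-9) {
  n <- length(values)
  ord <- order(values)
  splits <- unique(pmin(pmax(round(seq(1, n - 1,
                                       length.out = config$em_restarts)), 1),
                        n - 1))
  best <- NULL
  for (k in splits) {
    in1 <- logical(n)
    in1[ord[seq_len(k)]] <- TRUE
    for (iter in seq_len(config$em_max_iter)) {
      fit <- partition_loglik(values, weights, in1, config)
      d1 <- stats::dnorm(values, fit$p1$mu, fit$p1$sigma, log = TRUE)
      d2 <- stats::dnorm(values, fit$p2$mu, fit$p2$sigma, log = TRUE)
      new1 <- ifelse(d1 == d2, in1, d1 > d2)
      if (all(new1) || !any(new1)) break  # refuse to empty a group
      if (all(new1 == in1)) break
      in1 <- new1
    }
    fit <- partition_loglik(values, weights, in1, config)
    key <- partition_key(in1, fit$p1, fit$p2)
    if (is.null(best) || fit$loglik > best$fit$loglik + tol ||
        (fit$loglik >= best$fit$loglik - tol && key_beats(key, best$key))) {
      best <- list(in1 = in1, fit = fit, key = key)
    }
  }
  best
}

finish_two_group <- function(values, in1, fit) {
  if (fit$p1$mu > fit$p2$mu ||
      (fit$p1$mu == fit$p2$mu && in1[1])) {
    a <- in1; pa <- fit$p1; pb <- fit$p2
  } else {
    a <- !in1; pa <- fit$p2; pb <- fit$p1
  }
  list(assignment = ifelse(a, "A", "B"),
       mu_A = pa$mu, mu_B = pb$mu,
       sigma_A = pa$sigma, sigma_B = pb$sigma,
       loglik = fit$loglik)
}

#' Mixture likelihood-ratio test for one gene
#'
#' Compares the two-component and one-component weighted Gaussian fits of a
#' gene's probeset log2 fold changes. The log maximum-likelihood ratio is
#' nonnegative (the one-group model is nested in the two-group model); its
#' doubled value is referred to a chi-squared distribution with 2 degrees of
#' freedom (the second mean and second sigma), whose upper tail has the
#' closed form `exp(-lr/2)`.
#'
#' @param summaries data frame for one gene with columns `probeset_id`,
#'   `log2fc`, `effective_weight`, `n_avg_obs` (>= 2 rows, positive total
#'   weight).
#' @param config a [fit_config()].
#' @param gene_symbol optional label carried into the result.
#' @return a list of class `gene_fit`: the A/B `assignment` (named by
#'   probeset), group and single-model parameters, `log_mlr`, `lr_stat`,
#'   `p_value`, `avg_change` (`mu_A - mu_B`), and `avg_obs`.
#' @export
fit_gene <- function(summaries, config = fit_config(), gene_symbol = NA_character_) {
  if (nrow(summaries) < 2) {
    stopf("gene %s has a single probeset and cannot be tested", gene_symbol)
  }
  x <- summaries$log2fc
  w <- summaries$effective_weight
  if (sum(w) <= 0) stopf("gene %s: all probeset weights are zero; untestable", gene_symbol)
  one <- fit_single(x, w, config)
  two <- fit_two_group(x, w, config)
  log_mlr <- two$loglik - one$loglik
  if (log_mlr < 0) log_mlr <- 0  # numerical tolerance in nested fits
  lr <- 2 * log_mlr
  structure(list(gene_symbol = gene_symbol,
                 assignment = setNames(two$assignment, summaries$probeset_id),
                 mu_A = two$mu_A, mu_B = two$mu_B,
                 sigma_A = two$sigma_A, sigma_B = two$sigma_B,
                 mu_single = one$mu, sigma_single = one$sigma,
                 log_mlr = log_mlr, lr_stat = lr,
                 p_value = stats::pchisq(lr, df = 2, lower.tail = FALSE),
                 avg_change = two$mu_A - two$mu_B,
                 avg_obs = mean(summaries$n_avg_obs)),
            class = "gene_fit")
}

#' Fit the mixture model for every eligible gene
#'
#' Runs [fit_gene()] on every annotated gene with at least two probesets in
#' the summary table and a positive total weight; other genes are skipped
#' with a recorded reason.
#'
#' @param summary_table output of [probeset_summary_table()].
#' @param config a [fit_config()].
#' @return a list with `fits` (one row per tested gene), `assignments`
#'   (long data frame gene/probeset/group), and `skipped`
#'   (gene/reason).
#' @export
fit_all_genes <- function(summary_table, config = fit_config()) {
  st <- summary_table[!is.na(summary_table$gene_symbol), , drop = FALSE]
  pieces <- split(seq_len(nrow(st)), st$gene_symbol)
  pieces <- pieces[order(names(pieces))]
  fits <- list(); assigns <- list(); skipped <- list()
  for (g in names(pieces)) {
    rows <- st[pieces[[g]], , drop = FALSE]
    if (nrow(rows) < 2) {
      skipped[[g]] <- "single-probeset gene"
      next
    }
    if (sum(rows$effective_weight) <= 0) {
      skipped[[g]] <- "all probeset weights zero"
      next
    }
    fit <- fit_gene(rows, config, gene_symbol = g)
    fits[[g]] <- data.frame(gene_symbol = g, n_probesets = nrow(rows),
                            mu_A = fit$mu_A, mu_B = fit$mu_B,
                            sigma_A = fit$sigma_A, sigma_B = fit$sigma_B,
                            mu_single = fit$mu_single,
                            sigma_single = fit$sigma_single,
                            log_mlr = fit$log_mlr, lr_stat = fit$lr_stat,
                            p_value = fit$p_value,
                            avg_change = fit$avg_change,
                            avg_obs = fit$avg_obs,
                            stringsAsFactors = FALSE)
    assigns[[g]] <- data.frame(gene_symbol = g,
                               probeset_id = names(fit$assignment),
                               group = unname(fit$assignment),
                               stringsAsFactors = FALSE)
  }
  fits_df <- if (length(fits)) {
    do.call(rbind, c(fits, list(make.row.names = FALSE)))
  } else {
    empty_fits_frame()
  }
  assigns_df <- if (length(assigns)) {
    do.call(rbind, c(assigns, list(make.row.names = FALSE)))
  } else {
    data.frame(gene_symbol = character(), probeset_id = character(),
               group = character(), stringsAsFactors = FALSE)
  }
  list(fits = fits_df, assignments = assigns_df,
       skipped = data.frame(gene_symbol = names(skipped),
                            reason = if (length(skipped)) unlist(skipped) else character(0),
                            row.names = NULL, stringsAsFactors = FALSE))
}

empty_fits_frame <- function() {
  data.frame(gene_symbol = character(), n_probesets = integer(),
             mu_A = numeric(), mu_B = numeric(), sigma_A = numeric(),
             sigma_B = numeric(), mu_single = numeric(),
             sigma_single = numeric(), log_mlr = numeric(),
             lr_stat = numeric(), p_value = numeric(),
             avg_change = numeric(), avg_obs = numeric(),
             stringsAsFactors = FALSE)
}
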