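test_that("multiprobeset modifier counts bipartitions and is monotone", {
  cfg <- modifier_config()
  expect_equal(multiprobeset_modifier(2, 1, cfg), 0)
  # counts verified against explicit enumeration of bipartitions
  expect_equal(length(all_bipartitions(3)), 3)
  expect_equal(multiprobeset_modifier(3, 1, cfg), -log(3))
  expect_equal(length(all_bipartitions(4)), 7)
  expect_equal(multiprobeset_modifier(4, 1, cfg), -log(7))
  expect_equal(multiprobeset_modifier(3, 5, cfg), -log(3) * 5)

  vals <- vapply(2:12, multiprobeset_modifier, numeric(1), avg_obs = 1,
                 config = cfg)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals <= 0))
})

test_that("cutoff modifier is a logistic step centred at the threshold", {
  cfg <- modifier_config(min_fold_change = 1, sharpness = 8, full_penalty = 2)
  expect_equal(expression_cutoff_modifier(1, 1, cfg), -2 / 2)  # exact midpoint
  expect_equal(expression_cutoff_modifier(-1, 1, cfg), -1)     # |AvgChange|
  expect_lt(abs(expression_cutoff_modifier(1 + 10 / 8, 1, cfg)), 2 * exp(-10))
  expect_lt(expression_cutoff_modifier(0, 1, cfg), -2 * 0.999)

  # sharper curve: unchanged at threshold, harsher below, gentler above
  sharp <- modifier_config(min_fold_change = 1, sharpness = 16,
                           full_penalty = 2)
  expect_equal(expression_cutoff_modifier(1, 1, sharp), -1)
  expect_lt(expression_cutoff_modifier(0.9, 1, sharp),
            expression_cutoff_modifier(0.9, 1, cfg))
  expect_gt(expression_cutoff_modifier(1.1, 1, sharp),
            expression_cutoff_modifier(1.1, 1, cfg))

  # monotone in |AvgChange| and bounded
  vals <- vapply(seq(0, 3, 0.1), expression_cutoff_modifier, numeric(1),
                 avg_obs = 1, config = cfg)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > -2 & vals < 0))
})

test_that("centering modifier rewards opposite-direction groups", {
  cfg <- modifier_config()
  expect_equal(centering_modifier(1, -1, 1, cfg), 0.5)
  expect_equal(centering_modifier(2, 0.5, 1, cfg), -0.5)
  expect_equal(centering_modifier(-0.2, -1, 1, cfg), -0.5)
  expect_equal(centering_modifier(1, 0, 1, cfg), 0)
  expect_equal(centering_modifier(1, -1, 6, cfg), 3)
})

make_fits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_symbol = r$gene, n_probesets = r$n %||% 2,
               mu_A = r$mu_A, mu_B = r$mu_B, sigma_A = 0.1, sigma_B = 0.1,
               mu_single = (r$mu_A + r$mu_B) / 2, sigma_single = 0.5,
               log_mlr = r$log_mlr, lr_stat = 2 * r$log_mlr,
               p_value = exp(-r$log_mlr),
               avg_change = r$mu_A - r$mu_B, avg_obs = r$avg_obs %||% 6,
               stringsAsFactors = FALSE)
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("scoring never touches p-values and ranks by descending score", {
  fits <- make_fits(list(gene = "G1", mu_A = 1, mu_B = -1, log_mlr = 10),
                    list(gene = "G2", mu_A = 2, mu_B = 0.5, log_mlr = 10),
                    list(gene = "G3", mu_A = 0.2, mu_B = -0.1, log_mlr = 1))
  scored <- score_and_rank(fits)
  expect_identical(sort(scored$p_value), sort(fits$p_value))  # bitwise same set
  expect_equal(scored$splice_score,
               scored$log_mlr + scored$mod_multiprobeset +
                 scored$mod_cutoff + scored$mod_centering)
  expect_false(is.unsorted(rev(scored$splice_score)))
  # equal log MLR: opposite-direction gene outranks same-direction gene
  expect_lt(which(scored$gene_symbol == "G1"),
            which(scored$gene_symbol == "G2"))
})

test_that("disabling all modifiers reduces the score to the log MLR", {
  set.seed(53)
  fits <- make_fits(list(gene = "G1", mu_A = 1, mu_B = -1, log_mlr = 5),
                    list(gene = "G2", mu_A = 1, mu_B = 0.2, log_mlr = 8),
                    list(gene = "G3", mu_A = 3, mu_B = -2, log_mlr = 2))
  off <- modifier_config(enable_multiprobeset = FALSE, enable_cutoff = FALSE,
                         enable_centering = FALSE)
  scored <- score_and_rank(fits, off)
  expect_equal(scored$splice_score, scored$log_mlr)
  expect_equal(scored$gene_symbol,
               fits$gene_symbol[order(-fits$log_mlr)])
})

test_that("ideal candidates are the significant positive-score genes", {
  fx <- generate_fixture(fixture_spec(n_genes = 120, seed = 19))
  res <- run_compare(fx$expression, fx$annotation, fx$design)
  hand <- res$results$p_value < 0.01 & res$results$splice_score > 0
  expect_identical(res$results$ideal_candidate, hand)
})

test_that("normalization keeps modifier influence constant across sample size", {
  # noise-free probeset pattern: log MLR scales linearly with paired
  # observations, and so must every modifier
  gene_at <- function(n_obs) {
    data.frame(probeset_id = paste0("p", 1:4),
               log2fc = c(1, 1, -1, -1),
               effective_weight = n_obs, n_avg_obs = n_obs)
  }
  cfg <- modifier_config()
  ratios <- vapply(c(3, 30), function(n_obs) {
    fit <- fit_gene(gene_at(n_obs), gene_symbol = "G")
    mods <- multiprobeset_modifier(4, fit$avg_obs, cfg) +
      expression_cutoff_modifier(fit$avg_change, fit$avg_obs, cfg) +
      centering_modifier(fit$mu_A, fit$mu_B, fit$avg_obs, cfg)
    abs(mods) / fit$log_mlr
  }, numeric(1))
  expect_lt(abs(ratios[1] - ratios[2]) / ratios[2], 0.2)
})
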