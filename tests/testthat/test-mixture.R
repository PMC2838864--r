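test_that("weighted Gaussian log-likelihood matches closed forms", {
  expect_equal(weighted_gaussian_loglik(5, 1, 5, 0.1),
               -log(0.1 * sqrt(2 * pi)))
  x <- c(-0.5, 0.2, 1.3); w <- c(0.5, 2, 1)
  ll <- weighted_gaussian_loglik(x, w, 0.3, 0.7)
  expect_equal(ll, 2 * weighted_gaussian_loglik(x, w / 2, 0.3, 0.7) / 1,
               tolerance = 1e-12)
  expect_equal(weighted_gaussian_loglik(x, 2 * w, 0.3, 0.7), 2 * ll,
               tolerance = 1e-12)
  hand <- sum(w * (-log(0.7 * sqrt(2 * pi)) - (x - 0.3)^2 / (2 * 0.7^2)))
  expect_equal(ll, hand, tolerance = 1e-12)
})

test_that("single-component fits are floored weighted moments", {
  f <- fit_single(c(1, 1, 1, 1), rep(2, 4))
  expect_equal(f$mu, 1)
  expect_equal(f$sigma, 0.10)

  f2 <- fit_single(c(0, 2), c(1, 1))
  expect_equal(f2$mu, 1)
  expect_equal(f2$sigma, 1)

  f3 <- fit_single(c(0, 2), c(3, 1))
  expect_equal(f3$mu, 0.5)

  expect_error(fit_single(c(0, 2), c(0, 0)), "untestable")
})

test_that("two-group fit separates clear clusters with floored sigmas", {
  f <- fit_two_group(c(1, 1, -1, -1), rep(1, 4))
  expect_equal(f$assignment, c("A", "A", "B", "B"))
  expect_equal(f$mu_A, 1)
  expect_equal(f$mu_B, -1)
  expect_equal(f$sigma_A, 0.10)
  expect_equal(f$sigma_B, 0.10)
})

test_that("identical values give log MLR 0 and a canonical partition", {
  df <- data.frame(probeset_id = paste0("p", 1:4), log2fc = 1,
                   effective_weight = 2, n_avg_obs = 6)
  fit <- fit_gene(df, gene_symbol = "G")
  expect_equal(fit$log_mlr, 0)
  expect_equal(fit$p_value, 1)
  expect_true(all(c("A", "B") %in% fit$assignment))
  # canonical tie-break is deterministic
  fit2 <- fit_gene(df, gene_symbol = "G")
  expect_identical(fit$assignment, fit2$assignment)
})

test_that("the selected bipartition equals independent exhaustive enumeration", {
  set.seed(41)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    x <- rnorm(n, 0, 1)
    w <- runif(n, 0.1, 6)
    f <- fit_two_group(x, w)
    o <- oracle_two_group(x, w)
    expect_equal(f$loglik, o$ll, tolerance = 1e-9)
    expect_true(same_partition(which(f$assignment == "A"), seq_len(n), o$g1))
  }
})

test_that("iterative (EM) fitting is bounded by and usually attains the optimum", {
  # The classification-EM path is a local search used only above the
  # exhaustive-enumeration cutoff; it can never beat the exhaustive optimum
  # and should attain it in the large majority of random genes.
  cfg_em <- fit_config(max_probesets_exhaustive = 2)
  set.seed(43)
  matched <- 0; total <- 120
  for (rep in seq_len(total)) {
    n <- sample(3:8, 1)
    # mix of clustered and diffuse genes
    x <- if (rep %% 2) rnorm(n, 0, 0.3) else
      c(rnorm(ceiling(n / 2), 1, 0.2), rnorm(floor(n / 2), -1, 0.2))
    w <- runif(n, 0.5, 6)
    em <- fit_two_group(x, w, cfg_em)
    ex <- fit_two_group(x, w, fit_config())
    expect_lte(em$loglik, ex$loglik + 1e-9)
    if (abs(em$loglik - ex$loglik) < 1e-9) matched <- matched + 1
  }
  expect_gte(matched / total, 0.9)
})

test_that("gene-level LR test matches brute-force two-probeset evaluation", {
  df <- data.frame(probeset_id = c("p1", "p2"), log2fc = c(1, -1),
                   effective_weight = c(3, 3), n_avg_obs = 6)
  fit <- fit_gene(df, gene_symbol = "G")
  # only one bipartition exists; evaluate both models in closed form
  ll2 <- 2 * 3 * dnorm(0, 0, 0.1, log = TRUE)          # exact fits, floored
  mu <- 0; sd1 <- max(sqrt((3 * 1 + 3 * 1) / 6), 0.1)  # weighted SD = 1
  ll1 <- sum(3 * dnorm(c(1, -1), mu, sd1, log = TRUE))
  expect_equal(fit$log_mlr, ll2 - ll1, tolerance = 1e-9)
  expect_equal(fit$p_value, exp(-fit$lr_stat / 2), tolerance = 1e-12)
  expect_equal(fit$avg_change, 2)
  expect_equal(fit$avg_obs, 6)
})

test_that("chi-squared(2) upper tail equals exp(-lr/2)", {
  expect_equal(pchisq(5.991, 2, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  for (lr in c(0, 0.5, 2, 5.991464, 20, 80)) {
    expect_equal(pchisq(lr, 2, lower.tail = FALSE), exp(-lr / 2),
                 tolerance = 1e-12)
  }
})

test_that("log MLR is nonnegative and shift-equivariant", {
  set.seed(47)
  for (rep in 1:30) {
    n <- sample(2:7, 1)
    df <- data.frame(probeset_id = paste0("p", 1:n),
                     log2fc = rnorm(n, 0, 0.5),
                     effective_weight = runif(n, 0, 6),
                     n_avg_obs = 6)
    if (sum(df$effective_weight) == 0) df$effective_weight[1] <- 1
    fit <- fit_gene(df, gene_symbol = "G")
    expect_gte(fit$log_mlr, 0)

    shifted <- df; shifted$log2fc <- df$log2fc + 1.7
    fs <- fit_gene(shifted, gene_symbol = "G")
    expect_equal(fs$log_mlr, fit$log_mlr, tolerance = 1e-9)
    expect_equal(fs$mu_A, fit$mu_A + 1.7, tolerance = 1e-9)
    expect_equal(fs$mu_B, fit$mu_B + 1.7, tolerance = 1e-9)
    expect_equal(fs$mu_single, fit$mu_single + 1.7, tolerance = 1e-9)
  }
})

test_that("fitting a whole table skips untestable genes with reasons", {
  tab <- data.frame(probeset_id = paste0("p", 1:5),
                    gene_symbol = c("G1", "G1", "G2", "G3", "G3"),
                    log2fc = c(1, -1, 0.3, 0.2, 0.1),
                    effective_weight = c(2, 2, 1, 0, 0),
                    n_avg_obs = 6, stringsAsFactors = FALSE)
  out <- fit_all_genes(tab)
  expect_equal(out$fits$gene_symbol, "G1")
  expect_setequal(out$skipped$gene_symbol, c("G2", "G3"))
  expect_equal(out$skipped$reason[out$skipped$gene_symbol == "G2"],
               "single-probeset gene")
  expect_equal(out$skipped$reason[out$skipped$gene_symbol == "G3"],
               "all probeset weights zero")
  expect_equal(nrow(out$assignments), 2)
})
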