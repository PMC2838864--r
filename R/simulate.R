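#' Specify a synthetic platform and expression fixture
#'
#' The generator emulates the four regimes a probeset-level isoform scan
#' must distinguish: no change, concordant increase, concordant decrease,
#' and a discordant isoform switch in which two probeset groups move apart
#' by `switch_delta` log2 units. It also plants the two nuisance classes the
#' filtering stage exists for: negative-strand-matching probesets (NSMPs)
#' and probesets expressed at background level, both drawn from a common
#' background intensity distribution.
#'
#' Defaults mirror a routine two-condition probeset-summary comparison:
#' six samples per group, per-sample log2 intensity noise of 0.2, an
#' RMA-like baseline of N(8, 2), a probesets-per-gene distribution matching
#' the commonly used human 3' expression platforms (57% of genes with
#' multiple probesets, about 3.2 probesets among those), isoform switches in
#' 20% of multi-probeset genes separated by 2 log2 units, and conventional
#' two-fold concordant expression changes in 20% of genes.
#'
#' @param n_genes number of annotated genes.
#' @param probesets_per_gene probability weights over 1..8 probesets.
#' @param n_control,n_treatment samples per group.
#' @param noise_sd per-sample log2 intensity noise SD.
#' @param switch_fraction fraction of multi-probeset genes given an isoform
#'   switch.
#' @param switch_delta log2 separation between the implanted groups.
#' @param expression_change_fraction fraction of remaining genes given a
#'   concordant expression change (half up, half down).
#' @param expression_change_magnitude log2 magnitude of concordant changes.
#' @param nsmp_count number of NSMP probesets.
#' @param absent_fraction fraction of target probesets planted at
#'   background level.
#' @param baseline_mean,baseline_sd log2 baseline intensity distribution of
#'   expressed probesets.
#' @param background_mean,background_sd log2 intensity distribution of the
#'   NSMP/absent background.
#' @param seed integer RNG seed; a fixed seed makes the fixture
#'   byte-identical across runs.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 500,
                         probesets_per_gene = c(0.43, 0.27, 0.12, 0.08,
                                                0.05, 0.03, 0.01, 0.01),
                         n_control = 6, n_treatment = 6,
                         noise_sd = 0.2,
                         switch_fraction = 0.2, switch_delta = 2.0,
                         expression_change_fraction = 0.2,
                         expression_change_magnitude = 1.0,
                         nsmp_count = 100, absent_fraction = 0.05,
                         baseline_mean = 8, baseline_sd = 2,
                         background_mean = 3.5, background_sd = 0.8,
                         seed = 1) {
  stopifnot(n_genes >= 1, length(probesets_per_gene) == 8,
            all(probesets_per_gene >= 0), sum(probesets_per_gene) > 0,
            n_control >= 2, n_treatment >= 2, noise_sd >= 0,
            switch_fraction >= 0, switch_fraction <= 1,
            expression_change_fraction >= 0, expression_change_fraction <= 1,
            absent_fraction >= 0, absent_fraction <= 1,
            nsmp_count >= 0, switch_delta >= 0)
  structure(as.list(environment()), class = "fixture_spec")
}

random_sequence <- function(n, len = 60) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate a synthetic platform annotation
#'
#' Deterministic under the spec's seed. NSMP records are annotated with the
#' symbol of the gene whose opposite strand they match and flagged
#' `is_nsmp`; every probeset carries a random nucleotide target sequence.
#'
#' @param spec a [fixture_spec()].
#' @return a `probeset_annotation` data frame.
#' @export
generate_platform <- function(spec) {
  set.seed(spec$seed)
  genes <- sprintf("GENE%04d", seq_len(spec$n_genes))
  k <- sample(1:8, spec$n_genes, replace = TRUE, prob = spec$probesets_per_gene)
  sym <- rep(genes, k)
  n_target <- length(sym)
  n_total <- n_target + spec$nsmp_count
  ids <- sprintf("%06d_at", 100000 + seq_len(n_total))
  nsmp_sym <- if (spec$nsmp_count > 0) {
    sample(genes, spec$nsmp_count, replace = TRUE)
  } else character(0)
  out <- data.frame(probeset_id = ids,
                    gene_symbol = c(sym, nsmp_sym),
                    is_nsmp = rep(c(FALSE, TRUE), c(n_target, spec$nsmp_count)),
                    target_sequence = random_sequence(n_total),
                    stringsAsFactors = FALSE)
  class(out) <- c("probeset_annotation", "data.frame")
  out
}

#' Generate a synthetic expression matrix with known ground truth
#'
#' Treatment samples add the gene's regime effect to each probeset's
#' baseline: nothing for null genes, a shared shift for concordant genes,
#' and opposite half-`switch_delta` shifts for the two implanted groups of
#' switch genes. Absent probesets and NSMPs draw their baseline from the
#' background distribution and carry no effect. Gaussian noise of
#' `noise_sd` is added per measurement.
#'
#' @param spec a [fixture_spec()].
#' @param platform annotation from [generate_platform()] (regenerated from
#'   the spec when omitted).
#' @return a list with `expression` (log2 matrix), `design`
#'   ([group_design()]), and `truth` (lists of per-gene regimes and
#'   per-probeset assignments).
#' @export
generate_expression <- function(spec, platform = NULL) {
  if (is.null(platform)) platform <- generate_platform(spec)
  set.seed(spec$seed + 1L)
  targets <- platform[!platform$is_nsmp, , drop = FALSE]
  genes <- unique(targets$gene_symbol)
  sizes <- table(targets$gene_symbol)[genes]
  multi <- genes[sizes >= 2]

  regime <- setNames(rep("null", length(genes)), genes)
  n_switch <- round(spec$switch_fraction * length(multi))
  switch_genes <- if (n_switch > 0) sample(multi, n_switch) else character(0)
  regime[switch_genes] <- "switch"
  rest <- setdiff(genes, switch_genes)
  n_chg <- round(spec$expression_change_fraction * length(rest))
  chg <- if (n_chg > 0) sample(rest, n_chg) else character(0)
  regime[chg[seq_len(floor(n_chg / 2))]] <- "concordant_up"
  if (n_chg > floor(n_chg / 2)) {
    regime[chg[(floor(n_chg / 2) + 1):n_chg]] <- "concordant_down"
  }

  np <- nrow(targets)
  group <- rep(NA_character_, np)
  effect <- numeric(np)
  for (g in genes) {
    ix <- which(targets$gene_symbol == g)
    effect[ix] <- switch(regime[[g]],
                         null = 0,
                         concordant_up = spec$expression_change_magnitude,
                         concordant_down = -spec$expression_change_magnitude,
                         switch = 0)
    if (regime[[g]] == "switch") {
      k <- length(ix)
      n_a <- sample.int(k - 1, 1)
      a <- sample(ix, n_a)
      group[a] <- "A"; group[setdiff(ix, a)] <- "B"
      effect[a] <- spec$switch_delta / 2
      effect[setdiff(ix, a)] <- -spec$switch_delta / 2
    }
  }

  n_absent <- round(spec$absent_fraction * np)
  absent <- rep(FALSE, np)
  if (n_absent > 0) absent[sample.int(np, n_absent)] <- TRUE
  effect[absent] <- 0

  baseline <- stats::rnorm(np, spec$baseline_mean, spec$baseline_sd)
  baseline[absent] <- stats::rnorm(sum(absent), spec$background_mean,
                                   spec$background_sd)
  nsmp_n <- spec$nsmp_count
  nsmp_baseline <- stats::rnorm(nsmp_n, spec$background_mean, spec$background_sd)

  samples <- c(sprintf("ctrl_%02d", seq_len(spec$n_control)),
               sprintf("trt_%02d", seq_len(spec$n_treatment)))
  is_trt <- rep(c(0, 1), c(spec$n_control, spec$n_treatment))
  all_base <- c(baseline, nsmp_baseline)
  all_eff <- c(effect, numeric(nsmp_n))
  mean_mat <- outer(all_base, rep(1, length(samples))) +
    outer(all_eff, is_trt)
  mat <- mean_mat + matrix(stats::rnorm(length(mean_mat), 0, spec$noise_sd),
                           nrow(mean_mat))
  rownames(mat) <- c(targets$probeset_id,
                     platform$probeset_id[platform$is_nsmp])
  colnames(mat) <- samples
  attr(mat, "input_scale") <- "log2"

  design <- group_design(samples[is_trt == 0], samples[is_trt == 1])
  truth <- list(genes = data.frame(gene_symbol = genes,
                                   regime = unname(regime[genes]),
                                   stringsAsFactors = FALSE),
                probesets = data.frame(probeset_id = targets$probeset_id,
                                       gene_symbol = targets$gene_symbol,
                                       group = group,
                                       planted_absent = absent,
                                       stringsAsFactors = FALSE))
  list(expression = mat, design = design, truth = truth)
}

#' Generate a complete fixture (platform + expression + truth)
#'
#' @param spec a [fixture_spec()].
#' @return a list with `annotation`, `expression`, `design`, `truth`, and
#'   the `spec` itself.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  platform <- generate_platform(spec)
  ex <- generate_expression(spec, platform)
  list(annotation = platform, expression = ex$expression,
       design = ex$design, truth = ex$truth, spec = spec)
}

#' Score ideal-candidate calls against the generator's ground truth
#'
#' A switch gene counts as *testable* when it was fitted and both implanted
#' probeset groups still have at least one member among the fitted
#' probesets (a switch whose discriminating probesets were filtered out as
#' background-level is undetectable by construction). Sensitivity is the
#' fraction of testable switch genes flagged as ideal candidates with the
#' implanted partition recovered exactly (A = implanted up group); the
#' false-discovery rate is the fraction of ideal-candidate calls whose true
#' regime is not a switch.
#'
#' @param scored output of [score_and_rank()].
#' @param assignments the `assignments` element of [fit_all_genes()].
#' @param truth the `truth` element of a generated fixture.
#' @return a list with `sensitivity`, `fdr`, `n_testable_switch`,
#'   `n_calls`, and `n_true_positive`.
#' @export
evaluate_against_truth <- function(scored, assignments, truth) {
  switch_genes <- truth$genes$gene_symbol[truth$genes$regime == "switch"]
  tp <- 0L; testable <- 0L
  for (g in switch_genes) {
    fitted <- assignments[assignments$gene_symbol == g, , drop = FALSE]
    if (nrow(fitted) < 2) next
    planted <- truth$probesets[match(fitted$probeset_id,
                                     truth$probesets$probeset_id), "group"]
    if (!all(c("A", "B") %in% planted)) next
    testable <- testable + 1L
    called <- scored$ideal_candidate[scored$gene_symbol == g]
    if (length(called) == 1 && called && all(fitted$group == planted)) {
      tp <- tp + 1L
    }
  }
  calls <- scored$gene_symbol[scored$ideal_candidate]
  fp <- sum(!calls %in% switch_genes)
  list(sensitivity = if (testable > 0) tp / testable else NA_real_,
       fdr = if (length(calls) > 0) fp / length(calls) else 0,
       n_testable_switch = testable, n_calls = length(calls),
       n_true_positive = tp)
}

#' Write a fixture's annotation as a platform CSV
#'
#' Uses the Affymetrix-style column names the default
#' [annotation_dialect()] expects; unannotated symbols are written as
#' `---`, NSMP status as a TRUE/FALSE column.
#'
#' @param annotation a `probeset_annotation` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  df <- data.frame(`Probe Set ID` = annotation$probeset_id,
                   `Gene Symbol` = ifelse(is.na(annotation$gene_symbol),
                                          "---", annotation$gene_symbol),
                   NSMP = annotation$is_nsmp,
                   `Target Sequence` = ifelse(is.na(annotation$target_sequence),
                                              "", annotation$target_sequence),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = TRUE, row.names = FALSE)
  invisible(path)
}

#' Write a sample design table
#'
#' @param design a [group_design()].
#' @param path output path (TSV with `sample_id` and `group` columns).
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  df <- data.frame(sample_id = c(design$control, design$treatment),
                   group = rep(c("control", "treatment"),
                               c(length(design$control), length(design$treatment))),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
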