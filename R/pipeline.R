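#' Full run configuration
#'
#' Bundles every tunable of a comparison run: the declared input scale, the
#' significance level for the ideal-candidate flag, the weighting, mixture
#' and modifier parameters, and the presence-filtering settings.
#'
#' @param input_scale `"log2"` or `"linear"` (how the expression file was
#'   normalized).
#' @param alpha ideal-candidate significance threshold, default 0.01.
#' @param weight a [weight_config()].
#' @param fit a [fit_config()].
#' @param modifiers a [modifier_config()].
#' @param panp_enabled run PANP presence filtering? Requires >= 20 NSMPs.
#' @param alpha_present per-sample detection level for presence calls.
#' @param group_rule presence rule per group (`"majority"`, `"any"`,
#'   `"all"`).
#' @param write_fasta write one FASTA of probeset target sequences per
#'   tested gene?
#' @param seed integer recorded in the run log and used by any stochastic
#'   step (the comparison itself is deterministic).
#' @return an object of class `splicerav_config`.
#' @export
splicerav_config <- function(input_scale = c("log2", "linear"),
                             alpha = 0.01,
                             weight = weight_config(),
                             fit = fit_config(),
                             modifiers = modifier_config(),
                             panp_enabled = TRUE,
                             alpha_present = 0.05,
                             group_rule = "majority",
                             write_fasta = FALSE,
                             seed = 1L) {
  structure(list(input_scale = match.arg(input_scale), alpha = alpha,
                 weight = weight, fit = fit, modifiers = modifiers,
                 panp_enabled = panp_enabled, alpha_present = alpha_present,
                 group_rule = group_rule, write_fasta = write_fasta,
                 seed = seed),
            class = "splicerav_config")
}

as_expression <- function(expression, input_scale) {
  if (is.character(expression)) read_expression(expression, input_scale)
  else expression
}

as_annotation <- function(annotation, dialect) {
  if (is.character(annotation)) read_annotation(annotation, dialect)
  else annotation
}

as_design <- function(design) {
  if (is.character(design)) read_design(design) else design
}

#' Run a full control-vs-treatment isoform comparison
#'
#' The two-step procedure end to end: per-probeset differential-expression
#' summaries and weights, then the per-gene mixture likelihood-ratio test,
#' modifier scoring, ranking, and splice-index definitions. Inputs may be
#' file paths or in-memory objects. All outputs are computed before any
#' file is written, so a failing run leaves no partial results behind, and
#' the run is deterministic: repeated runs produce byte-identical files.
#'
#' Output files in `out_dir`:
#' * `splicerav_results.tsv` - ranked gene table (splice score, log MLR,
#'   p-value, group means, modifiers, A/B probeset lists, ideal-candidate
#'   flag).
#' * `probeset_summaries.tsv` - per-probeset fold changes, t-tests,
#'   presence calls, weights, and A/B assignment.
#' * `index_definitions.tsv` - one splice-index definition per probeset of
#'   every tested gene.
#' * `run_log.txt` - all parameters, input dimensions, filter and skip
#'   tallies.
#' * `fasta/` - per-gene probeset target sequences (when enabled and
#'   sequences are available).
#'
#' @param expression expression matrix or TSV path (probesets x samples).
#' @param annotation `probeset_annotation` data frame or annotation CSV
#'   path.
#' @param design [group_design()] or design-table path.
#' @param out_dir output directory, created if needed; `NULL` skips all
#'   file output.
#' @param config a [splicerav_config()].
#' @param dialect an [annotation_dialect()] used when `annotation` is a
#'   path.
#' @return invisibly, a list with `results`, `probesets`, `definitions`,
#'   `assignments`, `filter_report`, `skipped`, and `paths`.
#' @export
run_compare <- function(expression, annotation, design, out_dir = NULL,
                        config = splicerav_config(),
                        dialect = annotation_dialect()) {
  mat <- as_expression(expression, config$input_scale)
  annot <- as_annotation(annotation, dialect)
  design <- as_design(design)
  check_design(design, mat)

  calls <- NULL
  if (config$panp_enabled) {
    nsmp_ids <- intersect(annot$probeset_id[annot$is_nsmp], rownames(mat))
    calls <- panp_detection(mat, nsmp_ids, design,
                            alpha_present = config$alpha_present,
                            group_rule = config$group_rule)
  }
  filt <- filter_probesets(mat, calls, annot)

  summaries <- probeset_summary_table(filt$matrix, design, annot,
                                      config$weight)
  fit <- fit_all_genes(summaries, config$fit)
  scored <- score_and_rank(fit$fits, config$modifiers, config$alpha)
  if (nrow(scored) == 0) {
    warnf("no gene with multiple probesets survived filtering; results table is empty")
  }
  defs <- build_index_definitions(fit$assignments)

  # attach presence flags and A/B assignment to the probeset table
  if (!is.null(calls)) {
    idx <- match(summaries$probeset_id, calls$calls$probeset_id)
    summaries$present_in_control <- calls$calls$present_in_control[idx]
    summaries$present_in_treatment <- calls$calls$present_in_treatment[idx]
  } else {
    summaries$present_in_control <- NA
    summaries$present_in_treatment <- NA
  }
  aidx <- match(summaries$probeset_id, fit$assignments$probeset_id)
  summaries$group <- ifelse(is.na(aidx), "", fit$assignments$group[aidx])

  # per-gene A/B probeset lists for the results table
  ab_list <- function(genes, grp) {
    vapply(genes, function(g) {
      a <- fit$assignments[fit$assignments$gene_symbol == g, , drop = FALSE]
      paste(a$probeset_id[a$group == grp], collapse = ",")
    }, character(1))
  }
  if (nrow(scored)) {
    scored$probesets_A <- ab_list(scored$gene_symbol, "A")
    scored$probesets_B <- ab_list(scored$gene_symbol, "B")
  } else {
    scored$probesets_A <- character(0)
    scored$probesets_B <- character(0)
  }

  paths <- list()
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths$results <- file.path(out_dir, "splicerav_results.tsv")
    paths$probesets <- file.path(out_dir, "probeset_summaries.tsv")
    paths$definitions <- file.path(out_dir, "index_definitions.tsv")
    paths$log <- file.path(out_dir, "run_log.txt")
    write_result_table(scored, paths$results)
    write_result_table(summaries, paths$probesets)
    write_result_table(defs, paths$definitions)
    write_run_log(paths$log, config, design, mat, filt, fit, scored)
    if (config$write_fasta && any(!is.na(annot$target_sequence))) {
      fasta_dir <- file.path(out_dir, "fasta")
      groups <- group_by_gene(annot)
      tested <- unique(fit$assignments$gene_symbol)
      for (g in intersect(tested, names(groups))) {
        write_gene_fasta(g, groups[[g]], annot, fasta_dir)
      }
      paths$fasta <- fasta_dir
    }
  }

  invisible(list(results = scored, probesets = summaries, definitions = defs,
                 assignments = fit$assignments, filter_report = filt$report,
                 skipped = fit$skipped, paths = paths))
}

#' Score splice-index definitions on a (validation) cohort
#'
#' Computes every usable index on the supplied matrix and dichotomizes each
#' at its cohort median; definitions referencing probesets the matrix lacks
#' are skipped and logged.
#'
#' @param definitions data frame from [build_index_definitions()] (or the
#'   `index_definitions.tsv` path of a previous run).
#' @param expression log2 expression matrix or TSV path for the cohort.
#' @param out_dir output directory (`splice_index.tsv`,
#'   `index_labels.tsv`, `index_log.txt`); `NULL` skips file output.
#' @param input_scale scale of the expression file.
#' @return invisibly, a list with `index` (wide per-sample values),
#'   `labels` (long per-definition, per-sample high/low labels), and
#'   `skipped`.
#' @export
run_index <- function(definitions, expression, out_dir = NULL,
                      input_scale = c("log2", "linear")) {
  if (is.character(definitions)) {
    definitions <- utils::read.delim(definitions, stringsAsFactors = FALSE,
                                     check.names = FALSE)
  }
  mat <- as_expression(expression, match.arg(input_scale))
  tab <- compute_index_table(definitions, mat)
  if (nrow(tab$index) == 0) {
    stopf("no index definition references probesets present in the matrix")
  }
  samples <- colnames(mat)
  labels <- do.call(rbind, lapply(seq_len(nrow(tab$index)), function(i) {
    vals <- as.numeric(tab$index[i, samples])
    names(vals) <- samples
    lab <- suppressWarnings(dichotomize(vals))
    data.frame(gene_symbol = tab$index$gene_symbol[i],
               probeset_id = tab$index$probeset_id[i],
               direction_hypothesis = tab$index$direction_hypothesis[i],
               sample_id = samples, index = unname(vals),
               label = unname(lab), stringsAsFactors = FALSE)
  }))
  paths <- list()
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths$index <- file.path(out_dir, "splice_index.tsv")
    paths$labels <- file.path(out_dir, "index_labels.tsv")
    paths$log <- file.path(out_dir, "index_log.txt")
    write_result_table(tab$index, paths$index)
    write_result_table(labels, paths$labels)
    lines <- c(sprintf("definitions supplied = %d", nrow(definitions)),
               sprintf("definitions usable = %d", nrow(tab$index)),
               sprintf("samples = %d", length(samples)))
    if (nrow(tab$skipped)) {
      lines <- c(lines, "skipped definitions:",
                 sprintf("  %s/%s: %s", tab$skipped$gene_symbol,
                         tab$skipped$probeset_id, tab$skipped$reason))
    }
    writeLines(lines, paths$log)
  }
  invisible(list(index = tab$index, labels = labels, skipped = tab$skipped,
                 paths = paths))
}

#' Generate and write a synthetic fixture
#'
#' Writes `expression.tsv`, `annotation.csv`, `design.tsv`, and the ground
#' truth (`truth_genes.tsv`, `truth_probesets.tsv`) for a [fixture_spec()].
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory.
#' @return invisibly, the fixture list from [generate_fixture()] with a
#'   `paths` element added.
#' @export
run_simulate <- function(spec = fixture_spec(), out_dir) {
  fx <- generate_fixture(spec)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list(expression = file.path(out_dir, "expression.tsv"),
                annotation = file.path(out_dir, "annotation.csv"),
                design = file.path(out_dir, "design.tsv"),
                truth_genes = file.path(out_dir, "truth_genes.tsv"),
                truth_probesets = file.path(out_dir, "truth_probesets.tsv"))
  write_expression(fx$expression, paths$expression)
  write_annotation(fx$annotation, paths$annotation)
  write_design(fx$design, paths$design)
  utils::write.table(fx$truth$genes, paths$truth_genes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fx$truth$probesets, paths$truth_probesets, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fx$paths <- paths
  invisible(fx)
}

# user-facing tables: 6 significant digits, tab-separated, no quoting
write_result_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- fmt_sig6(out[[j]])
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_run_log <- function(path, config, design, mat, filt, fit, scored) {
  m <- config$modifiers; w <- config$weight; f <- config$fit
  reasons <- table(filt$report$reason)
  skip_reasons <- table(fit$skipped$reason)
  lines <- c(
    "splicerav run log",
    sprintf("input_scale = %s", config$input_scale),
    sprintf("alpha = %g", config$alpha),
    sprintf("wt_scale = %g", w$wt_scale),
    sprintf("alpha_tnorm = %g", w$alpha_tnorm),
    sprintf("sigma_floor = %g", f$sigma_floor),
    sprintf("max_probesets_exhaustive = %d", f$max_probesets_exhaustive),
    sprintf("em_restarts = %d", f$em_restarts),
    sprintf("min_fold_change = %g", m$min_fold_change),
    sprintf("sharpness = %g", m$sharpness),
    sprintf("full_penalty = %g", m$full_penalty),
    sprintf("centering_bonus = %g", m$centering_bonus),
    sprintf("centering_penalty = %g", m$centering_penalty),
    sprintf("normalize_by_avg_obs = %s", m$normalize_by_avg_obs),
    sprintf("modifiers_enabled = multiprobeset:%s cutoff:%s centering:%s",
            m$enable_multiprobeset, m$enable_cutoff, m$enable_centering),
    sprintf("panp_enabled = %s", config$panp_enabled),
    sprintf("alpha_present = %g", config$alpha_present),
    sprintf("group_rule = %s", config$group_rule),
    sprintf("seed = %s", config$seed),
    sprintf("control_samples = %s", paste(design$control, collapse = ",")),
    sprintf("treatment_samples = %s", paste(design$treatment, collapse = ",")),
    sprintf("probesets_in_matrix = %d", nrow(mat)),
    sprintf("probesets_after_filtering = %d", nrow(filt$matrix)),
    sprintf("probesets_removed = %d", nrow(filt$report)),
    sprintf("removed_by_reason = %s",
            paste(sprintf("%s:%d", names(reasons), as.integer(reasons)),
                  collapse = " ")),
    sprintf("genes_tested = %d", nrow(scored)),
    sprintf("genes_skipped = %d", nrow(fit$skipped)),
    sprintf("skipped_by_reason = %s",
            paste(sprintf("%s:%d", names(skip_reasons),
                          as.integer(skip_reasons)), collapse = " ")),
    sprintf("ideal_candidates = %d", sum(scored$ideal_candidate))
  )
  writeLines(lines, path)
  invisible(path)
}
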