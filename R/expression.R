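#' Read a probeset-by-sample expression matrix
#'
#' Expects a tab-delimited file whose first column holds probeset ids and
#' whose header row holds sample ids (MAS5 or RMA probeset summaries).
#' Values are stored internally on the log2 scale; linear-scale input is
#' transformed once on load and must be strictly positive.
#'
#' @param path path to the TSV file.
#' @param input_scale `"log2"` (RMA-style, default) or `"linear"`
#'   (MAS5-style); declare the scale your normalization produced.
#' @return a numeric matrix (log2 scale) with probeset rownames and sample
#'   colnames; the declared scale is recorded in attribute `input_scale`.
#' @export
read_expression <- function(path, input_scale = c("log2", "linear")) {
  input_scale <- match.arg(input_scale)
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("expression file %s has no sample columns", path)
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stopf("duplicate probeset ids in %s: %s", path,
                         paste(utils::head(dup, 10), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]) | is.na(vals[[j]]))
    if (length(bad)) {
      stopf("non-numeric or missing value in %s at row %d, column '%s'",
            path, bad[1] + 1L, names(vals)[j])
    }
    vals[[j]] <- v
  }
  mat <- as.matrix(vals)
  rownames(mat) <- ids
  if (input_scale == "linear") {
    if (any(mat <= 0)) {
      w <- which(mat <= 0, arr.ind = TRUE)[1, ]
      stopf("linear-scale intensities must be positive; value <= 0 at probeset '%s', sample '%s'",
            ids[w[1]], colnames(mat)[w[2]])
    }
    mat <- log2(mat)
  }
  attr(mat, "input_scale") <- input_scale
  mat
}

#' Write an expression matrix as TSV
#'
#' Values are written with full double precision so that a write/read
#' round trip is bit-identical.
#'
#' @param mat numeric matrix, probesets x samples (log2 scale).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("probeset_id", colnames(mat)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], fmt_full(mat[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Define the control/treatment sample design
#'
#' @param control,treatment disjoint character vectors of sample ids, each of
#'   length >= 2 (the homoskedastic t-statistic needs two observations per
#'   group).
#' @return an object of class `group_design`.
#' @export
group_design <- function(control, treatment) {
  control <- as.character(control); treatment <- as.character(treatment)
  if (length(control) < 2 || length(treatment) < 2) {
    stopf("each group needs >= 2 samples (got %d control, %d treatment)",
          length(control), length(treatment))
  }
  both <- intersect(control, treatment)
  if (length(both)) stopf("samples in both groups: %s", paste(both, collapse = ", "))
  structure(list(control = control, treatment = treatment), class = "group_design")
}

#' Read a sample design table
#'
#' Two columns, `sample_id` and `group` (values `control`/`treatment`);
#' TSV or CSV.
#'
#' @param path path to the design file.
#' @return a [group_design()].
#' @export
read_design <- function(path) {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(df))) {
    stopf("design file %s must have columns: %s", path, paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$group), c("control", "treatment"))
  if (length(bad)) stopf("design file %s: unknown group value(s): %s",
                         path, paste(bad, collapse = ", "))
  group_design(df$sample_id[df$group == "control"],
               df$sample_id[df$group == "treatment"])
}

check_design <- function(design, mat) {
  all_s <- c(design$control, design$treatment)
  missing <- setdiff(all_s, colnames(mat))
  if (length(missing)) {
    stopf("design samples absent from expression matrix: %s",
          paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' PANP-style detection calls from NSMP intensities
#'
#' For each sample, the intensities of negative-strand-matching probesets
#' (NSMPs) form an empirical null for "not expressed above background". The
#' detection p-value of probeset p in sample s is the fraction of that
#' sample's NSMP intensities at or above p's intensity (ties count as
#' exceedance, the conservative direction). A probeset is present in a group
#' when, under the chosen rule, its samples have detection p below
#' `alpha_present` (default: a strict majority).
#'
#' Detection is refused below 20 NSMPs: the empirical 5th percentile of the
#' null is meaningless at lower resolution.
#'
#' @param mat log2 expression matrix.
#' @param nsmp_ids probeset ids to use as the empirical null; must all be
#'   rows of `mat`.
#' @param design a [group_design()].
#' @param alpha_present per-sample detection significance level.
#' @param group_rule `"majority"` (> 50% of the group's samples detected),
#'   `"any"`, or `"all"`.
#' @return a list of class `panp_calls` with elements `detection_p`
#'   (probesets x design samples matrix) and `calls` (data frame with
#'   `probeset_id`, `present_in_control`, `present_in_treatment`).
#' @export
panp_detection <- function(mat, nsmp_ids, design, alpha_present = 0.05,
                           group_rule = c("majority", "any", "all")) {
  group_rule <- match.arg(group_rule)
  check_design(design, mat)
  missing <- setdiff(nsmp_ids, rownames(mat))
  if (length(missing)) {
    stopf("NSMP probesets absent from expression matrix: %s",
          paste(utils::head(missing, 10), collapse = ", "))
  }
  if (length(nsmp_ids) < 20) {
    stopf(paste("only %d NSMP probesets available (>= 20 required for a usable",
                "empirical null); supply an explicit keep-list or disable",
                "presence filtering"), length(nsmp_ids))
  }
  samples <- c(design$control, design$treatment)
  sub <- mat[, samples, drop = FALSE]
  nsmp <- mat[nsmp_ids, samples, drop = FALSE]
  detp <- matrix(NA_real_, nrow(sub), ncol(sub),
                 dimnames = list(rownames(sub), samples))
  for (s in seq_along(samples)) {
    null_sorted <- sort(nsmp[, s])
    n <- length(null_sorted)
    # count of null values >= x, via rank in the sorted null
    below <- findInterval(sub[, s], null_sorted, left.open = TRUE)
    detp[, s] <- (n - below) / n
  }
  present <- function(sample_set) {
    d <- detp[, sample_set, drop = FALSE] < alpha_present
    switch(group_rule,
           majority = rowMeans(d) > 0.5,
           any = apply(d, 1, any),
           all = apply(d, 1, all))
  }
  calls <- data.frame(probeset_id = rownames(sub),
                      present_in_control = present(design$control),
                      present_in_treatment = present(design$treatment),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(detection_p = detp, calls = calls,
                 alpha_present = alpha_present, group_rule = group_rule),
            class = "panp_calls")
}

#' Remove NSMP and background-level probesets
#'
#' Drops (i) NSMP probesets and (ii) probesets not expressed above background
#' in either the control or the treatment group, the two classes of probesets
#' whose fold-change discrepancies do not reflect the target transcript.
#'
#' @param mat log2 expression matrix.
#' @param calls a `panp_calls` object from [panp_detection()], or `NULL` to
#'   filter on NSMP status alone.
#' @param annotation a `probeset_annotation` data frame (for NSMP flags);
#'   probesets absent from the annotation are kept.
#' @return a list with `matrix` (the filtered matrix) and `report` (data
#'   frame of removed probesets with a `reason` of `"nsmp"` or `"absent"`).
#' @export
filter_probesets <- function(mat, calls = NULL, annotation = NULL) {
  reason <- setNames(rep(NA_character_, nrow(mat)), rownames(mat))
  if (!is.null(annotation)) {
    nsmp <- annotation$probeset_id[annotation$is_nsmp]
    reason[rownames(mat) %in% nsmp] <- "nsmp"
  }
  if (!is.null(calls)) {
    absent <- calls$calls$probeset_id[!calls$calls$present_in_control &
                                      !calls$calls$present_in_treatment]
    sel <- rownames(mat) %in% absent & is.na(reason)
    reason[sel] <- "absent"
  }
  removed <- !is.na(reason)
  list(matrix = mat[!removed, , drop = FALSE],
       report = data.frame(probeset_id = rownames(mat)[removed],
                           reason = unname(reason[removed]),
                           row.names = NULL, stringsAsFactors = FALSE))
}
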