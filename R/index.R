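#' Build per-probeset splice-index definitions from a gene's A/B partition
#'
#' Each probeset of a partitioned gene defines one index: its log2
#' expression minus the mean log2 expression of the probesets in the
#' opposite group. A-group probesets carry the direction hypothesis `UP`
#' (predicted increased in the treatment/aggressive class of the training
#' comparison), B-group probesets `DOWN`; carrying the hypothesis forward
#' licenses one-sided tests in independent validation cohorts.
#'
#' @param assignments data frame with columns `gene_symbol`, `probeset_id`,
#'   `group` (`"A"`/`"B"`), e.g. the `assignments` element of
#'   [fit_all_genes()].
#' @return a data frame with one row per probeset: `gene_symbol`,
#'   `probeset_id`, `own_group`, `opposite_probesets` (comma-separated), and
#'   `direction_hypothesis`.
#' @export
build_index_definitions <- function(assignments) {
  pieces <- split(seq_len(nrow(assignments)), assignments$gene_symbol)
  out <- lapply(pieces[order(names(pieces))], function(ix) {
    rows <- assignments[ix, , drop = FALSE]
    if (!all(c("A", "B") %in% rows$group)) {
      stopf("gene %s has a degenerate partition (missing A or B group)",
            rows$gene_symbol[1])
    }
    opp <- vapply(seq_len(nrow(rows)), function(i) {
      paste(rows$probeset_id[rows$group != rows$group[i]], collapse = ",")
    }, character(1))
    data.frame(gene_symbol = rows$gene_symbol,
               probeset_id = rows$probeset_id,
               own_group = rows$group,
               opposite_probesets = opp,
               direction_hypothesis = ifelse(rows$group == "A", "UP", "DOWN"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res)) {
    res <- data.frame(gene_symbol = character(), probeset_id = character(),
                      own_group = character(), opposite_probesets = character(),
                      direction_hypothesis = character(), stringsAsFactors = FALSE)
  }
  res
}

#' Compute one splice index across samples
#'
#' Per sample: the probeset's log2 expression minus the mean log2 expression
#' of the opposite group's probesets. Computed entirely in log2 space, so it
#' is invariant to per-sample multiplicative (array-level) scaling.
#'
#' @param defn a single row of [build_index_definitions()] output (data
#'   frame or list).
#' @param mat log2 expression matrix containing all referenced probesets.
#' @return a named numeric vector, one index value per sample.
#' @export
compute_index <- function(defn, mat) {
  opp <- strsplit(defn$opposite_probesets, ",", fixed = TRUE)[[1]]
  need <- c(defn$probeset_id, opp)
  missing <- setdiff(need, rownames(mat))
  if (length(missing)) {
    stopf("probesets absent from matrix: %s", paste(missing, collapse = ", "))
  }
  own <- mat[defn$probeset_id, ]
  oppmean <- colMeans(mat[opp, , drop = FALSE])
  own - oppmean
}

#' Compute all usable splice indexes for a validation matrix
#'
#' Definitions referencing probesets absent from the matrix (platform
#' subset mismatches) are skipped and reported.
#'
#' @param definitions output of [build_index_definitions()].
#' @param mat log2 expression matrix.
#' @return a list with `index` (wide data frame: definition columns plus one
#'   column per sample) and `skipped` (data frame of unusable definitions
#'   with reasons).
#' @export
compute_index_table <- function(definitions, mat) {
  usable <- logical(nrow(definitions))
  reasons <- character(nrow(definitions))
  vals <- matrix(NA_real_, nrow(definitions), ncol(mat),
                 dimnames = list(NULL, colnames(mat)))
  for (i in seq_len(nrow(definitions))) {
    defn <- definitions[i, , drop = FALSE]
    opp <- strsplit(defn$opposite_probesets, ",", fixed = TRUE)[[1]]
    missing <- setdiff(c(defn$probeset_id, opp), rownames(mat))
    if (length(missing)) {
      reasons[i] <- paste("missing probesets:", paste(missing, collapse = ","))
      next
    }
    usable[i] <- TRUE
    vals[i, ] <- compute_index(defn, mat)
  }
  index <- cbind(definitions[usable, , drop = FALSE],
                 as.data.frame(vals[usable, , drop = FALSE]))
  rownames(index) <- NULL
  skipped <- data.frame(definitions[!usable, c("gene_symbol", "probeset_id")],
                        reason = reasons[!usable],
                        row.names = NULL, stringsAsFactors = FALSE)
  list(index = index, skipped = skipped)
}

#' Dichotomize index values at the cohort median
#'
#' Samples strictly above the median are labelled `"high"`; samples at or
#' below it `"low"` (ties at the median go to `"low"` by convention). A
#' constant vector yields all-`"low"` with a warning.
#'
#' @param values numeric index values (length >= 2), typically named by
#'   sample.
#' @return a character vector of `"high"`/`"low"` labels, names preserved.
#' @export
dichotomize <- function(values) {
  if (length(values) < 2) stopf("dichotomization needs >= 2 samples")
  med <- stats::median(values)
  if (all(values == values[1])) {
    warnf("all index values identical; every sample labelled 'low'")
    return(setNames(rep("low", length(values)), names(values)))
  }
  setNames(ifelse(values > med, "high", "low"), names(values))
}
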