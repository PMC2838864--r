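write_expr_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

strip_scale <- function(m) {
  attr(m, "input_scale") <- NULL
  unname(m)
}

test_that("expression input is stored as log2 and round-trips exactly", {
  path <- write_expr_tsv(c("probeset_id\ts1\ts2", "p1\t4\t8", "p2\t1\t2"))
  mat <- read_expression(path, input_scale = "linear")
  expect_equal(strip_scale(mat), matrix(c(2, 0, 3, 1), 2))

  mat2 <- read_expression(path, input_scale = "log2")
  expect_equal(strip_scale(mat2), matrix(c(4, 1, 8, 2), 2))

  set.seed(5)
  big <- matrix(rnorm(500, 8, 2), 50, 10,
                dimnames = list(paste0("p", 1:50), paste0("s", 1:10)))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_expression(big, tmp)
  back <- read_expression(tmp, "log2")
  expect_identical(strip_scale(back), unname(big))  # bit-identical round trip
})

test_that("malformed expression input is rejected with location info", {
  expect_error(
    read_expression(write_expr_tsv(c("id\ts1", "p1\t1", "p1\t2")), "log2"),
    "duplicate.*p1")
  expect_error(
    read_expression(write_expr_tsv(c("id\ts1\ts2", "p1\t1\tx")), "log2"),
    "row 2.*s2")
  expect_error(
    read_expression(write_expr_tsv(c("id\ts1", "p1\t0")), "linear"),
    "positive")
})

test_that("design groups must be disjoint, sized, and present in the matrix", {
  expect_error(group_design("a", c("c", "d")), ">= 2")
  expect_error(group_design(c("a", "b"), c("b", "c")), "both groups")
  mat <- matrix(0, 2, 4, dimnames = list(c("p1", "p2"), letters[1:4]))
  d <- group_design(c("a", "b"), c("c", "z"))
  expect_error(panp_detection(mat, "p1", d), "absent")
})

make_panp_matrix <- function(n_nsmp = 25, seed = 2) {
  set.seed(seed)
  samples <- c(paste0("c", 1:4), paste0("t", 1:4))
  nsmp <- matrix(rnorm(n_nsmp * 8, 4, 1), n_nsmp, 8)
  rownames(nsmp) <- paste0("n", seq_len(n_nsmp))
  nsmp
}

test_that("detection p-values are empirical NSMP exceedance probabilities", {
  nsmp <- make_panp_matrix()
  samples <- c(paste0("c", 1:4), paste0("t", 1:4))
  probes <- rbind(high = rep(100, 8),
                  med = apply(nsmp, 2, median))
  mat <- rbind(probes, nsmp)
  colnames(mat) <- samples
  d <- group_design(paste0("c", 1:4), paste0("t", 1:4))
  calls <- panp_detection(mat, rownames(nsmp), d)
  expect_equal(unname(calls$detection_p["high", ]), rep(0, 8))
  # at the median of 25 nulls, 13 of 25 values are >= the probe
  expect_true(all(abs(calls$detection_p["med", ] - 0.5) < 0.06))
  cl <- calls$calls
  expect_true(cl$present_in_control[cl$probeset_id == "high"])
  expect_false(cl$present_in_control[cl$probeset_id == "med"])
})

test_that("presence follows the majority rule against the generated null", {
  nsmp <- make_panp_matrix(seed = 3)
  samples <- c(paste0("c", 1:4), paste0("t", 1:4))
  x <- rep(2, 8)                      # below background everywhere ...
  x[1:3] <- max(nsmp) + 1             # ... except 3 of 4 control samples
  mat <- rbind(x = x, nsmp)
  colnames(mat) <- samples
  d <- group_design(paste0("c", 1:4), paste0("t", 1:4))
  calls <- panp_detection(mat, rownames(nsmp), d)
  expect_true(calls$calls$present_in_control[1])
  expect_false(calls$calls$present_in_treatment[1])
  # under the "all" rule the same probeset is not present
  calls_all <- panp_detection(mat, rownames(nsmp), d, group_rule = "all")
  expect_false(calls_all$calls$present_in_control[1])
})

test_that("detection p-values are rank-based (monotone-transform invariant)", {
  set.seed(9)
  samples <- c(paste0("c", 1:3), paste0("t", 1:3))
  mat <- matrix(rnorm(60 * 6, 5, 2), 60, 6,
                dimnames = list(paste0("p", 1:60), samples))
  d <- group_design(paste0("c", 1:3), paste0("t", 1:3))
  nsmp <- paste0("p", 1:30)
  p1 <- panp_detection(mat, nsmp, d)$detection_p
  p2 <- panp_detection(exp(mat / 3), nsmp, d)$detection_p
  expect_identical(p1, p2)
})

test_that("a null matrix is called present at about the nominal rate", {
  set.seed(13)
  samples <- c(paste0("c", 1:3), paste0("t", 1:3))
  nsmp_ids <- paste0("n", 1:99)
  mat <- matrix(rnorm(499 * 6, 4, 1), 499, 6,
                dimnames = list(c(nsmp_ids, paste0("p", 1:400)), samples))
  d <- group_design(paste0("c", 1:3), paste0("t", 1:3))
  detp <- panp_detection(mat, nsmp_ids, d)$detection_p[paste0("p", 1:400), ]
  frac <- mean(detp < 0.05)
  expect_lt(abs(frac - 0.05), 0.02)
})

test_that("filtering removes NSMP and both-absent probesets, and only those", {
  nsmp <- make_panp_matrix(seed = 4)
  samples <- c(paste0("c", 1:4), paste0("t", 1:4))
  mat <- rbind(ok1 = rep(10, 8), ok2 = rep(9, 8), gone = rep(2, 8), nsmp)
  colnames(mat) <- samples
  d <- group_design(paste0("c", 1:4), paste0("t", 1:4))
  annot <- data.frame(probeset_id = rownames(mat),
                      gene_symbol = "G",
                      is_nsmp = grepl("^n", rownames(mat)),
                      stringsAsFactors = FALSE)
  calls <- panp_detection(mat, rownames(nsmp), d)
  filt <- filter_probesets(mat, calls, annot)
  expect_setequal(rownames(filt$matrix), c("ok1", "ok2"))
  expect_setequal(unique(filt$report$reason), c("nsmp", "absent"))
  expect_equal(filt$report$reason[filt$report$probeset_id == "gone"], "absent")

  # idempotent: filtering the filtered matrix removes nothing
  calls2 <- panp_detection(rbind(filt$matrix, nsmp), rownames(nsmp), d)
  filt2 <- filter_probesets(filt$matrix, calls2, annot)
  expect_identical(filt2$matrix, filt$matrix)
  expect_equal(nrow(filt2$report), 0)
})

test_that("planted background probesets are exactly the ones removed", {
  # degenerate background (every NSMP and absent probeset exactly at the
  # background level) makes the planted set the provably removed set:
  # ties count as exceedance, so planted probesets get detection p = 1
  spec <- fixture_spec(n_genes = 60, absent_fraction = 0.1, noise_sd = 0,
                       baseline_mean = 12, baseline_sd = 1,
                       background_mean = 3, background_sd = 0, seed = 21)
  fx <- generate_fixture(spec)
  nsmp_ids <- fx$annotation$probeset_id[fx$annotation$is_nsmp]
  calls <- panp_detection(fx$expression, nsmp_ids, fx$design)
  filt <- filter_probesets(fx$expression, calls, fx$annotation)
  planted <- fx$truth$probesets$probeset_id[fx$truth$probesets$planted_absent]
  expect_setequal(filt$report$probeset_id[filt$report$reason == "absent"],
                  planted)
  expect_setequal(filt$report$probeset_id[filt$report$reason == "nsmp"],
                  nsmp_ids)
})
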