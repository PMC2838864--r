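# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Weighted mean and (population) weighted SD.  Falls back to unweighted
# moments when the total weight is zero so that group parameters stay
# defined for zero-weight members (their likelihood contribution is zero
# either way).
weighted_moments <- function(x, w) {
  W <- sum(w)
  if (W > 0) {
    mu <- sum(w * x) / W
    sd <- sqrt(sum(w * (x - mu)^2) / W)
  } else {
    mu <- mean(x)
    sd <- sqrt(mean((x - mu)^2))
  }
  list(mu = mu, sd = sd)
}

# full-precision numeric formatting (round-trips doubles exactly)
fmt_full <- function(x) sprintf("%.17g", x)

# 6 significant digits for user-facing tables; full precision kept in memory
fmt_sig6 <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    format(signif(v, 6), scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

sanitize_filename <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)
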