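# Independent oracles, deliberately written differently from the package
# internals (combn-based subset enumeration, bisection for quantiles).

# all bipartitions of 1..n into two nonempty unordered groups
all_bipartitions <- function(n) {
  out <- list()
  for (k in 1:floor(n / 2)) {
    subs <- utils::combn(n, k, simplify = FALSE)
    for (s in subs) {
      if (k == n - k && s[1] != 1) next  # avoid double-counting equal halves
      out[[length(out) + 1]] <- list(g1 = s, g2 = setdiff(1:n, s))
    }
  }
  out
}

# brute-force maximizer of the summed weighted Gaussian group likelihoods
oracle_two_group <- function(x, w, floor = 0.10) {
  stats_of <- function(ix) {
    W <- sum(w[ix])
    if (W > 0) {
      mu <- sum(w[ix] * x[ix]) / W
      s <- sqrt(sum(w[ix] * (x[ix] - mu)^2) / W)
    } else {
      mu <- mean(x[ix]); s <- sqrt(mean((x[ix] - mu)^2))
    }
    c(mu, max(s, floor))
  }
  ll_of <- function(ix, p) sum(w[ix] * dnorm(x[ix], p[1], p[2], log = TRUE))
  best <- NULL
  for (bp in all_bipartitions(length(x))) {
    p1 <- stats_of(bp$g1); p2 <- stats_of(bp$g2)
    ll <- ll_of(bp$g1, p1) + ll_of(bp$g2, p2)
    if (is.null(best) || ll > best$ll) {
      best <- list(ll = ll, g1 = bp$g1, g2 = bp$g2,
                   mu1 = p1[1], mu2 = p2[1])
    }
  }
  best
}

# two-tailed critical t value by CDF bisection (independent of qt)
oracle_t_crit <- function(alpha, df, lo = 0, hi = 1e4, tol = 1e-10) {
  target <- 1 - alpha / 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (stats::pt(mid, df) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# textbook pooled-variance two-sample t
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# do two A-group membership vectors describe the same bipartition?
same_partition <- function(a1, all1, a2) {
  setequal(a1, a2) || setequal(setdiff(all1, a1), a2)
}
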