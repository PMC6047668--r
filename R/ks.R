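# Kolmogorov-Smirnov machinery used by the rank-enrichment tests.
#
# The statistics are computed here rather than via stats::ks.test because
# the rank vectors carry midrank ties by design and the reported p-value is
# the asymptotic Kolmogorov tail probability with an explicit reporting
# floor; stats::ks.test serves as an independent cross-check in the test
# suite.

# Asymptotic Kolmogorov survival function Q(lambda) = P(K > lambda).
pkolmogorov_sf <- function(lambda) {
  if (is.na(lambda)) return(NA_real_)
  if (lambda <= 0) return(1)
  j <- seq_len(100L)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

# One-sample KS of x against the uniform distribution on (0, 1].
# Returns the sup-norm distance D and the asymptotic p-value.
ks_uniform <- function(x) {
  stopifnot(length(x) >= 1L, all(x >= 0), all(x <= 1))
  n <- length(x)
  x <- sort(x)
  i <- seq_len(n)
  D <- max(pmax(i / n - x, x - (i - 1) / n))
  list(D = D, p = pkolmogorov_sf(sqrt(n) * D), n = n)
}

# Two-sample KS; asymptotic p with effective sample size n1*n2/(n1+n2).
ks_two_sample <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  grid <- sort(unique(c(x, y)))
  Fx <- vapply(grid, function(g) mean(x <= g), 0)
  Fy <- vapply(grid, function(g) mean(y <= g), 0)
  D <- max(abs(Fx - Fy))
  n_eff <- length(x) * length(y) / (length(x) + length(y))
  list(D = D, p = pkolmogorov_sf(sqrt(n_eff) * D), n = n_eff)
}

# Reporting floor shared by all enrichment results ("P < 1e-15" convention).
P_FLOOR <- 1e-15

floor_p <- function(p) max(p, P_FLOOR)
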