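# Shared fixture builders; everything is generated in code at test time.

flat_contour <- function(length_mm = 30, n = 2) {
  tibble::tibble(x_mm = seq(0, length_mm, length.out = n),
                 y_mm = rep(0, n))
}

# Dense trapezoidal arc-length integration of an analytic profile: the
# second, independent integrator used against the adaptive quadrature.
trapezoid_ri <- function(profile, n = 1e6) {
  L <- profile$section_length_mm
  x <- seq(0, L, length.out = n + 1)
  dy <- rugosity:::profile_dy(profile, x)
  f <- sqrt(1 + dy^2)
  h <- L / n
  arc <- h * (sum(f) - (f[1] + f[length(f)]) / 2)
  100 * (arc - L) / L
}

# Independent Benjamini-Hochberg step-up written from the definition:
# q_(i) = min over j >= i of p_(j) * m / j.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Adjusted Rand index between two labelings, from the contingency-table
# definition.
rand_index_adjusted <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Random jagged open contour used for geometric property checks.
random_contour <- function(n = 40, seed = NULL) {
  gen <- function() {
    tibble::tibble(x_mm = sort(runif(n, 0, 30)),
                   y_mm = runif(n, -2, 2))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
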