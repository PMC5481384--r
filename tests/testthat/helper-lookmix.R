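# shared generators for the test suite

# a random valid mixture with both bands and widths >= 1 frame
random_mixture <- function() {
  b <- sample(-128:-10, 1)
  e <- sample(10:128, 1)
  looking_mixture(a = -130, b = b, e = e, f = 130,
                  pi = stats::runif(1), lam = stats::runif(1))
}

# a random trial series drawn from a random mixture
random_series <- function(T = sample(8:30, 1)) {
  sample_trials(random_mixture(), T, infant_id = "r", occasion = 3)
}

# cohort table from raw vectors
make_cohort <- function(pi_hat, d_bar, occasion = 3,
                        infant_id = paste0("i", seq_along(pi_hat))) {
  cohort_table(data.frame(
    infant_id = infant_id, occasion = occasion,
    pi_hat = pi_hat, d_bar = d_bar, T = 24,
    stringsAsFactors = FALSE
  ))
}

# exhaustive (pi, lam) grid-search log-likelihood at fixed endpoints,
# matching the fitter's width-floored likelihood; the brute-force oracle
grid_search_loglik <- function(d, a, b, e, f, n_grid = 201, min_width = 1) {
  w <- function(lo, hi) max(hi - lo, min_width)
  us <- ifelse(d >= a & d <= f, 1 / w(a, f), 0)
  un <- if (is.na(b)) rep(0, length(d)) else
    ifelse(d >= a & d <= b, 1 / w(a, b), 0)
  up <- if (is.na(e)) rep(0, length(d)) else
    ifelse(d >= e & d <= f, 1 / w(e, f), 0)
  pis <- seq(0, 1, length.out = n_grid)
  lams <- seq(0, 1, length.out = n_grid)
  best <- -Inf
  for (lam in lams) {
    ul <- lam * un + (1 - lam) * up
    for (pi in pis) {
      mix <- pi * us + (1 - pi) * ul
      if (all(mix > 0)) {
        ll <- sum(log(mix))
        if (ll > best) best <- ll
      }
    }
  }
  best
}
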