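# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths.

# fine-grid quadrature of a function by the composite trapezoid rule
quad_oracle <- function(f, a, b, n = 20000) {
  x <- seq(a, b, length.out = n)
  y <- f(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# brute-force terminal-window search: all suffixes of >= 3 points after
# Tmax, adjusted R^2 computed from squared correlation, ties (1e-4) to
# the longer window
brute_lambda_z <- function(t, conc) {
  tmax <- t[which.max(conc)]
  keep <- t > tmax & conc > 0
  tt <- t[keep]
  cc <- log(conc[keep])
  m <- length(tt)
  best <- NULL
  for (i in seq_len(max(m - 2, 0))) {
    ts <- tt[i:m]
    ys <- cc[i:m]
    k <- length(ts)
    slope <- cov(ts, ys) / var(ts)
    if (slope >= 0) next
    r2 <- cor(ts, ys)^2
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || adj > best$adj + 1e-4 ||
        (abs(adj - best$adj) <= 1e-4 && k > best$k)) {
      best <- list(adj = adj, k = k, lambda = -slope,
                   window = c(ts[1], ts[k]))
    }
  }
  best
}

# mono-exponential profile sampled at given times
mono_profile <- function(c0, lambda, times) {
  tibble::tibble(t = times, conc = c0 * exp(-lambda * times), blq = FALSE)
}

# default-parameter model for one obese-typical subject
example_model <- function(...) {
  args <- list(CL = 8.2, V1 = 20.5, V2 = 20.5, Q = 16.4, dose = 600,
               t_inf = 0.5, fu = 0.86, k_isf = 2, penetration = 0.53)
  args[names(list(...))] <- list(...)
  do.call(pk_model, args)
}

# noiseless single-subject cohort with fixed group parameters
noiseless_config <- function(n_per_group = 1, seed = 1, ...) {
  cohort_config(n_per_group = n_per_group, iiv_cv = 0,
                residual_cv = c(plasma = 0, dialysate = 0), seed = seed, ...)
}
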