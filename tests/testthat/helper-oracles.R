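# Independent oracles used to freeze expected values.

# free inhibitor-site fraction by bisection on the mass-balance equation:
# free * (1 + L_free/K) = ... solved directly in terms of bound complex c:
# (I - c)(L - c) = K c, 0 <= c <= min(I, L)
free_fraction_bisect <- function(I, L, K, tol = 1e-15) {
  if (L == 0) return(1)
  g <- function(c) (I - c) * (L - c) - K * c
  lo <- 0
  hi <- min(I, L)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (I - (lo + hi) / 2) / I
}

logit <- function(p) log(p / (1 - p))

# noiseless monoexponential sampled profile for NCA closed-form checks
monoexp_profile <- function(c0 = 100, t_half = 5, times = 0:30,
                            lloq = 1e-6) {
  concentration_profile(times, c0 * 2^(-times / t_half), lloq = lloq)
}
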