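# Independent oracles: brute-force path enumeration for the HMM and the
# untruncated O(n^2) direct weighted sum for the Gaussian smoother. These
# re-derive the model probabilities from scratch and never call the
# package's decoding/smoothing code paths.

oracle_transition_matrix <- function(d, K, stay1, decay, stay_min) {
  d <- min(max(d, 1), decay)
  stay <- max(stay_min, stay1^d)
  m <- matrix(if (K > 1) (1 - stay) / (K - 1) else 0, K, K)
  diag(m) <- stay
  m
}

# Exhaustive argmax over all K^n state paths. Returns the maximal log
# probability, whether the argmax is unique (beyond a tolerance), and the
# maximizing path (first in expand.grid order on ties).
brute_force_viterbi <- function(log_emit, positions, stay1, decay, stay_min,
                                tol = 1e-9) {
  n <- nrow(log_emit)
  K <- ncol(log_emit)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  lp <- log_emit[1, paths[, 1]] - log(K)
  if (n > 1) {
    for (t in 2:n) {
      m <- oracle_transition_matrix(positions[t] - positions[t - 1], K,
                                    stay1, decay, stay_min)
      lp <- lp + log(m[cbind(paths[, t - 1], paths[, t])]) +
        log_emit[t, paths[, t]]
    }
  }
  best <- which.max(lp)
  second <- if (length(lp) > 1) max(lp[-best]) else -Inf
  list(log_prob = lp[best],
       unique = lp[best] - second > tol,
       path = unname(paths[best, ]))
}

gaussian_emissions <- function(obs, means, sd) {
  vapply(means, function(m) stats::dnorm(obs, m, sd, log = TRUE),
         numeric(length(obs)))
}

loh_emissions <- function(is_loh, eps, pe) {
  cbind(ifelse(is_loh, log(eps), log(1 - eps)),
        ifelse(is_loh, log(pe), log(1 - pe)))
}

# Untruncated Gaussian kernel smoother, direct O(n^2) weighted sum.
smooth_oracle <- function(positions, values, sigma) {
  w <- exp(-outer(positions, positions, "-")^2 / (2 * sigma^2))
  as.vector((w %*% values) / rowSums(w))
}
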