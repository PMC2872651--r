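#' Copy-number HMM parameters
#'
#' Parameters of the hidden Markov model used to segment the smoothed log2
#' track. Hidden states are integer copy numbers with fixed Gaussian
#' emission means in log2 units (`log2(cn/2)`, with copy number 0 floored at
#' -3). Transitions are distance dependent: the probability of staying in
#' the same state over a gap of `d` bp is
#' `max(stay_min, stay_prob_at_1bp^min(d, decay_length))`, with the leave
#' probability split equally among the other states.
#'
#' @param states Ordered integer copy-number states.
#' @param state_means Emission means in log2 units, strictly increasing,
#'   one per state.
#' @param emission_sd Gaussian emission standard deviation (log2 units).
#' @param stay_prob_at_1bp Stay probability over a 1 bp gap.
#' @param decay_length Gap length (bp) at which transition decay saturates.
#' @param stay_min Lower bound on the stay probability.
#' @return A `cn_hmm_params` object.
#' @export
cn_hmm_params <- function(states = 0:4,
                          state_means = c(-3, -1, 0, log2(3 / 2), 1),
                          emission_sd = 0.25,
                          stay_prob_at_1bp = 1 - 1e-7,
                          decay_length = 1e7,
                          stay_min = 0.1) {
  if (length(states) != length(state_means) || length(states) < 1) {
    stop("states and state_means must have equal, positive length", call. = FALSE)
  }
  if (any(diff(state_means) <= 0)) {
    stop("state_means must be strictly increasing", call. = FALSE)
  }
  if (!(emission_sd > 0)) stop("emission_sd must be > 0", call. = FALSE)
  if (!(stay_prob_at_1bp > 0 && stay_prob_at_1bp < 1)) {
    stop("stay_prob_at_1bp must be in (0, 1)", call. = FALSE)
  }
  structure(list(states = states, state_means = state_means,
                 emission_sd = emission_sd,
                 stay_prob_at_1bp = stay_prob_at_1bp,
                 decay_length = decay_length, stay_min = stay_min),
            class = "cn_hmm_params")
}

#' LOH HMM parameters
#'
#' Parameters of the two-state (retention, loss) hidden Markov model used to
#' segment per-SNP LOH calls at informative (germline-heterozygous) SNPs.
#' Emissions are Bernoulli: in the retention state an informative SNP reads
#' as LOH with probability `miscall_rate` (genotyping error); in the loss
#' state with probability `loh_emission`. Transitions share the
#' distance-dependent form of [cn_hmm_params()]. Ties are broken toward
#' retention.
#'
#' @param miscall_rate P(LOH call | retention state).
#' @param loh_emission P(LOH call | loss state).
#' @param stay_prob_at_1bp,decay_length,stay_min As in [cn_hmm_params()].
#' @return A `loh_hmm_params` object.
#' @export
loh_hmm_params <- function(miscall_rate = 0.05,
                           loh_emission = 0.95,
                           stay_prob_at_1bp = 1 - 1e-7,
                           decay_length = 1e7,
                           stay_min = 0.1) {
  if (!(miscall_rate > 0 && miscall_rate < loh_emission && loh_emission < 1)) {
    stop("need 0 < miscall_rate < loh_emission < 1", call. = FALSE)
  }
  structure(list(states = c("retention", "loss"),
                 miscall_rate = miscall_rate, loh_emission = loh_emission,
                 stay_prob_at_1bp = stay_prob_at_1bp,
                 decay_length = decay_length, stay_min = stay_min),
            class = "loh_hmm_params")
}

# Log stay/leave probabilities over a gap of d bp.
.transition_logprobs <- function(d, n_states, stay_prob_at_1bp, decay_length, stay_min) {
  d <- min(max(d, 1), decay_length)
  stay <- max(stay_min, exp(d * log(stay_prob_at_1bp)))
  leave <- if (n_states > 1) (1 - stay) / (n_states - 1) else 0
  c(stay = log(stay), leave = if (n_states > 1) log(leave) else -Inf)
}

# Log-space Viterbi over a distance-dependent sticky chain.
# log_emit: n x K matrix; positions: sorted bp. Ties break toward the
# lower-index state at every maximization (which.max takes the first max).
.viterbi_core <- function(log_emit, positions, stay_prob_at_1bp, decay_length, stay_min) {
  n <- nrow(log_emit)
  K <- ncol(log_emit)
  if (n == 0) stop("empty observation sequence", call. = FALSE)
  if (K == 1) {
    return(list(path = rep(1L, n), log_prob = sum(log_emit[, 1])))
  }
  delta <- log_emit[1, ] - log(K)  # uniform initial distribution
  psi <- matrix(1L, nrow = n, ncol = K)
  if (n > 1) {
    for (t in 2:n) {
      tr <- .transition_logprobs(positions[t] - positions[t - 1], K,
                                 stay_prob_at_1bp, decay_length, stay_min)
      nd <- numeric(K)
      for (k in seq_len(K)) {
        cand <- delta + tr["leave"]
        cand[k] <- delta[k] + tr["stay"]
        j <- which.max(cand)
        psi[t, k] <- j
        nd[k] <- cand[j]
      }
      delta <- nd + log_emit[t, ]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1) {
    for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  }
  list(path = path, log_prob = max(delta))
}

.loh_log_emissions <- function(is_loh, params) {
  eps <- params$miscall_rate
  pe <- params$loh_emission
  cbind(
    retention = ifelse(is_loh, log(eps), log1p(-eps)),
    loss = ifelse(is_loh, log(pe), log1p(-pe))
  )
}

#' Viterbi decoding of a genomic observation sequence
#'
#' Returns the maximum-probability hidden state path for a position-sorted,
#' single-chromosome observation sequence, under a uniform initial
#' distribution, distance-dependent sticky transitions and either Gaussian
#' emissions (`cn_hmm_params`: observations are smoothed log2 ratios) or
#' Bernoulli emissions (`loh_hmm_params`: observations are logical LOH
#' flags, or the strings `"LOH"`/`"retention"`, at informative SNPs). All
#' arithmetic is in log space; ties break toward the lower-index state.
#'
#' @param observations Numeric vector (copy-number model) or logical /
#'   character vector (LOH model), one per SNP.
#' @param positions Sorted bp positions, same length as `observations`.
#' @param params A [cn_hmm_params()] or [loh_hmm_params()] object.
#' @return Vector of decoded states (integer copy numbers or
#'   `"retention"`/`"loss"`), with attribute `log_prob`.
#' @export
#' @examples
#' p <- cn_hmm_params(emission_sd = 0.1)
#' viterbi_decode(c(0, 0, 0, -1, -1, -1), (1:6) * 1000, p)
viterbi_decode <- function(observations, positions, params) {
  if (length(observations) == 0) stop("empty observation sequence", call. = FALSE)
  if (length(observations) != length(positions)) {
    stop("observations and positions must have equal length", call. = FALSE)
  }
  if (is.unsorted(positions)) stop("positions must be sorted ascending", call. = FALSE)
  if (inherits(params, "cn_hmm_params")) {
    log_emit <- vapply(seq_along(params$states), function(k) {
      stats::dnorm(observations, params$state_means[k], params$emission_sd, log = TRUE)
    }, numeric(length(observations)))
    log_emit <- matrix(log_emit, ncol = length(params$states))
  } else if (inherits(params, "loh_hmm_params")) {
    if (is.character(observations)) {
      bad <- !(observations %in% c("LOH", "retention"))
      if (any(bad)) {
        stop("LOH observations must be \"LOH\" or \"retention\" (non-informative SNPs are not decodable)",
             call. = FALSE)
      }
      observations <- observations == "LOH"
    }
    log_emit <- .loh_log_emissions(as.logical(observations), params)
  } else {
    stop("'params' must be cn_hmm_params or loh_hmm_params", call. = FALSE)
  }
  res <- .viterbi_core(log_emit, positions, params$stay_prob_at_1bp,
                       params$decay_length, params$stay_min)
  structure(params$states[res$path], log_prob = res$log_prob)
}

.runs_to_segments <- function(chromosome, positions, states, values) {
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(
    chromosome = chromosome,
    start = positions[starts],
    end = positions[ends],
    state = r$values,
    n_snps = r$lengths,
    mean_value = vapply(seq_along(starts), function(i) {
      mean(values[starts[i]:ends[i]])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Segment a smoothed copy-number track
#'
#' Runs Viterbi decoding of the smoothed log2 ratios independently per
#' chromosome and collapses maximal runs of constant hidden state into
#' segments. Segment spans run from the first to the last member SNP
#' (1-based inclusive); the union of segments covers every SNP exactly
#' once.
#'
#' @param track A `cn_track` with smoothed columns filled.
#' @param params A [cn_hmm_params()] object.
#' @return A data frame of segments (`chromosome`, `start`, `end`, `state`
#'   = integer copy number, `n_snps`, `mean_value` = mean smoothed log2).
#' @export
segment_cn <- function(track, params = cn_hmm_params()) {
  if (nrow(track) == 0) stop("empty track", call. = FALSE)
  if (anyNA(track$smoothed_log2)) {
    stop("track has unset smoothed columns; run gaussian_smooth() first", call. = FALSE)
  }
  chroms <- unique(track$chromosome)
  segs <- lapply(chroms, function(chrom) {
    idx <- which(track$chromosome == chrom)
    states <- viterbi_decode(track$smoothed_log2[idx], track$position[idx], params)
    .runs_to_segments(chrom, track$position[idx], as.vector(states),
                      track$smoothed_log2[idx])
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  attr(out, "track_type") <- "cn"
  out
}

#' Segment a per-SNP LOH call track
#'
#' Runs the two-state LOH HMM over the informative SNPs of each chromosome
#' (non-informative SNPs contribute no emissions but are spanned by the
#' resulting segments) and collapses state runs into segments. A chromosome
#' with no informative SNPs yields a single retention segment spanning its
#' SNPs, flagged `low_confidence` with `n_snps = 0`.
#'
#' @param loh_track A `loh_track` from [build_loh_track()].
#' @param params A [loh_hmm_params()] object.
#' @return A data frame of segments (`chromosome`, `start`, `end`, `state`
#'   in retention/loss, `n_snps` = informative SNPs, `mean_value` = fraction
#'   of informative SNPs called LOH, `low_confidence`).
#' @export
segment_loh <- function(loh_track, params = loh_hmm_params()) {
  if (nrow(loh_track) == 0) stop("empty LOH track", call. = FALSE)
  chroms <- unique(loh_track$chromosome)
  segs <- lapply(chroms, function(chrom) {
    idx <- which(loh_track$chromosome == chrom)
    inf <- idx[loh_track$call[idx] != "non_informative"]
    if (length(inf) == 0) {
      return(data.frame(
        chromosome = chrom,
        start = min(loh_track$position[idx]),
        end = max(loh_track$position[idx]),
        state = "retention", n_snps = 0L, mean_value = NA_real_,
        low_confidence = TRUE, stringsAsFactors = FALSE
      ))
    }
    is_loh <- loh_track$call[inf] == "LOH"
    states <- viterbi_decode(is_loh, loh_track$position[inf], params)
    out <- .runs_to_segments(chrom, loh_track$position[inf], as.vector(states),
                             as.numeric(is_loh))
    out$low_confidence <- FALSE
    out
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  attr(out, "track_type") <- "loh"
  out
}
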