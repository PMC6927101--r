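## Linear-chain CRF over BIO2 tags: sequence scoring, the forward
## algorithm (log-partition), Viterbi decoding, and the gradients used in
## training.  Transitions form a (K+2) x (K+2) matrix indexed [from, to]
## with two extra states: start = K+1 and stop = K+2.

crf_start_idx <- function(K) K + 1L
crf_stop_idx <- function(K) K + 2L

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Score a tag sequence under a linear-chain CRF
#'
#' The score is the sum of per-position emission scores plus transition
#' scores, including start -> first tag and last tag -> stop.
#'
#' @param emissions `T x K` matrix of per-position tag scores.
#' @param transitions `(K+2) x (K+2)` matrix `[from, to]`; row `K+1` is the
#'   start state, column `K+2` the stop state.
#' @param tag_sequence Integer vector of length `T` with values in `1..K`.
#' @return Scalar score.
#' @export
crf_score <- function(emissions, transitions, tag_sequence) {
  Tn <- nrow(emissions); K <- ncol(emissions)
  stopifnot(nrow(transitions) == K + 2L, ncol(transitions) == K + 2L)
  if (length(tag_sequence) != Tn)
    stop("tag sequence length (", length(tag_sequence),
         ") != number of positions (", Tn, ")")
  if (Tn == 0L) return(transitions[crf_start_idx(K), crf_stop_idx(K)])
  s <- transitions[crf_start_idx(K), tag_sequence[1L]] +
    emissions[1L, tag_sequence[1L]]
  if (Tn > 1L) {
    from <- tag_sequence[-Tn]; to <- tag_sequence[-1L]
    s <- s + sum(transitions[cbind(from, to)]) +
      sum(emissions[cbind(2:Tn, to)])
  }
  s + transitions[tag_sequence[Tn], crf_stop_idx(K)]
}

#' Log-partition function of a linear-chain CRF (forward algorithm)
#'
#' @inheritParams crf_score
#' @return `log sum_y exp(crf_score(y))` over all `K^T` tag sequences.
#' @export
crf_log_partition <- function(emissions, transitions) {
  Tn <- nrow(emissions); K <- ncol(emissions)
  st <- crf_start_idx(K); sp <- crf_stop_idx(K)
  if (Tn == 0L) return(transitions[st, sp])
  alpha <- transitions[st, 1:K] + emissions[1L, ]
  if (Tn > 1L) for (t in 2:Tn) {
    alpha <- apply(alpha + transitions[1:K, 1:K, drop = FALSE], 2L, log_sum_exp) + emissions[t, ]
  }
  log_sum_exp(alpha + transitions[1:K, sp])
}

#' CRF log-likelihood of a gold tag sequence
#'
#' `crf_score(gold) - log Z`; always `<= 0`, and `0` exactly when only one
#' sequence is possible.
#'
#' @inheritParams crf_score
#' @param gold_tags Integer tag sequence in `1..K`.
#' @return Scalar log-likelihood.
#' @export
crf_log_likelihood <- function(emissions, transitions, gold_tags) {
  crf_score(emissions, transitions, gold_tags) -
    crf_log_partition(emissions, transitions)
}

#' Viterbi decoding of a linear-chain CRF
#'
#' Returns the tag sequence attaining the maximal [crf_score]; ties break
#' to the lowest tag index at the earliest differing position.
#'
#' @inheritParams crf_score
#' @return List with `tags` (integer vector, length `T`) and `score`.
#' @export
crf_viterbi <- function(emissions, transitions) {
  Tn <- nrow(emissions); K <- ncol(emissions)
  st <- crf_start_idx(K); sp <- crf_stop_idx(K)
  if (Tn == 0L)
    return(list(tags = integer(0), score = transitions[st, sp]))
  delta <- transitions[st, 1:K] + emissions[1L, ]
  back <- matrix(0L, nrow = Tn, ncol = K)
  if (Tn > 1L) for (t in 2:Tn) {
    cand <- delta + transitions[1:K, 1:K, drop = FALSE]     # [from, to]
    best_from <- apply(cand, 2L, which.max)   # first max = lowest index
    delta <- cand[cbind(best_from, 1:K)] + emissions[t, ]
    back[t, ] <- best_from
  }
  final <- delta + transitions[1:K, sp]
  last <- which.max(final)
  tags <- integer(Tn)
  tags[Tn] <- last
  if (Tn > 1L) for (t in Tn:2) tags[t - 1L] <- back[t, tags[t]]
  list(tags = tags, score = final[last])
}

#' Negative log-likelihood and gradients of a linear-chain CRF
#'
#' Computes the loss `-crf_log_likelihood` together with its gradients
#' with respect to the emission and transition scores via the
#' forward-backward algorithm (gradient = expected feature counts under
#' the model minus observed counts).
#'
#' @inheritParams crf_log_likelihood
#' @return List with `loss`, `d_emissions` (`T x K`) and `d_transitions`
#'   (`(K+2) x (K+2)`).
#' @keywords internal
crf_nll_grad <- function(emissions, transitions, gold_tags) {
  Tn <- nrow(emissions); K <- ncol(emissions)
  st <- crf_start_idx(K); sp <- crf_stop_idx(K)
  d_trans <- matrix(0, K + 2L, K + 2L)
  if (Tn == 0L) return(list(loss = 0, d_emissions = emissions * 0,
                            d_transitions = d_trans))
  ## forward (alpha) and backward (beta) messages in log space
  alpha <- matrix(-Inf, Tn, K)
  alpha[1L, ] <- transitions[st, 1:K] + emissions[1L, ]
  if (Tn > 1L) for (t in 2:Tn)
    alpha[t, ] <- apply(alpha[t - 1L, ] + transitions[1:K, 1:K, drop = FALSE], 2L, log_sum_exp) +
      emissions[t, ]
  beta <- matrix(-Inf, Tn, K)
  beta[Tn, ] <- transitions[1:K, sp]
  if (Tn > 1L) for (t in (Tn - 1L):1L) {
    v <- emissions[t + 1L, ] + beta[t + 1L, ]
    beta[t, ] <- apply(transitions[1:K, 1:K, drop = FALSE] +
                         matrix(v, K, K, byrow = TRUE), 1L, log_sum_exp)
  }
  logZ <- log_sum_exp(alpha[Tn, ] + transitions[1:K, sp])

  ## unary marginals -> emission gradient
  marg <- exp(alpha + beta - logZ)
  d_emis <- marg
  d_emis[cbind(seq_len(Tn), gold_tags)] <- d_emis[cbind(seq_len(Tn), gold_tags)] - 1

  ## pairwise marginals -> transition gradient
  d_trans[st, 1:K] <- exp(transitions[st, 1:K] + emissions[1L, ] + beta[1L, ] - logZ)
  d_trans[1:K, sp] <- exp(alpha[Tn, ] + transitions[1:K, sp] - logZ)
  if (Tn > 1L) for (t in 1:(Tn - 1L)) {
    pair <- outer(alpha[t, ], emissions[t + 1L, ] + beta[t + 1L, ], "+") +
      transitions[1:K, 1:K, drop = FALSE]
    d_trans[1:K, 1:K] <- d_trans[1:K, 1:K] + exp(pair - logZ)
  }
  d_trans[st, gold_tags[1L]] <- d_trans[st, gold_tags[1L]] - 1
  d_trans[gold_tags[Tn], sp] <- d_trans[gold_tags[Tn], sp] - 1
  if (Tn > 1L) for (t in 1:(Tn - 1L))
    d_trans[gold_tags[t], gold_tags[t + 1L]] <-
      d_trans[gold_tags[t], gold_tags[t + 1L]] - 1

  loss <- logZ - crf_score(emissions, transitions, gold_tags)
  list(loss = loss, d_emissions = d_emis, d_transitions = d_trans)
}
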