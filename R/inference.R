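#' Level-1 state inference over the local patch
#'
#' Posterior over the 9 local location states given one pigment observation:
#' `q1` is proportional to the observation likelihood times the prior. With a
#' deterministic remapped likelihood the posterior support is exactly the set
#' of local states consistent with the observation; a small floor keeps the
#' update defined if an observation is impossible under every local state.
#'
#' @param local a [remap_likelihood()] object.
#' @param observation `"pigment"` or `"no_pigment"`.
#' @param prior1 normalised prior over the 9 local states (default uniform).
#' @param epsilon likelihood floor (default 1e-3).
#' @return Normalised posterior vector of length 9.
#' @export
infer_level1 <- function(local, observation, prior1 = rep(1 / 9, 9),
                         epsilon = 1e-3) {
  observation <- match.arg(observation, c("pigment", "no_pigment"))
  if (abs(sum(prior1) - 1) > 1e-6 || any(prior1 < 0)) {
    stop("prior1 must be a normalised distribution", call. = FALSE)
  }
  lik <- local$outcome_probs[observation, ]
  post <- lik * prior1
  if (sum(post) == 0) post <- (lik + epsilon) * prior1
  post / sum(post)
}

## Motif-conditioned Bernoulli likelihood of one evidence pair:
## P(outcome at loc | motif m) for each m, from the model's pigment kernel.
evidence_likelihood <- function(model, loc, outcome) {
  p <- model$P_pig[loc + 1L, ]
  if (outcome == "pigment") p else 1 - p
}

#' Level-2 motif inference from one cycle of evidence
#'
#' Combines the pigment outcomes at the (usually four) locations visited
#' during the level-1 cycle with the transition-propagated previous motif
#' posterior: `q2` is proportional to the product of the per-observation
#' motif likelihoods times `B2 %*% q2_prev`. The motif-conditioned outcome
#' probability at a cell is 1 on the motif's own cells and the floor
#' `epsilon` elsewhere (and everywhere for motifs absent from the vase), so
#' background observations are uninformative and the update reduces to the
#' transition prediction.
#'
#' @param evidence data frame (or list) with `loc` (0-based locations) and
#'   `outcome` (`"pigment"` / `"no_pigment"`) for the cycle.
#' @param model a [init_model()] object.
#' @param q2_prev normalised motif posterior from the previous cycle.
#' @param B2 transition matrix; defaults to `model$B2` (pass the current
#'   learned matrix during an episode).
#' @return Normalised motif posterior.
#' @export
infer_level2 <- function(evidence, model, q2_prev, B2 = model$B2) {
  if (abs(sum(q2_prev) - 1) > 1e-6 || any(q2_prev < 0)) {
    stop("q2_prev must be a normalised distribution", call. = FALSE)
  }
  lik <- rep(1, ncol(B2))
  for (i in seq_along(evidence$loc)) {
    lik <- lik * evidence_likelihood(model, evidence$loc[i], evidence$outcome[i])
  }
  post <- unname(lik) * as.vector(B2 %*% q2_prev)
  post / sum(post)
}

#' Predicted outcome distribution at a candidate location
#'
#' Top-down prediction: the per-cell Bernoulli pigment probability under each
#' motif (1 on the motif's cells, floor elsewhere) averaged under the motif
#' belief.
#'
#' @param candidate_loc 0-based location.
#' @param q2 normalised motif belief (during an episode, the one-step
#'   transition-propagated belief `B2 %*% q2`).
#' @param model a [init_model()] object.
#' @return Named numeric vector `c(pigment = , no_pigment = )`.
#' @export
predict_outcome <- function(candidate_loc, q2, model) {
  if (abs(sum(q2) - 1) > 1e-6) {
    stop("q2 must be normalised", call. = FALSE)
  }
  p <- sum(q2 * model$P_pig[candidate_loc + 1L, ])
  c(pigment = p, no_pigment = 1 - p)
}

## x log x with the 0 log 0 = 0 convention
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

## Binary entropy in nats
entropy2 <- function(p) -(xlogx(p) + xlogx(1 - p))

#' Dirichlet information-gain matrix over B2 entries
#'
#' Entry `(i, j)` is the KL divergence from the current Dirichlet over column
#' `j` of B2 to the Dirichlet obtained by adding `rate` pseudo-counts to
#' entry `(i, j)`, i.e. the information gained by evidencing the transition
#' j -> i once. Rarely evidenced transitions carry the largest gain; this is
#' the novelty bonus in the expected free energy.
#'
#' @param b2_counts positive count matrix.
#' @param rate count mass of one update.
#' @return Matrix of non-negative gains, same shape as `b2_counts`.
#' @export
dirichlet_gain <- function(b2_counts, rate = 1.0) {
  s <- rep(colSums(b2_counts), each = nrow(b2_counts))
  a <- b2_counts
  g <- (lgamma(s + rate) - lgamma(s)) - (lgamma(a + rate) - lgamma(a)) +
    rate * (digamma(a + rate) - digamma(s + rate))
  matrix(g, nrow(b2_counts), ncol(b2_counts), dimnames = dimnames(b2_counts))
}

#' Expected free energy of a candidate saccade
#'
#' Scores one candidate location with the single-step functional
#' `G = w_risk * risk + w_ambiguity * ambiguity - w_novelty * novelty`:
#' * risk — KL divergence from the predicted outcome distribution to the
#'   preference distribution `softmax(C)`;
#' * ambiguity — expected outcome entropy under the motif belief (zero when
#'   every motif predicts the cell deterministically);
#' * novelty — expected Dirichlet information gain on the B2 counts for the
#'   motif transition the move would evidence.
#' Lower G is better; [select_action()] takes the greedy argmin.
#'
#' @param candidate_loc 0-based location.
#' @param q2 predictive motif belief used for outcome prediction (during an
#'   episode, `B2 %*% q2_current`).
#' @param model a [init_model()] object (uses its current `b2_counts`).
#' @param q2_prev motif belief the evidenced transition originates from
#'   (default `q2`).
#' @param weights named numeric vector with `risk`, `ambiguity`, `novelty`.
#' @param rate learning rate used for the novelty gain.
#' @return Scalar G, with the three terms attached as attribute `"terms"`.
#' @export
expected_free_energy <- function(candidate_loc, q2, model, q2_prev = q2,
                                 weights = c(risk = 1, ambiguity = 1,
                                             novelty = 1),
                                 rate = 1.0) {
  pred <- predict_outcome(candidate_loc, q2, model)
  risk <- sum(pred * (log(pmax(pred, .Machine$double.xmin)) -
                        log(model$C_probs)))
  p_m <- model$P_pig[candidate_loc + 1L, ]
  ambiguity <- sum(q2 * entropy2(p_m))

  ## expected next-motif belief if the agent moved there
  qp <- p_m * q2
  qn <- (1 - p_m) * q2
  qp <- if (sum(qp) > 0) qp / sum(qp) else q2
  qn <- if (sum(qn) > 0) qn / sum(qn) else q2
  qnext <- pred[["pigment"]] * qp + (1 - pred[["pigment"]]) * qn
  novelty <- sum(qnext * (dirichlet_gain(model$b2_counts, rate) %*% q2_prev))

  g <- weights[["risk"]] * risk + weights[["ambiguity"]] * ambiguity -
    weights[["novelty"]] * novelty
  structure(g, terms = c(risk = risk, ambiguity = ambiguity,
                         novelty = novelty))
}

## Vectorised G over a set of candidate locations; must agree with
## expected_free_energy() element-wise (tested).
efe_all <- function(candidates, q2, model, q2_prev = q2,
                    weights = c(risk = 1, ambiguity = 1, novelty = 1),
                    rate = 1.0) {
  P <- model$P_pig[candidates + 1L, , drop = FALSE]   # n_cand x n_motifs
  p <- as.vector(P %*% q2)                            # predicted P(pigment)
  cp <- model$C_probs
  risk <- p * (log(pmax(p, .Machine$double.xmin)) - log(cp[["pigment"]])) +
    (1 - p) * (log(pmax(1 - p, .Machine$double.xmin)) -
                 log(cp[["no_pigment"]]))
  ambiguity <- as.vector(entropy2(P) %*% q2)

  Qp <- sweep(P, 2, q2, "*")
  Qn <- sweep(1 - P, 2, q2, "*")
  sp <- rowSums(Qp)
  sn <- rowSums(Qn)
  Qp <- Qp / ifelse(sp > 0, sp, 1)
  Qn <- Qn / ifelse(sn > 0, sn, 1)
  if (any(sp == 0)) {
    Qp[sp == 0, ] <- matrix(q2, sum(sp == 0), length(q2), byrow = TRUE)
  }
  if (any(sn == 0)) {
    Qn[sn == 0, ] <- matrix(q2, sum(sn == 0), length(q2), byrow = TRUE)
  }
  Qnext <- p * Qp + (1 - p) * Qn
  gain_from <- as.vector(dirichlet_gain(model$b2_counts, rate) %*% q2_prev)
  novelty <- as.vector(Qnext %*% gain_from)

  weights[["risk"]] * risk + weights[["ambiguity"]] * ambiguity -
    weights[["novelty"]] * novelty
}

#' Action selection from expected free energies
#'
#' With `temperature = 0` (the greedy limit) returns the candidate with
#' minimal expected free energy, breaking exact ties uniformly at random.
#' With `temperature > 0` the action is sampled from the policy posterior
#' `q(pi)` proportional to `exp(-G / temperature)`, the standard softmax
#' policy distribution of discrete active inference. All randomness flows
#' through the session RNG (seed it for reproducibility).
#'
#' @param G numeric vector of per-candidate G values.
#' @param candidates vector of candidate identifiers aligned with `G`
#'   (default their indices).
#' @param temperature softmax temperature (inverse policy precision);
#'   0 selects the greedy argmin.
#' @return The chosen element of `candidates`.
#' @export
select_action <- function(G, candidates = seq_along(G), temperature = 0) {
  if (length(G) == 0) stop("empty candidate set", call. = FALSE)
  if (length(G) != length(candidates)) {
    stop("G and candidates must have equal length", call. = FALSE)
  }
  if (temperature < 0) stop("temperature must be >= 0", call. = FALSE)
  if (temperature == 0) {
    ties <- which(G == min(G))
    pick <- if (length(ties) == 1L) ties else ties[sample.int(length(ties), 1L)]
    return(candidates[pick])
  }
  w <- exp(-(G - min(G)) / temperature)
  candidates[sample.int(length(G), 1L, prob = w)]
}
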