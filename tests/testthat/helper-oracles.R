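# Independent brute-force oracles used to check the inference engine, plus a
# lazily computed, cached default-condition sweep shared by the slower tests.

# 3x3 patch read directly off the pigment matrix with explicit loops
oracle_patch <- function(vase, loc) {
  n_cols <- vase$grid$n_cols
  r0 <- loc %/% n_cols
  c0 <- loc %% n_cols
  out <- numeric(9)
  i <- 0
  for (dr in -1:1) {
    for (dc in -1:1) {
      i <- i + 1
      r <- r0 + dr
      cc <- c0 + dc
      out[i] <- if (r < 0 || r >= vase$grid$n_rows ||
                    cc < 0 || cc >= vase$grid$n_cols) 0
                else vase$pigment[r + 1, cc + 1]
    }
  }
  out
}

# explicit Bayes rule over the 9 local states
oracle_level1 <- function(lik, prior) {
  post <- numeric(length(prior))
  for (i in seq_along(prior)) post[i] <- lik[i] * prior[i]
  post / sum(post)
}

# per-motif Bernoulli pigment probability straight from the ground truth
oracle_p_pig <- function(vase, loc, motif, eps) {
  n_cols <- vase$grid$n_cols
  lab <- vase$motif_label[loc %/% n_cols + 1, loc %% n_cols + 1]
  if (lab == motif) 1 else eps
}

# enumeration of the 4-factor evidence product over all motifs
oracle_level2 <- function(vase, locs, outcomes, B2, q2_prev, eps) {
  n_m <- ncol(B2)
  pred <- as.vector(B2 %*% q2_prev)
  post <- numeric(n_m)
  for (m in seq_len(n_m) - 1L) {
    lik <- 1
    for (i in seq_along(locs)) {
      p <- oracle_p_pig(vase, locs[i], m, eps)
      lik <- lik * if (outcomes[i] == "pigment") p else 1 - p
    }
    post[m + 1L] <- lik * pred[m + 1L]
  }
  post / sum(post)
}

# general KL between two Dirichlet distributions (full formula, not the
# incremental simplification used by the package)
oracle_dirichlet_kl <- function(a_new, a_old) {
  s_new <- sum(a_new)
  s_old <- sum(a_old)
  lgamma(s_new) - sum(lgamma(a_new)) - lgamma(s_old) + sum(lgamma(a_old)) +
    sum((a_new - a_old) * (digamma(a_new) - digamma(s_new)))
}

# term-by-term G with explicit sums over the 2-outcome space and all motifs
oracle_efe <- function(vase, loc, q2, q2_prev, model, weights, rate) {
  n_m <- length(q2)
  eps <- model$config$epsilon
  p_m <- vapply(seq_len(n_m) - 1L, function(m) oracle_p_pig(vase, loc, m, eps),
                numeric(1))
  pred <- c(sum(q2 * p_m), sum(q2 * (1 - p_m)))
  cp <- model$C_probs
  risk <- 0
  for (o in 1:2) risk <- risk + pred[o] * (log(pred[o]) - log(cp[o]))
  ambiguity <- 0
  for (m in seq_len(n_m)) {
    for (po in c(p_m[m], 1 - p_m[m])) {
      if (po > 0) ambiguity <- ambiguity - q2[m] * po * log(po)
    }
  }
  qp <- p_m * q2
  qp <- qp / sum(qp)
  qn <- (1 - p_m) * q2
  qn <- qn / sum(qn)
  qnext <- pred[1] * qp + pred[2] * qn
  novelty <- 0
  for (i in seq_len(n_m)) {
    for (j in seq_len(n_m)) {
      a_old <- model$b2_counts[, j]
      a_new <- a_old
      a_new[i] <- a_new[i] + rate
      novelty <- novelty + qnext[i] * q2_prev[j] * oracle_dirichlet_kl(a_new, a_old)
    }
  }
  as.numeric(weights[["risk"]] * risk + weights[["ambiguity"]] * ambiguity -
               weights[["novelty"]] * novelty)
}

# default study conditions, shared across the sweep-based tests; computed at
# most once per test run
.cpast_cache <- new.env(parent = emptyenv())

default_sweep <- function() {
  if (is.null(.cpast_cache$sweep)) {
    .cpast_cache$sweep <- run_sweep(0:3, 1:20, cpast_config())
  }
  .cpast_cache$sweep
}

default_transfer <- function() {
  if (is.null(.cpast_cache$transfer)) {
    .cpast_cache$transfer <- run_transfer_sweep(default_sweep()$b2, 1:20,
                                                cpast_config())
  }
  .cpast_cache$transfer
}
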