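#' Run configuration with full defaults
#'
#' Collects every tunable the simulator exposes, validates it, and returns a
#' single config object passed to model construction and the experiment
#' drivers. All values are overridable here or via a YAML file
#' ([read_config()]).
#'
#' @param n_rows,n_cols grid dimensions (default 30 x 30, i.e. 900 locations).
#' @param band_row 0-based row of the decoration band; `NULL` for
#'   `floor(n_rows/2) - 1`.
#' @param timesteps foraging episode length (default 100 saccades).
#' @param trials categorisation trials per run (default 100).
#' @param n_motifs size of the motif state space, fixed across complexity
#'   levels so that learned transition matrices are comparable and
#'   transferable (default 4).
#' @param dirichlet_seed initial Dirichlet concentration per B2 entry (> 0).
#' @param b2_persistence sticky-prior weight: extra pseudo-count multiplier
#'   added to B2's diagonal at initialisation (`counts = dirichlet_seed *
#'   (1 + b2_persistence * I)`), encoding that a gaze dwelling on a
#'   decoration tends to stay within one motif between level-2 updates
#'   (default 2; 0 gives the flat prior).
#' @param learning_rate count mass added per level-2 Dirichlet update (> 0).
#' @param pref_pigment,pref_no_pigment log-preferences over the two outcomes;
#'   the agent strongly desires pigments.
#' @param epsilon likelihood floor mixed into motif-conditioned outcome
#'   probabilities to avoid zero-evidence dead ends (default 1e-3).
#' @param w_risk,w_ambiguity,w_novelty expected-free-energy term weights.
#' @param policy_temperature softmax temperature of the policy posterior
#'   `q(pi) \\propto exp(-G / temperature)`; 0 gives hard greedy argmin
#'   selection (default 0.5).
#' @param saccade_limit maximum Chebyshev saccade length; `Inf` (default)
#'   allows moves to any grid location.
#' @param plus_penalty decision-stage log-penalty on selecting the aversive
#'   "+" shape in the categorisation task.
#' @return An object of class `cpast_config` (a validated named list).
#' @export
cpast_config <- function(n_rows = 30L, n_cols = 30L, band_row = NULL,
                         timesteps = 100L, trials = 100L, n_motifs = 4L,
                         dirichlet_seed = 1.0, b2_persistence = 2,
                         learning_rate = 1.0,
                         pref_pigment = 4, pref_no_pigment = -4,
                         epsilon = 1e-3,
                         w_risk = 1, w_ambiguity = 1, w_novelty = 1,
                         policy_temperature = 0.5,
                         saccade_limit = Inf, plus_penalty = -8) {
  cfg <- list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    band_row = if (is.null(band_row)) NULL else as.integer(band_row),
    timesteps = as.integer(timesteps), trials = as.integer(trials),
    n_motifs = as.integer(n_motifs),
    dirichlet_seed = as.numeric(dirichlet_seed),
    b2_persistence = as.numeric(b2_persistence),
    learning_rate = as.numeric(learning_rate),
    pref_pigment = as.numeric(pref_pigment),
    pref_no_pigment = as.numeric(pref_no_pigment),
    epsilon = as.numeric(epsilon),
    w_risk = as.numeric(w_risk), w_ambiguity = as.numeric(w_ambiguity),
    w_novelty = as.numeric(w_novelty),
    policy_temperature = as.numeric(policy_temperature),
    saccade_limit = as.numeric(saccade_limit),
    plus_penalty = as.numeric(plus_penalty)
  )
  validate_config(cfg)
  structure(cfg, class = "cpast_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("config error: ", msg, call. = FALSE)
  chk(cfg$n_rows >= 1 && cfg$n_cols >= 1, "grid dimensions must be positive")
  chk(cfg$timesteps >= 4, "timesteps must be >= 4 (one full level-2 cycle)")
  chk(cfg$trials >= 1, "trials must be >= 1")
  chk(cfg$n_motifs >= 1, "n_motifs must be >= 1")
  chk(is.finite(cfg$dirichlet_seed) && cfg$dirichlet_seed > 0,
      "dirichlet_seed must be > 0")
  chk(is.finite(cfg$b2_persistence) && cfg$b2_persistence >= 0,
      "b2_persistence must be >= 0")
  chk(is.finite(cfg$learning_rate) && cfg$learning_rate > 0,
      "learning_rate must be > 0")
  chk(cfg$epsilon > 0 && cfg$epsilon < 0.5, "epsilon must be in (0, 0.5)")
  chk(all(c(cfg$w_risk, cfg$w_ambiguity, cfg$w_novelty) >= 0),
      "EFE weights must be non-negative")
  chk(cfg$policy_temperature >= 0, "policy_temperature must be >= 0")
  chk(cfg$saccade_limit > 0, "saccade_limit must be positive")
  invisible(cfg)
}

#' @export
print.cpast_config <- function(x, ...) {
  cat("<cpast_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-16s %s\n", k, if (is.null(v)) "auto" else format(v)))
  }
  invisible(x)
}

#' Read a run configuration from YAML
#'
#' Keys present in the file override [cpast_config()] defaults; unknown keys
#' raise a configuration error.
#'
#' @param path YAML file path.
#' @return A `cpast_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(cpast_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("config error: unknown keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(cpast_config, vals)
}

#' Write the resolved configuration next to run outputs
#' @param config a `cpast_config`.
#' @param path output YAML path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

## Small stable FNV-1a hash of the resolved config, used to stamp outputs so
## transfer files can be matched to the settings that produced them.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                        null = "null")
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
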