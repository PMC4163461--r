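# Independent transcription of the odds-likelihood update equations, used to
# cross-check the engine. Deliberately shares no code with the package: it is
# a direct, per-node application of
#   O(h) = P/(1-P);  O(h|x) = prod(L) * O(h);  P(h|x) = O/(1+O)
# and the two-branch linear interpolation for uncertain evidence, with min/max
# combination over antecedents.
#
# `hyps` is an ordered list: each entry
#   list(name, prior, ls, ln, op = "and"|"or", antecedents = character())
# where antecedent names refer to `evidence` entries (values in [0,1], with
# evidence prior `ev_prior`) or to earlier hypotheses.
oracle_propagate <- function(hyps, evidence, ev_prior = 0.5, tol = 1e-9) {
  post <- list()
  prior_of <- function(a) {
    if (a %in% names(evidence)) return(ev_prior)
    for (h in hyps) if (h$name == a) return(h$prior)
    stop("unknown antecedent ", a)
  }
  value_of <- function(a) {
    if (a %in% names(evidence)) return(evidence[[a]])
    post[[a]]
  }
  for (h in hyps) {
    vals <- vapply(h$antecedents, value_of, numeric(1))
    prs <- vapply(h$antecedents, prior_of, numeric(1))
    p_x_e <- if (h$op == "and") min(vals) else max(vals)
    p_x <- if (h$op == "and") min(prs) else max(prs)
    odds <- h$prior / (1 - h$prior)
    p_cert <- function(L) { o <- L * odds; o / (1 + o) }
    post[[h$name]] <- if (p_x_e >= 1 - tol) {
      p_cert(h$ls)
    } else if (p_x_e <= tol) {
      p_cert(h$ln)
    } else if (p_x_e < p_x) {
      p_cert(h$ln) + (h$prior - p_cert(h$ln)) / p_x * p_x_e
    } else {
      h$prior + (p_cert(h$ls) - h$prior) / (1 - p_x) * (p_x_e - p_x)
    }
  }
  unlist(post)
}

# Evidence map for crisp assignments on named symptom nodes.
crisp_evidence <- function(grades, cfg = quantify_config()) {
  out <- lapply(grades, assign_symptom_params, cfg = cfg)
  names(out) <- names(grades)
  out
}

expected_table2_values <- c(
  SP = 168, DP = 100, MAP = 130.98, MDP = 113.09, BV = 3.5212, PR = 68,
  Wt = 49, SV = 63.81, SI = 45.54, VPE = 2.18, CI = 2.7, Y = 3, Yr = 3.8,
  AC = 0.66, FEK = 0.11, BLK = 0.197)

six_classes <- c("HT", "HPT", "Low_BE", "High_BE", "Low_CPP", "High_CPP")

# Random valid sphygmogram feature records for property tests.
random_features <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    pd <- runif(1, 50, 95)
    ps <- pd + runif(1, 10, 90)
    spg_features(ps = ps, pd = pd, pbar = runif(1, pd, ps),
                 a_s = runif(1, 0, 60), a_d = runif(1, 1, 60),
                 period_T = runif(1, 0.5, 1.4), pv = runif(1, 0, 8))
  })
}
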