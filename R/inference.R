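#' Odds-likelihood primitives
#'
#' The engine works in odds space: a hypothesis with prior probability `p` has
#' prior odds `O = p / (1 - p)`; certain evidence multiplies the odds by its
#' likelihood (`LS` when certainly present, `LN` when certainly absent,
#' 1 when unknown), and the posterior probability is recovered as
#' `O' / (1 + O')`.
#'
#' @param p Prior probability, strictly inside (0,1).
#' @return `prior_odds`: the odds `p/(1-p)`.
#' @examples
#' prior_odds(0.02)                      # 0.0204...
#' posterior_prob_certain(200 * prior_odds(0.02))  # 0.8032...
#' @export
prior_odds <- function(p) {
  check_num(p, "p")
  if (p <= 0 || p >= 1)
    stop_domain("prior probability must be strictly inside (0,1), got ", p)
  p / (1 - p)
}

#' @rdname prior_odds
#' @param o Prior odds, `> 0`.
#' @param likelihoods Numeric vector of nonnegative likelihood multipliers
#'   (possibly empty: the odds pass through unchanged).
#' @return `posterior_odds`: `o * prod(likelihoods)`.
#' @export
posterior_odds <- function(o, likelihoods = numeric()) {
  check_num(o, "o")
  if (o <= 0) stop_domain("odds must be positive")
  if (length(likelihoods)) {
    if (any(!is.finite(likelihoods)) || any(likelihoods < 0))
      stop_domain("likelihoods must be finite and nonnegative")
  }
  o * prod(likelihoods)
}

#' @rdname prior_odds
#' @param o_post Posterior odds, `>= 0`.
#' @return `posterior_prob_certain`: `o_post / (1 + o_post)`; exact inverse of
#'   `prior_odds` within floating tolerance.
#' @export
posterior_prob_certain <- function(o_post) {
  check_num(o_post, "o_post")
  if (o_post < 0) stop_domain("posterior odds must be nonnegative")
  o_post / (1 + o_post)
}

#' Posterior probability under uncertain evidence
#'
#' Piecewise-linear interpolation between the three anchored beliefs: at
#' `P(x|e) = 0` the evidence is certainly false and the posterior is
#' `P(h|x')`; at `P(x|e) = P(x)` nothing has been learned and the posterior is
#' the prior `P(h)`; at `P(x|e) = 1` the evidence is certainly true and the
#' posterior is `P(h|x)`. The two branches meet continuously at `P(x)`.
#'
#' @param p_h Prior probability of the hypothesis.
#' @param p_h_given_x Posterior if the evidence were certainly true.
#' @param p_h_given_xprime Posterior if the evidence were certainly false.
#' @param p_x Prior probability of the evidence, strictly inside (0,1).
#' @param p_x_given_e Current probability of the evidence, in `[0,1]`.
#' @return The interpolated posterior probability.
#' @export
posterior_prob_uncertain <- function(p_h, p_h_given_x, p_h_given_xprime,
                                     p_x, p_x_given_e) {
  for (nm in c("p_h", "p_h_given_x", "p_h_given_xprime", "p_x", "p_x_given_e")) {
    v <- get(nm)
    check_num(v, nm)
    if (v < 0 || v > 1) stop_domain(nm, " must lie in [0,1], got ", v)
  }
  if (p_x <= 0 || p_x >= 1)
    stop_domain("p_x must be strictly inside (0,1): the interpolation slope is ",
                "undefined at the endpoints")
  if (p_x_given_e < p_x) {
    p_h_given_xprime + (p_h - p_h_given_xprime) / p_x * p_x_given_e
  } else {
    p_h + (p_h_given_x - p_h) / (1 - p_x) * (p_x_given_e - p_x)
  }
}

#' Combine antecedent probabilities at a logic node
#'
#' Conjunction nodes take the minimum of their antecedent probabilities,
#' disjunction nodes the maximum.
#'
#' @param probs Nonempty numeric vector of probabilities in `[0,1]`.
#' @return The combined probability.
#' @export
combine_conjunction <- function(probs) {
  if (!length(probs)) stop_domain("conjunction over an empty probability list")
  if (any(probs < 0 | probs > 1)) stop_domain("probabilities must lie in [0,1]")
  min(probs)
}

#' @rdname combine_conjunction
#' @export
combine_disjunction <- function(probs) {
  if (!length(probs)) stop_domain("disjunction over an empty probability list")
  if (any(probs < 0 | probs > 1)) stop_domain("probabilities must lie in [0,1]")
  max(probs)
}

# Internal: evaluate a logic subtree rooted at `name`, returning both the
# current combined probability P(x|e) and the combined evidence prior P(x),
# over the known antecedents only. Returns NULL if every antecedent is unknown.
logic_value <- function(net, name, state, cfg) {
  node <- net$nodes[[name]]
  if (node$type == "symptom") {
    ev <- state$evidence[[name]]
    if (is.null(ev) || ev$status == "unknown") return(NULL)
    return(list(p = ev$probability, prior = cfg$symptom_prior))
  }
  if (node$type == "hypothesis") {
    if (isTRUE(state$unknown[[name]])) return(NULL)
    return(list(p = state$posteriors[[name]], prior = node$prior))
  }
  vals <- Filter(Negate(is.null),
                 lapply(node_parents(net, name), logic_value,
                        net = net, state = state, cfg = cfg))
  if (!length(vals)) return(NULL)
  ps <- vapply(vals, `[[`, 0, "p")
  prs <- vapply(vals, `[[`, 0, "prior")
  if (node$op == "and") list(p = combine_conjunction(ps),
                             prior = combine_conjunction(prs))
  else list(p = combine_disjunction(ps), prior = combine_disjunction(prs))
}

# Internal: the effective LS/LN pair for a hypothesis node. When the node's
# sole evidence is a single symptom, the symptom's dynamically assigned
# Rule-1/2 likelihoods apply; otherwise the node's own (indifference) pair.
effective_likelihoods <- function(net, name, state) {
  node <- net$nodes[[name]]
  parents <- node_parents(net, name)
  if (length(parents) == 1L && net$nodes[[parents]]$type == "logic") {
    grand <- node_parents(net, parents)
    if (length(grand) == 1L && net$nodes[[grand]]$type == "symptom") {
      ev <- state$evidence[[grand]]
      if (!is.null(ev) && ev$status != "unknown") {
        return(list(ls = if (is.na(ev$ls)) 1 else ev$ls,
                    ln = if (is.na(ev$ln)) 1 else ev$ln,
                    source = grand))
      }
    }
  }
  list(ls = node$ls, ln = node$ln, source = name)
}

#' Propagate evidence through the net
#'
#' Processes hypothesis nodes in (stage, name) order. At each node the logic
#' layer collapses the known antecedents into a single effective evidence with
#' probability `P(x|e)` (min for conjunction, max for disjunction) and
#' evidence prior `P(x)` (same combination over antecedent priors: a symptom
#' contributes the configured indifference prior, an intermediate hypothesis
#' its node prior). Then:
#'
#' * `P(x|e)` within tolerance of 1 — odds update with LS;
#' * within tolerance of 0 — odds update with LN;
#' * strictly between — [posterior_prob_uncertain()] between the certain-false
#'   and certain-true posteriors;
#' * all antecedents unknown — the posterior stays at the prior.
#'
#' @param net A quantified `inference_net` (see [assign_poi_params()]).
#' @param evidence Named list of `evidence_state`s keyed by symptom node name,
#'   as produced by [quantify_record()].
#' @param cfg A [quantify_config()].
#' @return A `diagnosis_result`: list with `posteriors` (named numeric),
#'   `ranking` (hypothesis names by decreasing posterior, ties broken by
#'   name), and `trace` (per hypothesis, the applied numbers and branch).
#' @export
propagate <- function(net, evidence, cfg = quantify_config()) {
  stopifnot(inherits(net, "inference_net"))
  hyps <- net_hypotheses(net)
  for (nm in hyps)
    if (is.null(net$nodes[[nm]]$prior))
      stop_config("hypothesis node ", nm,
                  " is unquantified; run assign_poi_params() first")
  state <- list(evidence = evidence,
                posteriors = setNames(numeric(0), character(0)),
                unknown = list())
  trace <- list()
  # nodes are already ordered (stage, name) by build_net
  for (nm in hyps) {
    node <- net$nodes[[nm]]
    lvs <- Filter(Negate(is.null),
                  lapply(node_parents(net, nm), logic_value,
                         net = net, state = state, cfg = cfg))
    # a hypothesis has one logic parent by construction; alternative evidence
    # paths, were they ever attached directly, would combine disjunctively
    lv <- if (!length(lvs)) NULL
          else if (length(lvs) == 1L) lvs[[1L]]
          else list(p = combine_disjunction(vapply(lvs, `[[`, 0, "p")),
                    prior = combine_disjunction(vapply(lvs, `[[`, 0, "prior")))
    lik <- effective_likelihoods(net, nm, state)
    prior <- node$prior
    if (is.null(lv)) {
      state$posteriors[[nm]] <- prior
      state$unknown[[nm]] <- TRUE
      trace[[nm]] <- list(hypothesis = nm, stage = node$stage, prior = prior,
                          branch = "unknown", posterior = prior,
                          note = "prior retained: all evidence unknown")
      next
    }
    p_x_e <- lv$p; p_x <- lv$prior
    if (p_x_e >= 1 - cfg$tol) {
      post <- posterior_prob_certain(posterior_odds(prior_odds(prior), lik$ls))
      branch <- "certain_true"; applied <- c(ls = lik$ls)
    } else if (p_x_e <= cfg$tol) {
      post <- posterior_prob_certain(posterior_odds(prior_odds(prior), lik$ln))
      branch <- "certain_false"; applied <- c(ln = lik$ln)
    } else {
      p_hx <- posterior_prob_certain(posterior_odds(prior_odds(prior), lik$ls))
      p_hxp <- posterior_prob_certain(posterior_odds(prior_odds(prior), lik$ln))
      p_x_c <- min(max(p_x, cfg$tol), 1 - cfg$tol)
      post <- posterior_prob_uncertain(prior, p_hx, p_hxp, p_x_c, p_x_e)
      branch <- "uncertain"
      applied <- c(ls = lik$ls, ln = lik$ln, p_h_x = p_hx, p_h_xprime = p_hxp)
    }
    state$posteriors[[nm]] <- post
    state$unknown[[nm]] <- FALSE
    trace[[nm]] <- list(hypothesis = nm, stage = node$stage, prior = prior,
                        branch = branch, p_x = p_x, p_x_given_e = p_x_e,
                        applied = applied, likelihood_source = lik$source,
                        posterior = post)
  }
  posteriors <- state$posteriors[hyps]
  ranking <- hyps[order(-posteriors, hyps)]
  structure(list(posteriors = posteriors, ranking = ranking, trace = trace,
                 evidence = evidence),
            class = "diagnosis_result")
}

#' @export
print.diagnosis_result <- function(x, ...) {
  cat("<diagnosis_result>\n")
  print(round(x$posteriors[x$ranking], 6))
  invisible(x)
}

#' Recompute one trace entry from its stored numbers
#'
#' Replays the recorded branch arithmetic; used to verify that a trace fully
#' determines its posterior.
#'
#' @param entry One element of a `diagnosis_result`'s `trace`.
#' @return The recomputed posterior probability.
#' @export
replay_trace_entry <- function(entry) {
  switch(entry$branch,
    unknown = entry$prior,
    certain_true = posterior_prob_certain(
      posterior_odds(prior_odds(entry$prior), entry$applied[["ls"]])),
    certain_false = posterior_prob_certain(
      posterior_odds(prior_odds(entry$prior), entry$applied[["ln"]])),
    uncertain = posterior_prob_uncertain(
      entry$prior, entry$applied[["p_h_x"]], entry$applied[["p_h_xprime"]],
      min(max(entry$p_x, 1e-9), 1 - 1e-9), entry$p_x_given_e))
}

#' Render the reasoning chain behind one hypothesis
#'
#' Traces back from the hypothesis through its logic layer to the initial
#' symptom evidence: grades, assigned likelihoods, per-stage posteriors.
#'
#' @param result A `diagnosis_result` from [propagate()].
#' @param hypothesis Hypothesis name present in the result.
#' @param net The net the result was computed on (for the antecedent chain).
#' @return Character vector of explanation lines, invisibly printed.
#' @export
explain <- function(result, hypothesis, net = NULL) {
  stopifnot(inherits(result, "diagnosis_result"))
  if (!hypothesis %in% names(result$trace))
    stop_config("unknown hypothesis '", hypothesis, "'")
  entry <- result$trace[[hypothesis]]
  lines <- character()
  describe <- function(h, depth) {
    e <- result$trace[[h]]
    pad <- strrep("  ", depth)
    if (e$branch == "unknown") {
      lines <<- c(lines, sprintf("%s%s: prior retained (%.4g); all evidence unknown",
                                 pad, h, e$prior))
      return(invisible())
    }
    appl <- paste(sprintf("%s=%.4g", names(e$applied), e$applied), collapse = ", ")
    lines <<- c(lines, sprintf(
      "%s%s [stage %d]: prior %.4g, P(x)=%.4g, P(x|e)=%.4g, %s (%s) -> posterior %.6g",
      pad, h, e$stage, e$prior, e$p_x, e$p_x_given_e, e$branch, appl,
      e$posterior))
    if (!is.null(net)) {
      for (l in node_parents(net, h)) for (a in node_parents(net, l)) {
        an <- net$nodes[[a]]
        if (an$type == "symptom") {
          ev <- result$evidence[[a]]
          lines <<- c(lines, if (is.null(ev) || ev$status == "unknown")
            sprintf("%s  %s: unknown", pad, a)
            else sprintf("%s  %s: grade %.4g (%s)%s", pad, a, ev$grade, ev$status,
                         if (!is.na(ev$ls)) sprintf(", LS=%.4g", ev$ls)
                         else sprintf(", LN=%.4g", ev$ln)))
        } else if (an$type == "hypothesis") {
          describe(a, depth + 1L)
        }
      }
    }
  }
  describe(hypothesis, 0L)
  structure(lines, class = "hbfin_explanation")
}

#' @export
print.hbfin_explanation <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Diagnose one patient record
#'
#' Convenience pipeline: [assign_poi_params()] then [quantify_record()] then
#' [propagate()].
#'
#' @inheritParams quantify_record
#' @return A `diagnosis_result`.
#' @examples
#' \donttest{
#' net <- default_net()
#' res <- diagnose(net, table2_fixture())
#' res$ranking[1]  # "HT"
#' }
#' @export
diagnose <- function(net, record, table = default_condition_table(),
                     mfs = NULL, cfg = quantify_config()) {
  q <- quantify_record(net, record, table = table, mfs = mfs, cfg = cfg)
  propagate(q$net, q$evidence, cfg)
}
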