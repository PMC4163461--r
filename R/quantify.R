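#' Quantification configuration
#'
#' Constants governing how membership grades become statistical parameters on
#' the net:
#'
#' * Rule 1 — if the grade `f >= grade_threshold`, the symptom's evidence
#'   probability is `f` and its likelihood of sufficiency `LS = alpha * f`;
#' * Rule 2 — if `f < grade_threshold`, the probability is `f` and the
#'   likelihood of necessity `LN = beta * f`.
#'
#' The unassigned likelihood defaults to 1 (that evidence direction is
#' uninformative), keeping the odds product well defined. Intermediate and
#' conclusion hypothesis nodes are quantified by the principle of
#' indifference: every node without a user-pinned value receives
#' (`poi_prior`, `poi_ls`, `poi_ln`).
#'
#' @param alpha LS scaling coefficient (zero or positive; default 100).
#' @param beta LN scaling coefficient (zero or positive; default 10).
#' @param grade_threshold Rule-switch boundary, in (0,1); default 0.2, chosen
#'   to suppress outlier grades. The boundary itself fires Rule 1.
#' @param poi_prior Indifference prior probability for hypothesis nodes
#'   (default 0.02).
#' @param poi_ls,poi_ln Indifference likelihoods (defaults 200 and 0.01).
#' @param symptom_prior Evidence prior `P(x)` attributed to a symptom node in
#'   the uncertain-evidence interpolation: with no reason to favour presence
#'   or absence of a binary evidence, indifference gives 0.5.
#' @param tol Floating tolerance classifying grades as certain (default 1e-9).
#' @return A `quantify_config` list.
#' @export
quantify_config <- function(alpha = 100, beta = 10, grade_threshold = 0.2,
                            poi_prior = 0.02, poi_ls = 200, poi_ln = 0.01,
                            symptom_prior = 0.5, tol = 1e-9) {
  if (alpha < 0 || beta < 0) stop_config("alpha and beta must be >= 0")
  if (grade_threshold <= 0 || grade_threshold >= 1)
    stop_config("grade_threshold must be in (0,1)")
  if (poi_prior <= 0 || poi_prior >= 1) stop_config("poi_prior must be in (0,1)")
  if (poi_ls <= 0 || poi_ln <= 0) stop_config("poi_ls and poi_ln must be > 0")
  if (symptom_prior <= 0 || symptom_prior >= 1)
    stop_config("symptom_prior must be in (0,1)")
  structure(list(alpha = alpha, beta = beta, grade_threshold = grade_threshold,
                 poi_prior = poi_prior, poi_ls = poi_ls, poi_ln = poi_ln,
                 symptom_prior = symptom_prior, tol = tol),
            class = "quantify_config")
}

#' Assign dynamic statistical parameters to one symptom evidence
#'
#' Applies Rules 1–2 to a membership grade: exactly one of `ls`/`ln` is
#' assigned (the other stays `NA` and is treated as 1 by the engine). The
#' grade also serves as the evidence probability.
#'
#' @param grade Membership grade in `[0, 1]`.
#' @param cfg A [quantify_config()].
#' @return An `evidence_state`: list with `grade`, `probability`, `ls`, `ln`,
#'   `status` (one of `certain_true`, `certain_false`, `uncertain`).
#' @examples
#' assign_symptom_params(0.8)  # Rule 1: ls = 80
#' assign_symptom_params(0.1)  # Rule 2: ln = 1
#' @export
assign_symptom_params <- function(grade, cfg = quantify_config()) {
  check_num(grade, "grade")
  if (grade < 0 || grade > 1) stop_domain("grade must lie in [0,1], got ", grade)
  st <- if (grade >= 1 - cfg$tol) "certain_true"
        else if (grade <= cfg$tol) "certain_false"
        else "uncertain"
  if (grade >= cfg$grade_threshold) {
    structure(list(grade = grade, probability = grade,
                   ls = cfg$alpha * grade, ln = NA_real_, status = st),
              class = "evidence_state")
  } else {
    structure(list(grade = grade, probability = grade,
                   ls = NA_real_, ln = cfg$beta * grade, status = st),
              class = "evidence_state")
  }
}

#' Quantify hypothesis nodes by the principle of indifference
#'
#' Every hypothesis node of the net that has no user-pinned prior receives
#' (`poi_prior`, `poi_ls`, `poi_ln`); pinned nodes and symptom nodes are left
#' untouched.
#'
#' @param net An `inference_net`.
#' @param cfg A [quantify_config()].
#' @return The quantified net.
#' @export
assign_poi_params <- function(net, cfg = quantify_config()) {
  stopifnot(inherits(net, "inference_net"))
  for (nm in net_hypotheses(net)) {
    n <- net$nodes[[nm]]
    if (is.null(n$prior)) {
      net$nodes[[nm]]$prior <- cfg$poi_prior
      net$nodes[[nm]]$ls <- cfg$poi_ls
      net$nodes[[nm]]$ln <- cfg$poi_ln
    }
  }
  net
}

# Find the MF applicable to a symptom node: symptom matches and the MF's
# hypothesis is among the node's direct consequents (first match in the list).
mf_for_node <- function(mfs, net, node) {
  if (!length(mfs)) return(NULL)
  cons <- direct_consequents(net, node$name)
  for (m in mfs)
    if (identical(m$symptom, node$symptom) && m$hypothesis %in% cons)
      return(m)
  # fall back to a symptom-wide MF bound to the node name itself
  for (m in mfs)
    if (identical(m$symptom, node$name)) return(m)
  NULL
}

#' Quantify a net against one patient record
#'
#' For every symptom node: if the record carries the symptom, its grade is the
#' node's membership function evaluated at the value, or — when no MF is
#' configured — the crisp fallback (grade 1 if the value's condition label
#' equals the node's suffix, else 0); Rules 1–2 then assign the dynamic
#' parameters. Symptoms absent from the record are marked unknown, as are
#' crisp-fallback nodes whose bands need anthropometrics the record lacks.
#'
#' @param net An `inference_net` (will be PoI-quantified if not already).
#' @param record A [patient_record()].
#' @param table A `condition_table` for the crisp fallback; set `NULL` only if
#'   every symptom node has an MF.
#' @param mfs Optional list of [membership_function()]s.
#' @param cfg A [quantify_config()].
#' @return List with `net` (quantified) and `evidence` (named list of
#'   `evidence_state`, one per symptom node; unknowns have status `unknown`).
#' @export
quantify_record <- function(net, record, table = default_condition_table(),
                            mfs = NULL, cfg = quantify_config()) {
  stopifnot(inherits(net, "inference_net"), inherits(record, "patient_record"))
  net <- assign_poi_params(net, cfg)
  attributes <- record_attributes(record)
  evidence <- list()
  for (node in net_symptom_nodes(net)) {
    sym <- node$symptom
    if (is.null(record$values[[sym]])) {
      evidence[[node$name]] <- structure(
        list(grade = NA_real_, probability = NA_real_, ls = NA_real_,
             ln = NA_real_, status = "unknown"), class = "evidence_state")
      next
    }
    mf <- mf_for_node(mfs, net, node)
    if (!is.null(mf)) {
      grade <- eval_mf(mf, record$values[[sym]])
    } else {
      if (is.null(table))
        stop_config("symptom node ", node$name,
                    " has neither a membership function nor a condition table")
      if (!(sym %in% table$symptoms))
        stop_config("symptom node ", node$name,
                    " has neither a membership function nor a condition band")
      lab <- evaluate_condition(table, sym, record$values[[sym]], attributes,
                                strict = FALSE)
      band <- table$bands[[paste0(sym, ".", node$suffix)]]
      evaluable <- !is.null(band) &&
        !anyNA(band_interval(band, attributes))
      if (!evaluable && lab == "none") {
        evidence[[node$name]] <- structure(
          list(grade = NA_real_, probability = NA_real_, ls = NA_real_,
               ln = NA_real_, status = "unknown"), class = "evidence_state")
        next
      }
      grade <- as.numeric(identical(lab, node$suffix))
    }
    evidence[[node$name]] <- assign_symptom_params(grade, cfg)
  }
  list(net = net, evidence = evidence)
}
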