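#' Fit membership functions for every symptom node of a net
#'
#' For each symptom node, the records whose label lies downstream of the node
#' (the node's consequent hypothesis or anything it feeds into) are the
#' positives; the empirical grade curve is their labeled fraction per
#' histogram bin over the whole cohort, and the best family is fitted (see
#' [fit_mf()]). Nodes with too few positives, degenerate values, or a failed
#' fit are skipped — the crisp condition-band fallback covers them at
#' diagnosis time.
#'
#' @param net An `inference_net`.
#' @param records Labeled [patient_record()]s (the fitting partition).
#' @param kind Family passed to [fit_mf()] (default `"auto"`).
#' @param bins,min_fit_count,poly_order Passed to [fit_mf()].
#' @return List of [membership_function()]s.
#' @export
fit_net_mfs <- function(net, records, kind = "auto", bins = NULL,
                        min_fit_count = 20L, poly_order = 3L) {
  labels <- vapply(records, function(r)
    if (is.null(r$label)) NA_character_ else r$label, "")
  mfs <- list()
  for (node in net_symptom_nodes(net)) {
    sym <- node$symptom
    all_values <- unlist(lapply(records, function(r) r$values[[sym]]))
    if (is.null(all_values) || length(all_values) < min_fit_count) next
    pos_hyps <- downstream_hypotheses(net, node$name)
    pos <- !is.na(labels) & labels %in% pos_hyps
    values <- unlist(lapply(records[pos], function(r) r$values[[sym]]))
    if (length(values) < min_fit_count) next
    cons <- direct_consequents(net, node$name)
    mf <- tryCatch(
      fit_mf(values, all_values, kind = kind, bins = bins,
             symptom = sym, hypothesis = cons[1],
             min_fit_count = min_fit_count, poly_order = poly_order),
      hbfin_domain_error = function(e) NULL)
    if (!is.null(mf)) mfs[[node$name]] <- mf
  }
  mfs
}

#' Hold-out evaluation of the diagnostic pipeline
#'
#' Splits a labeled cohort, fits membership functions on the fitting
#' partition, diagnoses every test record, and scores top-1 recovery of the
#' generating class. The ranking is restricted to the candidate classes
#' (default: the labels present in the cohort) so that an intermediate
#' hypothesis sitting upstream of a class — e.g. low blood volume upstream of
#' hypotension — does not shadow the class it feeds.
#'
#' @param net An `inference_net`.
#' @param records Labeled [patient_record()]s.
#' @param table A `condition_table`.
#' @param fit_fraction Hold-out fraction for fitting, default 0.75.
#' @param seed Integer seed for the split.
#' @param candidates Hypothesis names eligible as predictions.
#' @param cfg A [quantify_config()].
#' @param mf_kind Membership family, default `"auto"`.
#' @return List with `accuracy` (overall top-1 fraction), `per_class` (data
#'   frame of class, n, accuracy), `predictions` (data frame of label,
#'   predicted, posterior), `mfs`, and `split`.
#' @export
evaluate_cohort <- function(net, records, table = default_condition_table(),
                            fit_fraction = 0.75, seed = NULL,
                            candidates = NULL, cfg = quantify_config(),
                            mf_kind = "auto") {
  split <- holdout_split(records, fit_fraction, seed = seed)
  mfs <- fit_net_mfs(net, split$fit, kind = mf_kind)
  labels <- vapply(split$test, function(r) r$label, "")
  if (is.null(candidates)) candidates <- sort(unique(labels))
  unknown <- setdiff(candidates, net_hypotheses(net))
  if (length(unknown))
    stop_config("candidate class(es) not in the net: ",
                paste(unknown, collapse = ", "))
  net <- assign_poi_params(net, cfg)
  preds <- lapply(split$test, function(r) {
    res <- diagnose(net, r, table = table, mfs = mfs, cfg = cfg)
    p <- res$posteriors[candidates]
    top <- candidates[order(-p, candidates)][1]
    data.frame(label = r$label, predicted = top, posterior = p[[top]])
  })
  preds <- do.call(rbind, preds)
  per_class <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    sel <- preds$label == cl
    data.frame(class = cl, n = sum(sel),
               accuracy = mean(preds$predicted[sel] == cl))
  }))
  list(accuracy = mean(preds$predicted == preds$label),
       per_class = per_class, predictions = preds, mfs = mfs, split = split)
}
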