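#' Cohort specification for the synthetic generator
#'
#' Describes per-class sampling rules: for each diagnosis class, which
#' condition band each symptom is drawn from. The default specification is
#' derived from a formula set: a class samples every symptom named in its
#' antecedent closure from the band the formula demands, and every other
#' symptom of the condition table from the normal band `c` (the `Healthy`
#' class samples everything from `c`). Values are drawn uniformly within the
#' band; unbounded bands are sampled on `[bound, bound + 3 * width_hint]`
#' (or the mirror below an upper bound), with per-symptom width hints shipped
#' in the default spec since the published table states no physiological
#' limits. Rejection sampling guarantees the drawn value actually classifies
#' into the target band (several published bands overlap a neighbouring
#' band's interval, where the more specific band wins).
#'
#' @param classes Named list: class -> named character vector symptom -> band
#'   label. Conveniently built by [class_band_map()].
#' @param n_per_class Records per class (>= 1).
#' @param noise_fraction Probability a symptom value is replaced by a draw
#'   from the symptom's global (uninformative) range; default 0.
#' @param missing_fraction Probability a symptom is dropped from the record;
#'   default 0.
#' @param weight_range,height_range Anthropometric sampling ranges (kg, cm)
#'   for classes that do not constrain them; defaults 58–62 kg and 163–167 cm,
#'   a deliberately narrow adult band so that the body-size factor — and with
#'   it every anthropometric band bound — is nearly common across the cohort
#'   and class separation is carried by the symptom values themselves.
#' @param width_hints Named numeric vector of band-width hints used for
#'   one-sided bands; entries missing from the list fall back to 15% of the
#'   bound's magnitude.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(classes, n_per_class = 50L,
                        noise_fraction = 0, missing_fraction = 0,
                        weight_range = c(58, 62), height_range = c(163, 167),
                        width_hints = default_width_hints()) {
  if (!length(classes) || is.null(names(classes)))
    stop_config("classes must be a named list")
  for (cl in names(classes)) {
    bands <- classes[[cl]]
    if (length(bands) && any(!bands %in% c("a", "b", "c")))
      stop_config("class ", cl, " references an unknown band label '",
                  setdiff(bands, c("a", "b", "c"))[1], "'")
  }
  if (n_per_class < 1L) stop_config("n_per_class must be >= 1")
  if (noise_fraction < 0 || noise_fraction > 1 ||
      missing_fraction < 0 || missing_fraction > 1)
    stop_config("fractions must lie in [0,1]")
  structure(list(classes = classes, n_per_class = as.integer(n_per_class),
                 noise_fraction = noise_fraction,
                 missing_fraction = missing_fraction,
                 weight_range = weight_range, height_range = height_range,
                 width_hints = width_hints),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_width_hints <- function() {
  c(SP = 20, DP = 10, MAP = 15, MDP = 10, PR = 15, Wt = 10,
    Y = 0.5, Yr = 0.5, AC = 0.3, CI = 0.3, FEK = 0.05, BLK = 0.02)
}

#' Per-class band assignments from a formula set
#'
#' For each requested class, collects the symptom-condition literals in the
#' class's antecedent closure (following intermediate hypothesis literals to
#' their defining formulas) and assigns every remaining symptom of the table
#' to the normal band `c`. A class named `Healthy` gets band `c` throughout.
#'
#' @param formulas List of `function_formula`s (e.g. [read_knowledge_base()]).
#' @param classes Character vector of class names (formula consequents or
#'   `"Healthy"`).
#' @param table A `condition_table` providing the symptom universe.
#' @return Named list suitable for [cohort_spec()].
#' @export
class_band_map <- function(formulas, classes,
                           table = default_condition_table()) {
  by_consequent <- split(formulas, vapply(formulas, `[[`, "", "consequent"))
  closure <- function(h, seen = character()) {
    if (h %in% seen) stop_config("cyclic formula reference at ", h)
    out <- c()
    for (f in by_consequent[[h]]) {
      for (lit in f$antecedents) {
        if (lit$type == "symptom") out[lit$symptom] <- lit$suffix
        else out <- c(out, closure(lit$name, c(seen, h)))
      }
    }
    out
  }
  res <- lapply(classes, function(cl) {
    bands <- if (identical(cl, "Healthy")) c() else {
      if (is.null(by_consequent[[cl]]))
        stop_config("class ", cl, " has no defining formula")
      closure(cl)
    }
    # AC has no normal band in the bundled table, and Wt doubles as the
    # weight attribute: both are only sampled from a band when a formula
    # demands it (otherwise Wt comes from the spec's weight_range).
    rest <- setdiff(table$symptoms, c(names(bands), "AC", "Wt"))
    bands <- c(bands, setNames(rep("c", length(rest)), rest))
    bands[names(bands) %in% table$symptoms]
  })
  setNames(res, classes)
}

sample_band <- function(table, symptom, label, attributes, width_hints,
                        max_tries = 200L) {
  b <- table$bands[[paste0(symptom, ".", label)]]
  if (is.null(b))
    stop_config("symptom ", symptom, " has no band '", label, "' to sample from")
  iv <- band_interval(b, attributes)
  if (anyNA(iv))
    stop_config("band ", symptom, "/", label,
                " needs anthropometrics missing from the sampling context")
  w <- if (symptom %in% names(width_hints)) width_hints[[symptom]] else NULL
  for (i in seq_len(max_tries)) {
    lo <- iv[1]; hi <- iv[2]
    if (!is.finite(lo)) {
      ww <- if (!is.null(w)) w else 0.15 * max(abs(hi), 1)
      lo <- hi - 3 * ww
    }
    if (!is.finite(hi)) {
      ww <- if (!is.null(w)) w else 0.15 * max(abs(lo), 1)
      hi <- lo + 3 * ww
    }
    if (!(lo < hi)) stop_config("band ", symptom, "/", label,
                                " has no sampling width configured")
    val <- runif(1, lo, hi)
    lab <- evaluate_condition(table, symptom, val, attributes, strict = FALSE)
    if (identical(lab, label)) return(val)
  }
  stop_config("could not sample a value classifying as ", symptom, "/", label,
              " after ", max_tries, " tries")
}

# Uninformative global range of a symptom: the hull of all its bands at the
# given anthropometrics, padded by half a width hint.
global_range <- function(table, symptom, attributes, width_hints) {
  bs <- Filter(function(b) b$symptom == symptom, table$bands)
  ivs <- lapply(bs, band_interval, attributes = attributes)
  ivs <- Filter(function(iv) !anyNA(iv), ivs)
  fin <- unlist(ivs)
  fin <- fin[is.finite(fin)]
  w <- if (symptom %in% names(width_hints)) width_hints[[symptom]]
       else 0.15 * max(abs(fin), 1)
  c(min(fin) - 3 * w, max(fin) + 3 * w)
}

#' Generate a labeled synthetic cohort
#'
#' For each class and record, draws anthropometrics, then each symptom
#' uniformly within its designated condition band (anthropometric bounds
#' evaluated per record), then corrupts the record: with probability
#' `noise_fraction` a symptom is resampled from its global range, and with
#' probability `missing_fraction` it is dropped. Reproducible under a fixed
#' seed.
#'
#' @param spec A [cohort_spec()].
#' @param table A `condition_table`.
#' @param seed Integer seed (the caller's RNG state is restored afterwards).
#' @return List of labeled [patient_record()]s.
#' @export
generate_cohort <- function(spec, table = default_condition_table(),
                            seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    records <- list()
    for (cl in names(spec$classes)) {
      bands <- spec$classes[[cl]]
      for (i in seq_len(spec$n_per_class)) {
        wt <- if (!is.null(bands["Wt"]) && !is.na(bands["Wt"]) &&
                  bands[["Wt"]] != "c") NA else runif(1, spec$weight_range[1],
                                                      spec$weight_range[2])
        ht <- runif(1, spec$height_range[1], spec$height_range[2])
        at <- list(height_cm = ht)
        if (!is.na(wt)) at$weight_kg <- wt
        vals <- list()
        # weight first: anthropometric bounds of other symptoms depend on it
        ord <- names(bands)[order(names(bands) != "Wt")]
        for (sym in ord) {
          v <- sample_band(table, sym, bands[[sym]], at, spec$width_hints)
          vals[[sym]] <- v
          if (sym == "Wt") at$weight_kg <- v
        }
        if (is.null(vals$Wt)) vals$Wt <- at$weight_kg
        at$weight_kg <- vals$Wt
        # corruption
        for (sym in names(vals)) {
          if (spec$noise_fraction > 0 && runif(1) < spec$noise_fraction) {
            gr <- global_range(table, sym, at, spec$width_hints)
            vals[[sym]] <- runif(1, gr[1], gr[2])
          }
          if (spec$missing_fraction > 0 && sym != "Wt" &&
              runif(1) < spec$missing_fraction)
            vals[[sym]] <- NULL
        }
        records[[length(records) + 1L]] <-
          patient_record(vals, attributes = at, label = cl)
      }
    }
    records
  })
}

#' Stratified hold-out split
#'
#' Splits labeled records into a fitting partition and a testing partition,
#' stratified by class: each class contributes `round(fit_fraction * n)`
#' records to the fitting set. The published protocol reserves 75% for
#' defining membership functions and the rest for validation.
#'
#' @param records List of labeled [patient_record()]s.
#' @param fit_fraction Fraction assigned to the fitting set, in (0,1);
#'   default 0.75.
#' @param seed Integer seed.
#' @return List with elements `fit` and `test` (disjoint, exhaustive).
#' @export
holdout_split <- function(records, fit_fraction = 0.75, seed = NULL) {
  if (fit_fraction <= 0 || fit_fraction >= 1)
    stop_domain("fit_fraction must be strictly inside (0,1)")
  labels <- vapply(records, function(r)
    if (is.null(r$label)) NA_character_ else r$label, "")
  if (anyNA(labels)) stop_domain("every record must carry a class label")
  with_seed(seed, {
    fit_idx <- integer()
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < 2L)
        stop_domain("class ", cl, " has fewer than 2 records; cannot split")
      k <- round(fit_fraction * length(idx))
      k <- min(max(k, 1L), length(idx) - 1L)
      fit_idx <- c(fit_idx, sample(idx, k))
    }
    list(fit = records[sort(fit_idx)],
         test = records[sort(setdiff(seq_along(records), fit_idx))])
  })
}
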