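#' @name condition_table
#' @title Symptom condition bands
#'
#' @description
#' A condition table maps each symptom (hemodynamic parameter or physiological
#' attribute) to up to three bands labeled `a` (pathological, typically high),
#' `b` (pathological, typically low) and `c` (normal). Band bounds may be plain
#' numbers or arithmetic expressions over the patient's weight `Wt` (kg), height
#' `L` (cm) and body-size factor `Q` (see [compute_q()]). A symptom value is
#' classified into the unique matching band, or `"none"`.
#'
#' Band operators: `ge`, `gt`, `le`, `lt` (one-sided), `range` (closed interval
#' `lower ~ upper`) and `approx` (closed interval `center * (1 +/- tol)`; the
#' published table never defines its "approximately" notation, so the tolerance
#' is a load-time parameter, default 0.10). Where a one-sided band encloses a
#' two-sided band (several published rows do), the two-sided band takes
#' precedence inside its interval; two bands of equal specificity may never
#' overlap, which is verified at load time over a grid of anthropometrics.
NULL

.allowed_vars <- c("Wt", "L", "Q")

# Parse an arithmetic expression over Wt/L/Q, rejecting anything else.
parse_band_expr <- function(text, where) {
  e <- tryCatch(str2lang(text), error = function(err)
    stop_config(where, ": cannot parse expression '", text, "'"))
  walk <- function(x) {
    if (is.numeric(x)) return(invisible())
    if (is.name(x)) {
      if (!(as.character(x) %in% .allowed_vars))
        stop_config(where, ": unknown variable '", as.character(x),
                    "' in expression '", text, "'")
      return(invisible())
    }
    if (is.call(x)) {
      op <- as.character(x[[1]])
      if (!(op %in% c("+", "-", "*", "/", "(")))
        stop_config(where, ": operator '", op, "' not allowed in '", text, "'")
      for (i in seq_along(x)[-1]) walk(x[[i]])
      return(invisible())
    }
    stop_config(where, ": invalid token in expression '", text, "'")
  }
  walk(e)
  e
}

expr_vars <- function(e) intersect(all.vars(e), .allowed_vars)

# Evaluate a band bound for given anthropometrics; NA when an expression needs
# an attribute that is absent.
eval_bound <- function(bound, attributes) {
  if (is.numeric(bound$value)) return(bound$value)
  vars <- expr_vars(bound$expr)
  wt <- attributes$weight_kg
  l <- attributes$height_cm
  env <- list()
  if ("Wt" %in% vars) { if (is.null(wt) || is.na(wt)) return(NA_real_); env$Wt <- wt }
  if ("L" %in% vars)  { if (is.null(l) || is.na(l)) return(NA_real_); env$L <- l }
  if ("Q" %in% vars) {
    if (is.null(wt) || is.null(l) || is.na(wt) || is.na(l)) return(NA_real_)
    env$Q <- compute_q(l, wt)
  }
  eval(bound$expr, envir = env, enclos = baseenv())
}

mk_bound <- function(entry, key, where) {
  val <- entry[[key]]
  expr_key <- paste0(key, "_expr")
  if (!is.null(val)) {
    if (!is.numeric(val)) stop_config(where, ": '", key, "' must be numeric")
    return(list(value = as.numeric(val)))
  }
  if (!is.null(entry[[expr_key]]))
    return(list(value = NULL, expr = parse_band_expr(entry[[expr_key]], where)))
  if (!is.null(entry$expr))
    return(list(value = NULL, expr = parse_band_expr(entry$expr, where)))
  NULL
}

# One band -> canonical form: interval [lower, upper] with inclusivity flags,
# each side a bound (number or expression) or infinite.
canon_band <- function(symptom, label, entry, approx_tol) {
  where <- paste0("condition table row ", symptom, "/", label)
  op <- entry$op
  if (is.null(op) || !(op %in% c("ge", "gt", "le", "lt", "range", "approx")))
    stop_config(where, ": op must be one of ge, gt, le, lt, range, approx")
  b <- list(symptom = symptom, label = label, op = op,
            lower = NULL, upper = NULL,
            lower_inclusive = TRUE, upper_inclusive = TRUE,
            approx_tol = approx_tol)
  main <- mk_bound(entry, "value", where)
  if (op %in% c("ge", "gt")) {
    if (is.null(main)) stop_config(where, ": missing bound")
    b$lower <- main; b$lower_inclusive <- (op == "ge")
  } else if (op %in% c("le", "lt")) {
    if (is.null(main)) stop_config(where, ": missing bound")
    b$upper <- main; b$upper_inclusive <- (op == "le")
  } else if (op == "range") {
    b$lower <- mk_bound(entry, "lower", where)
    b$upper <- mk_bound(entry, "upper", where)
    if (is.null(b$lower) || is.null(b$upper))
      stop_config(where, ": range needs lower and upper")
  } else { # approx
    if (is.null(main)) stop_config(where, ": approx needs a center value")
    b$center <- main
  }
  b$two_sided <- op %in% c("range", "approx")
  b
}

band_interval <- function(b, attributes) {
  if (b$op == "approx") {
    ctr <- eval_bound(b$center, attributes)
    if (is.na(ctr)) return(c(NA_real_, NA_real_))
    return(sort(c(ctr * (1 - b$approx_tol), ctr * (1 + b$approx_tol))))
  }
  lo <- if (is.null(b$lower)) -Inf else eval_bound(b$lower, attributes)
  hi <- if (is.null(b$upper)) Inf else eval_bound(b$upper, attributes)
  c(lo, hi)
}

band_matches <- function(b, value, attributes) {
  iv <- band_interval(b, attributes)
  if (anyNA(iv)) return(NA)
  lo_ok <- if (b$lower_inclusive) value >= iv[1] else value > iv[1]
  hi_ok <- if (b$upper_inclusive) value <= iv[2] else value < iv[2]
  lo_ok && hi_ok
}

#' Load and validate a condition table
#'
#' @param config Path to a YAML/JSON file, or an already-parsed list with a
#'   `symptoms` element mapping symptom name to per-label band entries.
#' @param approx_tol Relative half-width used for `approx` bands, default 0.10.
#'
#' @details At load time every band is checked: bounds parse, `lower <= upper`
#' at a grid of plausible anthropometrics, and bands of equal specificity
#' (both one-sided, or both two-sided) are pairwise disjoint at that grid. A
#' two-sided band nested inside a one-sided band is allowed and wins by
#' specificity at evaluation time.
#'
#' @return An object of class `condition_table`.
#' @export
load_condition_table <- function(config, approx_tol = 0.10) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_config("condition table file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$symptoms)) stop_config("condition table config lacks 'symptoms'")
  if (!(is.numeric(approx_tol) && approx_tol > 0 && approx_tol < 1))
    stop_config("approx_tol must be in (0,1)")
  bands <- list()
  for (symptom in names(config$symptoms)) {
    entry <- config$symptoms[[symptom]]
    for (label in names(entry)) {
      if (!(label %in% c("a", "b", "c")))
        stop_config("condition table row ", symptom, ": unknown label '", label, "'")
      bands[[paste0(symptom, ".", label)]] <-
        canon_band(symptom, label, entry[[label]], approx_tol)
    }
  }
  tab <- structure(list(bands = bands, symptoms = names(config$symptoms),
                        approx_tol = approx_tol),
                   class = "condition_table")
  validate_condition_table(tab)
  tab
}

# Grid of anthropometrics used for load-time interval checks.
.anthro_grid <- expand.grid(weight_kg = c(40, 49, 60, 75, 90),
                            height_cm = c(150, 165, 180))

validate_condition_table <- function(tab) {
  for (sym in tab$symptoms) {
    bs <- Filter(function(b) b$symptom == sym, tab$bands)
    for (b in bs) {
      for (i in seq_len(nrow(.anthro_grid))) {
        iv <- band_interval(b, as.list(.anthro_grid[i, ]))
        if (!anyNA(iv) && iv[1] > iv[2])
          stop_config("condition table row ", sym, "/", b$label,
                      ": lower bound exceeds upper bound")
      }
    }
    if (length(bs) > 1) {
      pairs <- utils::combn(seq_along(bs), 2)
      for (j in seq_len(ncol(pairs))) {
        b1 <- bs[[pairs[1, j]]]; b2 <- bs[[pairs[2, j]]]
        if (b1$two_sided != b2$two_sided) next  # resolved by specificity
        for (i in seq_len(nrow(.anthro_grid))) {
          at <- as.list(.anthro_grid[i, ])
          i1 <- band_interval(b1, at); i2 <- band_interval(b2, at)
          if (anyNA(i1) || anyNA(i2)) next
          lo <- max(i1[1], i2[1]); hi <- min(i1[2], i2[2])
          if (lo < hi || (lo == hi && touches_inclusive(b1, b2, lo, i1, i2)))
            stop_config("condition table rows ", sym, "/", b1$label, " and ",
                        sym, "/", b2$label, " overlap")
        }
      }
    }
  }
  invisible(tab)
}

touches_inclusive <- function(b1, b2, pt, i1, i2) {
  incl <- function(b, iv) {
    (iv[1] == pt && b$lower_inclusive) || (iv[2] == pt && b$upper_inclusive) ||
      (iv[1] < pt && pt < iv[2])
  }
  incl(b1, i1) && incl(b2, i2)
}

#' The bundled condition table
#'
#' Loads the package's default band set (16 symptom rows).
#'
#' @param approx_tol Passed to [load_condition_table()].
#' @return A `condition_table`.
#' @export
default_condition_table <- function(approx_tol = 0.10) {
  load_condition_table(system.file("extdata", "condition_table.yaml",
                                   package = "hbfin", mustWork = TRUE),
                       approx_tol = approx_tol)
}

#' Classify one symptom value into a condition label
#'
#' @param table A `condition_table`.
#' @param symptom Symptom name (must exist in the table).
#' @param value Numeric value in the symptom's units.
#' @param attributes Named list with `weight_kg` and/or `height_cm` when the
#'   symptom's bounds are anthropometric.
#' @param strict If `TRUE` (default), a band that cannot be evaluated because a
#'   required attribute is missing raises an error; if `FALSE` such bands are
#'   treated as non-matching.
#' @return `"a"`, `"b"`, `"c"`, or `"none"`.
#' @examples
#' tab <- default_condition_table()
#' evaluate_condition(tab, "SP", 168)  # "a"
#' evaluate_condition(tab, "PR", 68)   # "c"
#' @export
evaluate_condition <- function(table, symptom, value, attributes = list(),
                               strict = TRUE) {
  stopifnot(inherits(table, "condition_table"))
  check_num(value, symptom)
  if (!(symptom %in% table$symptoms))
    stop_config("unknown symptom '", symptom, "' in condition table lookup")
  bs <- Filter(function(b) b$symptom == symptom, table$bands)
  hits <- list()
  for (b in bs) {
    m <- band_matches(b, value, attributes)
    if (is.na(m)) {
      if (strict)
        stop_domain("band ", symptom, "/", b$label,
                    " needs anthropometric attributes that are missing")
      next
    }
    if (m) hits[[length(hits) + 1L]] <- b
  }
  if (!length(hits)) return("none")
  if (length(hits) > 1L) {
    two <- Filter(function(b) b$two_sided, hits)
    if (length(two) == 1L) return(two[[1L]]$label)
    stop_config("bands ", paste(vapply(hits, function(b) b$label, ""),
                                collapse = ","),
                " of symptom ", symptom, " match simultaneously")
  }
  hits[[1L]]$label
}

#' Classify every symptom of a patient record
#'
#' Batch form of [evaluate_condition()]: one entry per symptom present in both
#' the record and the table; absent symptoms are omitted (evidence unknown).
#' Bands whose anthropometric bounds cannot be evaluated for this record are
#' treated as non-matching, so classification never fails on a partial record.
#'
#' @param table A `condition_table`.
#' @param record A [patient_record()].
#' @return Named character vector of labels (`"a"`, `"b"`, `"c"` or `"none"`).
#' @export
conditions_for_record <- function(table, record) {
  stopifnot(inherits(record, "patient_record"))
  attributes <- record_attributes(record)
  syms <- intersect(names(record$values), table$symptoms)
  out <- vapply(syms, function(s)
    evaluate_condition(table, s, record$values[[s]], attributes, strict = FALSE),
    character(1))
  setNames(out, syms)
}
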