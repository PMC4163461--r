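#' Membership functions
#'
#' A membership function (MF) maps a symptom value to a grade in `[0, 1]`
#' expressing how compatible that value is with a specific diagnosis. Three
#' parametric families are supported:
#'
#' * `polynomial` — `f(s) = lambda0 + lambda1*s + ... + lambdat*s^t`, with the
#'   output clipped to `[0, 1]` (the family itself is unconstrained);
#' * `s_type` — the sigmoid `f(s) = 1 / (1 + exp(-a * (s - b)))`, `b` the
#'   turning point and `a` the slope;
#' * `quasi_gaussian` — `f(s) = exp(-((s - a) / (2 * d))^2)`, a bell with peak
#'   grade 1 at center `a` and bandwidth `2 d`; "quasi" because evaluation is
#'   restricted to a finite support rather than the whole real line.
#'
#' Outside the support `[lo, hi]` the boundary value is returned (constant
#' extrapolation).
#'
#' @param kind One of `"polynomial"`, `"s_type"`, `"quasi_gaussian"`.
#' @param symptom,hypothesis The (symptom, diagnosis) pair the MF grades.
#' @param params Named list of family parameters: `lambda` (coefficient vector,
#'   constant term first) for `polynomial`; `a`, `b` for `s_type`; `a`, `d`
#'   for `quasi_gaussian`.
#' @param support Numeric length-2 evaluation range `c(lo, hi)`.
#' @return An object of class `membership_function`.
#' @examples
#' mf <- membership_function("s_type", "SP", "HT",
#'                           params = list(a = 0.2, b = 150),
#'                           support = c(80, 220))
#' eval_mf(mf, 150)  # 0.5 at the turning point
#' @export
membership_function <- function(kind, symptom, hypothesis, params,
                                support = c(-Inf, Inf)) {
  kind <- match.arg(kind, c("polynomial", "s_type", "quasi_gaussian"))
  if (kind == "polynomial") {
    if (is.null(params$lambda) || !length(params$lambda))
      stop_config("polynomial MF needs a 'lambda' coefficient vector")
  } else if (kind == "s_type") {
    if (is.null(params$a) || is.null(params$b) || params$a == 0)
      stop_config("s_type MF needs slope a != 0 and turning point b")
  } else {
    if (is.null(params$a) || is.null(params$d) || params$d <= 0)
      stop_config("quasi_gaussian MF needs center a and half-bandwidth d > 0")
  }
  if (length(support) != 2L || support[1] > support[2])
    stop_config("support must be c(lo, hi) with lo <= hi")
  structure(list(kind = kind, symptom = symptom, hypothesis = hypothesis,
                 params = params, support = as.numeric(support)),
            class = "membership_function")
}

#' Evaluate a membership function
#'
#' Total over finite inputs: the value is clamped into the support and the
#' grade clipped into `[0, 1]`.
#'
#' @param mf A [membership_function()].
#' @param s Symptom value(s); vectorized.
#' @return Grade(s) in `[0, 1]`.
#' @export
eval_mf <- function(mf, s) {
  stopifnot(inherits(mf, "membership_function"))
  if (any(!is.finite(s))) stop_domain("symptom value must be finite")
  s <- pmin(pmax(s, mf$support[1]), mf$support[2])
  g <- switch(mf$kind,
    polynomial = {
      lam <- mf$params$lambda
      pow <- outer(s, seq_along(lam) - 1, `^`)
      as.numeric(pow %*% lam)
    },
    s_type = 1 / (1 + exp(-mf$params$a * (s - mf$params$b))),
    quasi_gaussian = exp(-((s - mf$params$a) / (2 * mf$params$d))^2))
  pmin(pmax(g, 0), 1)
}

# Empirical grade curve: fraction of records carrying the hypothesis label in
# each occupied histogram bin.
bin_grades <- function(values, all_values, bins) {
  rng <- range(all_values)
  brk <- seq(rng[1], rng[2], length.out = bins + 1L)
  cut_all <- findInterval(all_values, brk, rightmost.closed = TRUE,
                          all.inside = TRUE)
  cut_lab <- findInterval(values, brk, rightmost.closed = TRUE,
                          all.inside = TRUE)
  n_all <- tabulate(cut_all, nbins = bins)
  n_lab <- tabulate(cut_lab, nbins = bins)
  occ <- n_all > 0
  list(centers = ((brk[-1] + brk[-length(brk)]) / 2)[occ],
       grades = (n_lab[occ] / n_all[occ]))
}

fit_polynomial <- function(x, y, order = 3L) {
  order <- max(1L, min(order, length(unique(x)) - 1L))
  fit <- lm(y ~ poly(x, degree = order, raw = TRUE))
  lam <- as.numeric(coef(fit))
  lam[is.na(lam)] <- 0
  list(params = list(lambda = lam),
       rss = sum((pmin(pmax(fitted_poly(lam, x), 0), 1) - y)^2))
}

fitted_poly <- function(lam, x) as.numeric(outer(x, seq_along(lam) - 1, `^`) %*% lam)

fit_s_type <- function(x, y) {
  # start: turning point at the empirical 0.5 crossing, slope from data span
  b0 <- x[which.min(abs(y - 0.5))]
  slope_sign <- if (stats::cor(x, y) >= 0) 1 else -1
  a0 <- slope_sign * 4 / max(diff(range(x)), .Machine$double.eps)
  fit <- minpack.lm::nlsLM(y ~ 1 / (1 + exp(-a * (x - b))),
                           start = list(a = a0, b = b0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- as.list(coef(fit))
  if (p$a == 0) stop_domain("s_type fit degenerated to zero slope")
  list(params = list(a = p$a, b = p$b), rss = sum(stats::resid(fit)^2))
}

fit_quasi_gaussian <- function(x, y) {
  a0 <- x[which.max(y)]
  d0 <- max(sd(x) / 2, diff(range(x)) / 10, .Machine$double.eps)
  fit <- minpack.lm::nlsLM(y ~ exp(-((x - a) / (2 * d))^2),
                           start = list(a = a0, d = d0),
                           lower = c(-Inf, 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- as.list(coef(fit))
  list(params = list(a = p$a, d = p$d), rss = sum(stats::resid(fit)^2))
}

#' Choose the best-fitting membership family for a grade curve
#'
#' Fits all three families to the bin-center/grade pairs and returns the one
#' with the lowest residual sum of squares; exact ties are broken in the order
#' polynomial, s_type, quasi_gaussian. The published method names the three
#' families but not a selection rule; minimum residual is this package's
#' reproducible surrogate.
#'
#' @param centers Bin centers (>= 5 occupied bins).
#' @param grades Empirical grades at the centers.
#' @param poly_order Polynomial order for the polynomial candidate.
#' @return List with `kind`, `params`, `rss`.
#' @export
select_kind <- function(centers, grades, poly_order = 3L) {
  if (length(centers) < 5L) stop_domain("need at least 5 occupied bins")
  cands <- list(
    polynomial = function() fit_polynomial(centers, grades, poly_order),
    s_type = function() fit_s_type(centers, grades),
    quasi_gaussian = function() fit_quasi_gaussian(centers, grades))
  # candidate fits may legitimately fail or complain on degenerate curves;
  # the competition only needs their residuals
  fits <- lapply(cands, function(f)
    tryCatch(suppressWarnings(f()), error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop_domain("all membership-family fits failed")
  rss <- vapply(fits, function(f) if (is.null(f)) Inf else f$rss, numeric(1))
  kind <- names(which.min(rss))  # which.min keeps first on ties
  c(list(kind = kind), fits[[kind]])
}

#' Fit a membership function from labeled data
#'
#' Builds the empirical grade curve as the labeled fraction per histogram bin —
#' (count of hypothesis-labeled records in bin) / (count of all records in
#' bin) over occupied bins — then least-squares fits the chosen family to the
#' bin-center/grade pairs. The support is the cohort data range.
#'
#' @param values Symptom values of records labeled with the hypothesis.
#' @param all_values Symptom values of the whole cohort (`values` included).
#' @param kind `"auto"` (default, via [select_kind()]) or a family name.
#' @param bins Number of histogram bins; default Sturges' rule on the cohort.
#' @param symptom,hypothesis Names stored on the fitted MF.
#' @param min_fit_count Minimum number of labeled values (default 20).
#' @param poly_order Polynomial order (default 3).
#' @return A fitted [membership_function()].
#' @export
fit_mf <- function(values, all_values, kind = "auto", bins = NULL,
                   symptom = "s", hypothesis = "h",
                   min_fit_count = 20L, poly_order = 3L) {
  values <- as.numeric(values); all_values <- as.numeric(all_values)
  if (length(values) < min_fit_count)
    stop_domain("too few labeled values to fit an MF (", length(values),
                " < ", min_fit_count, ")")
  if (length(unique(all_values)) < 2L || diff(range(all_values)) == 0)
    stop_domain("degenerate variance: all cohort values equal")
  if (is.null(bins)) bins <- max(5L, nclass.Sturges(all_values))
  if (bins < 5L) stop_domain("bins must be >= 5")
  bg <- bin_grades(values, all_values, bins)
  if (length(bg$centers) < 5L)
    stop_domain("fewer than 5 occupied bins; widen the cohort or reduce bins")
  fit <- if (identical(kind, "auto")) {
    select_kind(bg$centers, bg$grades, poly_order)
  } else {
    kind <- match.arg(kind, c("polynomial", "s_type", "quasi_gaussian"))
    f <- switch(kind,
      polynomial = fit_polynomial(bg$centers, bg$grades, poly_order),
      s_type = fit_s_type(bg$centers, bg$grades),
      quasi_gaussian = fit_quasi_gaussian(bg$centers, bg$grades))
    c(list(kind = kind), f)
  }
  membership_function(fit$kind, symptom, hypothesis, fit$params,
                      support = range(all_values))
}

#' @importFrom grDevices nclass.Sturges
NULL

#' Read / write membership-function sets
#'
#' A set is a list of MFs serialized to YAML as entries
#' `{symptom, hypothesis, kind, params, support}`.
#'
#' @param mfs List of [membership_function()]s.
#' @param path YAML file path.
#' @return `write_mfs` returns `path` invisibly; `read_mfs` the list of MFs.
#' @export
write_mfs <- function(mfs, path) {
  out <- lapply(mfs, function(m)
    list(symptom = m$symptom, hypothesis = m$hypothesis, kind = m$kind,
         params = m$params, support = m$support))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_mfs
#' @export
read_mfs <- function(path) {
  if (!file.exists(path)) stop_config("MF file not found: ", path)
  raw <- yaml::read_yaml(path)
  lapply(raw, function(e) {
    p <- e$params
    if (!is.null(p$lambda)) p$lambda <- as.numeric(unlist(p$lambda))
    membership_function(e$kind, e$symptom, e$hypothesis, p,
                        support = as.numeric(unlist(e$support)))
  })
}
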