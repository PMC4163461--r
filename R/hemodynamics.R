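#' Sphygmogram morphological feature record
#'
#' Bundles the point and area based morphological features of one beat of the
#' arterial pulse waveform (sphygmogram): systolic and diastolic pressures, the
#' mean pressure over the cardiac period, the areas under the systolic and
#' diastolic portions of the curve, the period, and (optionally) venous
#' pressure. These are the raw inputs of the elastic-cavity hemodynamic model.
#'
#' @param ps Systolic pressure (mmHg).
#' @param pd Diastolic pressure (mmHg); must be strictly below `ps`.
#' @param pbar Mean arterial pressure over the period (mmHg); must lie in
#'   `[pd, ps]`.
#' @param a_s Area under the systolic portion of the curve (mmHg·s), `>= 0`.
#' @param a_d Area under the diastolic portion (mmHg·s), `>= 0`.
#' @param period_T Cardiac period (s), `> 0`.
#' @param pv Venous pressure (mmHg); defaults to 0, matching the usual
#'   approximation in the peripheral-resistance formula.
#'
#' @return An object of class `spg_features`.
#' @examples
#' spg_features(ps = 120, pd = 80, pbar = 100, a_s = 30, a_d = 30, period_T = 0.8)
#' @export
spg_features <- function(ps, pd, pbar, a_s, a_d, period_T, pv = 0) {
  for (nm in c("ps", "pd", "pbar", "a_s", "a_d", "period_T", "pv"))
    check_num(get(nm), nm)
  if (ps <= pd) stop_domain("ps must exceed pd (got ps=", ps, ", pd=", pd, ")")
  if (period_T <= 0) stop_domain("period_T must be positive")
  if (a_s < 0 || a_d < 0) stop_domain("a_s and a_d must be nonnegative")
  if (pbar < pd || pbar > ps)
    stop_domain("pbar must lie between pd and ps (got pbar=", pbar, ")")
  structure(list(ps = ps, pd = pd, pbar = pbar, a_s = a_s, a_d = a_d,
                 period_T = period_T, pv = pv),
            class = "spg_features")
}

#' Auxiliary blood pressure index k
#'
#' The dimensionless position of the mean pressure within the pulse pressure,
#' `k = (pbar - pd) / (ps - pd)`. Lies in `[0, 1]` for any valid feature record.
#'
#' @param pbar,ps,pd Mean, systolic and diastolic pressures (mmHg).
#' @return `k`, dimensionless.
#' @examples compute_k(pbar = 100, ps = 120, pd = 80) # 0.5
#' @export
compute_k <- function(pbar, ps, pd) {
  check_num(pbar, "pbar"); check_num(ps, "ps"); check_num(pd, "pd")
  if (ps == pd) stop_domain("degenerate pulse pressure: ps equals pd (ps=", ps, ")")
  (pbar - pd) / (ps - pd)
}

#' Stroke volume from the elastic-cavity solution
#'
#' `SV = 0.28 * k^2 * T * (ps - pd)` (mL/stroke). The constant 0.28 absorbs
#' unit conversion; units are documentation, not enforced.
#'
#' @param k Auxiliary blood pressure index (see [compute_k()]).
#' @param period_T Cardiac period (s), `> 0`.
#' @param ps,pd Systolic and diastolic pressures (mmHg).
#' @return Stroke volume (mL/stroke).
#' @examples compute_sv(k = 0.5, period_T = 0.8, ps = 120, pd = 80) # 2.24
#' @export
compute_sv <- function(k, period_T, ps, pd) {
  check_num(k, "k"); check_num(period_T, "period_T")
  check_num(ps, "ps"); check_num(pd, "pd")
  if (period_T <= 0) stop_domain("period_T must be positive (got ", period_T, ")")
  if (ps <= pd) stop_domain("ps must exceed pd")
  0.28 * k^2 * period_T * (ps - pd)
}

#' Auxiliary sphygmogram index
#'
#' `eta = 1 + a_s / a_d = (a_s + a_d) / a_d`, the ratio of the whole-beat area
#' to the diastolic area; always `>= 1`.
#'
#' @param a_s Systolic area (mmHg·s), `>= 0`.
#' @param a_d Diastolic area (mmHg·s), `> 0`.
#' @return `eta`, dimensionless.
#' @examples compute_eta(a_s = 30, a_d = 30) # 2
#' @export
compute_eta <- function(a_s, a_d) {
  check_num(a_s, "a_s"); check_num(a_d, "a_d")
  if (a_d == 0) stop_domain("a_d must be nonzero")
  1 + a_s / a_d
}

#' Arterial compliance
#'
#' `AC = SV / (eta * (ps - pd))`, in the table's µm/mmHg labeling.
#'
#' @param sv Stroke volume (mL/stroke).
#' @param eta Auxiliary sphygmogram index, `>= 1`.
#' @param ps,pd Systolic and diastolic pressures (mmHg).
#' @return Arterial compliance.
#' @examples compute_ac(sv = 60, eta = 1.5, ps = 120, pd = 80) # 1
#' @export
compute_ac <- function(sv, eta, ps, pd) {
  check_num(sv, "sv"); check_num(eta, "eta")
  check_num(ps, "ps"); check_num(pd, "pd")
  if (ps == pd) stop_domain("degenerate pulse pressure: ps equals pd")
  if (eta == 0) stop_domain("eta must be nonzero")
  sv / (eta * (ps - pd))
}

#' Peripheral resistance
#'
#' `R = (pbar - pv) / (SV * T)`; with the default `pv = 0` this equals the
#' common approximation `pbar / (SV * T)`. The period sits in the denominator
#' as printed in the source model.
#'
#' @param pbar Mean arterial pressure (mmHg).
#' @param sv Stroke volume (mL/stroke), `> 0`.
#' @param period_T Cardiac period (s), `> 0`.
#' @param pv Venous pressure (mmHg), default 0.
#' @return Peripheral resistance.
#' @examples compute_r(pbar = 100, sv = 50, period_T = 1) # 2
#' @export
compute_r <- function(pbar, sv, period_T, pv = 0) {
  check_num(pbar, "pbar"); check_num(sv, "sv")
  check_num(period_T, "period_T"); check_num(pv, "pv")
  if (sv == 0) stop_domain("sv must be nonzero")
  if (period_T == 0) stop_domain("period_T must be nonzero")
  (pbar - pv) / (sv * period_T)
}

#' Body-size factor Q
#'
#' The linear anthropometric factor `Q = 0.0061*L + 0.0128*Wt - 0.1592`
#' (height `L` in cm, weight `Wt` in kg) used by the condition-band table for
#' stroke-volume-family bounds.
#'
#' @param height_cm Height (cm), `> 0`.
#' @param weight_kg Weight (kg), `> 0`.
#' @return `Q`, dimensionless.
#' @examples compute_q(170, 60) # 1.6458
#' @export
compute_q <- function(height_cm, weight_kg) {
  check_num(height_cm, "height_cm"); check_num(weight_kg, "weight_kg")
  if (height_cm <= 0 || weight_kg <= 0)
    stop_domain("height_cm and weight_kg must be positive")
  0.0061 * height_cm + 0.0128 * weight_kg - 0.1592
}

#' Derive the hemodynamic parameter record from one feature record
#'
#' Chains [compute_k()], [compute_sv()], [compute_eta()], [compute_ac()],
#' [compute_r()] and [compute_q()] deterministically.
#'
#' @param f An [spg_features()] record.
#' @param height_cm,weight_kg Anthropometrics for the body-size factor.
#' @return A named list of class `hdp_record` with fields `k`, `sv`, `eta`,
#'   `ac`, `r`, `q`.
#' @examples
#' f <- spg_features(120, 80, 100, 30, 30, 0.8)
#' derive_hdps(f, height_cm = 170, weight_kg = 60)
#' @export
derive_hdps <- function(f, height_cm, weight_kg) {
  if (!inherits(f, "spg_features")) stop_domain("f must be an spg_features record")
  k   <- compute_k(f$pbar, f$ps, f$pd)
  sv  <- compute_sv(k, f$period_T, f$ps, f$pd)
  eta <- compute_eta(f$a_s, f$a_d)
  ac  <- compute_ac(sv, eta, f$ps, f$pd)
  r   <- compute_r(f$pbar, sv, f$period_T, f$pv)
  q   <- compute_q(height_cm, weight_kg)
  structure(list(k = k, sv = sv, eta = eta, ac = ac, r = r, q = q),
            class = "hdp_record")
}

#' Read sphygmogram feature records from CSV
#'
#' Expects the header `ps,pd,pbar,a_s,a_d,period_T,pv,height_cm,weight_kg`;
#' a missing or empty `pv` column is taken as 0.
#'
#' @param path CSV file path.
#' @return A data frame with one row per record.
#' @export
read_spg_features <- function(path) {
  if (!file.exists(path)) stop_config("feature file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("ps", "pd", "pbar", "a_s", "a_d", "period_T", "height_cm", "weight_kg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_config("feature CSV missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$pv)) df$pv <- 0
  df$pv[is.na(df$pv)] <- 0
  df
}

#' Append derived hemodynamic parameters to a feature table
#'
#' @param df Data frame as returned by [read_spg_features()].
#' @return The input with columns `k`, `sv`, `eta`, `ac`, `r`, `q` appended.
#' @export
derive_hdps_df <- function(df) {
  out <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    f <- tryCatch(
      spg_features(row$ps, row$pd, row$pbar, row$a_s, row$a_d, row$period_T, row$pv),
      error = function(e) stop_domain("row ", i, ": ", conditionMessage(e)))
    h <- tryCatch(derive_hdps(f, row$height_cm, row$weight_kg),
                  error = function(e) stop_domain("row ", i, ": ", conditionMessage(e)))
    unlist(h)
  })
  cbind(df, do.call(rbind, out))
}
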