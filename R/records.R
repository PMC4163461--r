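#' Patient symptom record
#'
#' A named vector of symptom values (a subset of the 38-dimensional medical
#' symptom space: physiological attributes plus hemodynamic parameters),
#' optional anthropometric/demographic attributes, and an optional diagnosis
#' label used for membership-function fitting and evaluation. Records may be
#' partial: an unknown symptom is absent, never zero.
#'
#' @param values Named numeric vector or list, symptom name -> value.
#' @param attributes Named list; recognized entries `age`, `gender`,
#'   `height_cm`, `weight_kg`. If `weight_kg` is absent but the symptom `Wt`
#'   is present, `Wt` supplies it for anthropometric band bounds.
#' @param label Optional diagnosis class name.
#' @return An object of class `patient_record`.
#' @examples
#' patient_record(c(SP = 140, PR = 68), attributes = list(weight_kg = 60))
#' @export
patient_record <- function(values, attributes = list(), label = NULL) {
  values <- unlist(values)
  if (length(values)) {
    if (is.null(names(values)) || any(!nzchar(names(values))))
      stop_domain("every symptom value must be named")
    if (!is.numeric(values) || any(!is.finite(values)))
      stop_domain("every symptom value must be finite")
  }
  structure(list(values = as.list(values), attributes = attributes,
                 label = label),
            class = "patient_record")
}

# Attributes used for band evaluation, with Wt falling back to the symptom.
record_attributes <- function(record) {
  at <- record$attributes
  if (is.null(at$weight_kg) && !is.null(record$values$Wt))
    at$weight_kg <- record$values$Wt
  at
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record>", if (!is.null(x$label)) paste0(" label=", x$label), "\n",
      sep = "")
  v <- unlist(x$values)
  if (length(v)) print(v) else cat("  (no symptom values)\n")
  invisible(x)
}

#' The bundled worked-example record
#'
#' A partial medical record of one hypertensive patient, with 16 symptom
#' values (pressures, blood volume, pulse rate, stroke-volume family, blood
#' viscosity, arterial compliance and blood-composition indices). Weight is
#' carried both as the symptom `Wt` and as the `weight_kg` attribute; height
#' was not recorded, so bands that need the body-size factor `Q` cannot be
#' evaluated for this record.
#'
#' @return A [patient_record()].
#' @examples
#' table2_fixture()$values$SP  # 168
#' @export
table2_fixture <- function() {
  patient_record(
    values = c(SP = 168, DP = 100, MAP = 130.98, MDP = 113.09, BV = 3.5212,
               PR = 68, Wt = 49, SV = 63.81, SI = 45.54, VPE = 2.18, CI = 2.7,
               Y = 3, Yr = 3.8, AC = 0.66, FEK = 0.11, BLK = 0.197),
    attributes = list(weight_kg = 49))
}

.attr_cols <- c("age", "gender", "height_cm", "weight_kg")

#' Read patient records from CSV
#'
#' The header names symptoms by their table acronyms (`SP`, `DP`, `MAP`, ...);
#' the columns `age`, `gender`, `height_cm`, `weight_kg` and `label` are
#' treated as attributes/label, everything else as a symptom. Empty cells mean
#' the symptom is unknown (absent), not zero.
#'
#' @param path CSV file path.
#' @return A list of [patient_record()]s.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop_config("record file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = FALSE)
  records_from_df(df)
}

records_from_df <- function(df) {
  sym_cols <- setdiff(names(df), c(.attr_cols, "label"))
  lapply(seq_len(nrow(df)), function(i) {
    vals <- list()
    for (s in sym_cols) {
      cell <- trimws(as.character(df[[s]][i]))
      if (is.na(cell) || !nzchar(cell)) next
      num <- suppressWarnings(as.numeric(cell))
      if (is.na(num))
        stop_domain("row ", i, ": non-numeric value '", cell,
                    "' in column ", s)
      vals[[s]] <- num
    }
    at <- list()
    for (a in .attr_cols) {
      if (!a %in% names(df)) next
      cell <- trimws(as.character(df[[a]][i]))
      if (is.na(cell) || !nzchar(cell)) next
      at[[a]] <- if (a == "gender") cell else {
        num <- suppressWarnings(as.numeric(cell))
        if (is.na(num)) stop_domain("row ", i, ": non-numeric ", a)
        num
      }
    }
    lab <- if ("label" %in% names(df)) {
      cell <- trimws(as.character(df$label[i]))
      if (is.na(cell) || !nzchar(cell)) NULL else cell
    } else NULL
    patient_record(vals, attributes = at, label = lab)
  })
}

#' Write patient records to CSV
#'
#' Inverse of [read_records()]: attribute columns first, then `label`, then the
#' union of all symptom names in first-appearance order; unknown symptoms are
#' written as empty cells.
#'
#' @param records List of [patient_record()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  df <- records_to_df(records)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

records_to_df <- function(records) {
  syms <- unique(unlist(lapply(records, function(r) names(r$values))))
  rows <- lapply(records, function(r) {
    row <- as.list(setNames(rep(NA_real_, length(syms)), syms))
    for (s in names(r$values)) row[[s]] <- r$values[[s]]
    at <- lapply(.attr_cols, function(a)
      if (is.null(r$attributes[[a]])) NA else r$attributes[[a]])
    names(at) <- .attr_cols
    c(at, list(label = if (is.null(r$label)) NA_character_ else r$label), row)
  })
  do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
}
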