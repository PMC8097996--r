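#' Analyte vocabulary
#'
#' The closed set of analyte names the package understands, and the
#' subset whose visit-to-visit variability is summarized.
#' @return character vector.
#' @export
analyteVocabulary <- function()
  c("hba1c", "total_cholesterol", "hdl_c", "ldl_c", "triglyceride",
    "glucose", "hemoglobin", "ferritin", "neutrophil", "lymphocyte")

#' @rdname analyteVocabulary
#' @export
variabilityAnalytes <- function()
  c("hba1c", "total_cholesterol", "hdl_c", "ldl_c", "triglyceride")

#' Visit-to-visit variability of a laboratory series
#'
#' Summarizes one patient's serial measurements of one analyte inside a
#' window: the baseline (earliest in-window) value, the temporal mean, the
#' sample standard deviation (n-1 denominator), and the coefficient of
#' variation CV = 100 * SD / mean. A patient is eligible for variability
#' analysis of a parameter only with three or more in-window measurements;
#' below that, mean/SD/CV are reported missing (the baseline value, when
#' any measurement exists, is still reported). CV is missing when the mean
#' is zero. The statistics are order-free: permuting the series does not
#' change them.
#'
#' @param values numeric measurements.
#' @param dates measurement dates (anything orderable; optional when no
#'   window is applied).
#' @param window length-2 vector (start, end) defining the in-window
#'   interval, inclusive; \code{NULL} uses all observations.
#' @return one-row data.frame: baseline, mean, sd, cv, n_measurements,
#'   eligible.
#' @examples
#' summarizeVariability(c(7, 8, 9))  # mean 8, sd 1, cv 12.5
#' @export
summarizeVariability <- function(values, dates = NULL, window = NULL) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  if (is.null(dates)) dates <- seq_along(values)
  if (length(dates) != length(values))
    stop("'dates' and 'values' must have equal length")
  if (!is.null(window)) {
    if (length(window) != 2L || window[1] > window[2])
      stop("'window' must be (start, end) with start <= end")
    keep <- dates >= window[1] & dates <= window[2]
    values <- values[keep]
    dates <- dates[keep]
  }
  n <- length(values)
  if (n == 0L)
    return(data.frame(baseline = NA_real_, mean = NA_real_, sd = NA_real_,
                      cv = NA_real_, n_measurements = 0L, eligible = FALSE))
  ord <- order(dates)
  baseline <- values[ord[1L]]
  eligible <- n >= 3L
  if (!eligible)
    return(data.frame(baseline = baseline, mean = NA_real_, sd = NA_real_,
                      cv = NA_real_, n_measurements = n, eligible = FALSE))
  m <- mean(values)
  s <- sd(values)
  cv <- if (m == 0) NA_real_ else 100 * s / m
  data.frame(baseline = baseline, mean = m, sd = s, cv = cv,
             n_measurements = n, eligible = TRUE)
}

#' Count hypoglycemic episodes
#'
#' An episode is a blood-glucose measurement strictly below 3.9 mmol/L.
#'
#' @param values numeric glucose measurements (mmol/L).
#' @param threshold episode threshold, default 3.9.
#' @return non-negative integer count.
#' @examples
#' countHypoglycemia(c(5.1, 3.8, 3.9, 2.9))  # 2: strict inequality
#' @export
countHypoglycemia <- function(values, threshold = 3.9) {
  if (!length(values)) return(0L)
  stopifnot(is.numeric(values), all(is.finite(values)))
  sum(values < threshold)
}

#' Neutrophil-to-lymphocyte ratio
#'
#' Baseline absolute neutrophil count divided by the lymphocyte count;
#' missing where the lymphocyte count is zero. Vectorized.
#'
#' @param neutrophil,lymphocyte counts (x10^9/L), both non-negative.
#' @return numeric ratio(s), \code{NA} where undefined.
#' @export
computeNLR <- function(neutrophil, lymphocyte) {
  if (any(neutrophil < 0, na.rm = TRUE) || any(lymphocyte < 0, na.rm = TRUE))
    stop("cell counts must be non-negative")
  ifelse(!is.na(lymphocyte) & lymphocyte == 0, NA_real_,
         neutrophil / lymphocyte)
}

#' Flag anemia
#'
#' Hemoglobin strictly below 13 g/dL for males, 12 g/dL for females.
#'
#' @param hemoglobin g/dL, non-negative.
#' @param sex "male" or "female" (vectorized, recycled).
#' @return logical.
#' @export
flagAnemia <- function(hemoglobin, sex) {
  if (any(hemoglobin < 0, na.rm = TRUE)) stop("hemoglobin must be non-negative")
  if (!all(sex %in% c("male", "female") | is.na(sex)))
    stop("unknown 'sex': must be \"male\" or \"female\"")
  thr <- ifelse(sex == "male", 13, 12)
  hemoglobin < thr
}

#' Flag iron deficiency
#'
#' Ferritin strictly below 67.4 pmol/L.
#'
#' @param ferritin pmol/L, non-negative.
#' @return logical.
#' @export
flagIronDeficiency <- function(ferritin) {
  if (any(ferritin < 0, na.rm = TRUE)) stop("ferritin must be non-negative")
  ferritin < 67.4
}

#' Engineered feature columns, in their documented order
#'
#' Per variability analyte: \code{<analyte>_baseline}, \code{_mean},
#' \code{_sd}, \code{_cv}; then \code{hypoglycemia_count}, \code{nlr},
#' \code{anemia}, \code{iron_deficiency}, \code{age}, \code{sex_male} and
#' the drug flags.
#' @return character vector of column names.
#' @export
featureColumns <- function() {
  c(as.vector(t(outer(variabilityAnalytes(),
                      c("_baseline", "_mean", "_sd", "_cv"), paste0))),
    "hypoglycemia_count", "nlr", "anemia", "iron_deficiency",
    "age", "sex_male", "biguanide", "sulphonylurea", "lipid_lowering")
}

#' Build the per-patient feature matrix
#'
#' Turns long-format labs plus a baseline table into one engineered
#' covariate row per patient: per-analyte baseline/mean/SD/CV inside the
#' measurement window (with the three-measurement eligibility rule applied
#' per parameter), the hypoglycemia episode count, baseline NLR, anemia and
#' iron-deficiency flags from the earliest in-window hemoglobin/ferritin,
#' and demographics/drug flags. Every cell is either a finite number or
#' explicitly missing; flags that cannot be determined are missing, not
#' false.
#'
#' By default the hypoglycemia count uses only measurements dated at or
#' before the window end (leakage-free: episodes after the index date are
#' in the patient's future); \code{leakFreeHypoglycemia = FALSE} counts
#' over all available glucose measurements, reproducing a
#' whole-follow-up covariate.
#'
#' @param x a [DiabetesCohort-class], or a long-format labs data.frame
#'   (patient_id, analyte, date, value) when \code{baseline} is given.
#' @param baseline per-patient data.frame (patient_id, age, sex, drug
#'   flags); taken from the cohort when \code{x} is one.
#' @param window length-2 Date (or numeric) vector: measurement window;
#'   defaults to the cohort's lookback window, or the observed lab date
#'   range.
#' @param outcomes optional outcomes data.frame (patient_id, time_days,
#'   event) stored in \code{colData}.
#' @param leakFreeHypoglycemia logical, see Details.
#' @return a [ClinicalFeatures-class] (features x patients) with assays
#'   \code{values} and \code{missing}.
#' @export
buildFeatureMatrix <- function(x, baseline = NULL, window = NULL,
                               outcomes = NULL,
                               leakFreeHypoglycemia = TRUE) {
  if (is(x, "DiabetesCohort")) {
    labs <- x@labs
    baseline <- baseline %||% x@baseline
    outcomes <- outcomes %||% x@outcomes
    if (is.null(window)) {
      bd <- as.Date(x@spec$baselineDate)
      window <- c(bd - round(x@spec$lookbackYears * 365.25), bd)
    }
  } else labs <- x
  stopifnot(is.data.frame(labs), is.data.frame(baseline))
  need <- c("patient_id", "analyte", "date", "value")
  if (!all(need %in% names(labs)))
    stop("labs must have columns ", paste(need, collapse = ", "))
  bad <- which(!labs$analyte %in% analyteVocabulary())
  if (length(bad))
    stop(sprintf("unknown analyte '%s' in labs row %d",
                 labs$analyte[bad[1]], bad[1]))
  if (anyDuplicated(baseline$patient_id))
    stop("duplicate patient ids in baseline table")
  if (is.null(window)) window <- range(labs$date)

  pid <- baseline$patient_id
  n <- length(pid)
  cols <- featureColumns()
  V <- matrix(NA_real_, n, length(cols), dimnames = list(pid, cols))

  labs <- labs[order(labs$patient_id, labs$analyte, labs$date), ]
  inWin <- labs$date >= window[1] & labs$date <= window[2]

  splitBy <- function(df) split(df, factor(df$patient_id, levels = pid))

  for (an in variabilityAnalytes()) {
    sub <- labs[inWin & labs$analyte == an, c("patient_id", "date", "value")]
    for (p in splitBy(sub)) {
      if (!nrow(p)) next
      s <- summarizeVariability(p$value, p$date)
      i <- p$patient_id[1]
      V[i, paste0(an, c("_baseline", "_mean", "_sd", "_cv"))] <-
        c(s$baseline, s$mean, s$sd, s$cv)
    }
  }

  # earliest in-window value of a supporting analyte, per patient
  firstValue <- function(an) {
    sub <- labs[inWin & labs$analyte == an, ]
    out <- setNames(rep(NA_real_, n), pid)
    if (nrow(sub)) {
      first <- sub[!duplicated(sub$patient_id), ]
      out[first$patient_id] <- first$value
    }
    out
  }

  hb <- firstValue("hemoglobin")
  fer <- firstValue("ferritin")
  neu <- firstValue("neutrophil")
  lym <- firstValue("lymphocyte")

  sex <- baseline$sex
  V[, "anemia"] <- ifelse(is.na(hb) | is.na(sex), NA_real_,
                          as.numeric(flagAnemia(pmax(hb, 0), sex)))
  V[, "iron_deficiency"] <- ifelse(is.na(fer), NA_real_,
                                   as.numeric(flagIronDeficiency(pmax(fer, 0))))
  V[, "nlr"] <- ifelse(is.na(neu) | is.na(lym), NA_real_,
                       computeNLR(pmax(neu, 0), pmax(lym, 0)))

  glu <- labs[labs$analyte == "glucose", ]
  if (leakFreeHypoglycemia) glu <- glu[glu$date <= window[2], ]
  cnt <- table(factor(glu$patient_id[glu$value < 3.9], levels = pid))
  V[, "hypoglycemia_count"] <- as.numeric(cnt)

  V[, "age"] <- baseline$age
  V[, "sex_male"] <- ifelse(is.na(sex), NA_real_, as.numeric(sex == "male"))
  for (d in c("biguanide", "sulphonylurea", "lipid_lowering"))
    V[, d] <- if (d %in% names(baseline)) as.numeric(baseline[[d]])
              else NA_real_

  ClinicalFeatures(V, outcomes = outcomes)
}

#' Construct ClinicalFeatures from a patients-by-features matrix
#'
#' @param values numeric matrix, patients in rows, features in columns
#'   (\code{NA} = missing).
#' @param missing optional logical matrix; defaults to \code{is.na(values)}.
#' @param outcomes optional data.frame (patient_id, time_days, event).
#' @return a [ClinicalFeatures-class].
#' @export
ClinicalFeatures <- function(values, missing = NULL, outcomes = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(missing)) missing <- is.na(values)
  cd <- S4Vectors::DataFrame(row.names = rownames(values))
  if (!is.null(outcomes)) {
    m <- match(rownames(values), outcomes$patient_id)
    cd$time_days <- outcomes$time_days[m]
    cd$event <- outcomes$event[m]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = t(values), missing = t(missing)),
    colData = cd)
  new("ClinicalFeatures", se)
}

#' Pad missing feature values with -1
#'
#' Replaces every missing cell of the \code{values} assay by \eqn{-1}
#' (booleans having already been encoded 0/1), the padding convention the
#' forest is trained under; the logical missing-mask assay is retained
#' unchanged for diagnostics.
#'
#' @param features a [ClinicalFeatures-class].
#' @return the padded [ClinicalFeatures-class].
#' @export
padMissing <- function(features) {
  stopifnot(is(features, "ClinicalFeatures"))
  v <- SummarizedExperiment::assay(features, "values")
  m <- SummarizedExperiment::assay(features, "missing")
  v[m | is.na(v)] <- -1
  SummarizedExperiment::assay(features, "values") <- v
  features
}
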