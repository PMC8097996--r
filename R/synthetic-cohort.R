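#' Default analyte panel for the synthetic cohort
#'
#' Population magnitudes for the ten analytes the feature-engineering
#' module understands. \code{popMean} and \code{betweenSD} describe the
#' between-patient distribution of the latent per-patient mean;
#' \code{sigmaMean}/\code{sigmaSD} the (log-normal) distribution of the
#' latent within-patient volatility. Units: HbA1c \%, lipids and glucose
#' mmol/L, hemoglobin g/dL, ferritin pmol/L, cell counts x10^9/L.
#' Magnitudes follow the biochemical profile of a territory-wide type-2
#' diabetes registry (HbA1c mean about 8.6\% with a mean visit-to-visit SD
#' of about 1.3).
#'
#' @return data.frame with columns name, popMean, betweenSD, sigmaMean,
#'   sigmaSD.
#' @export
defaultAnalytes <- function() {
  data.frame(
    name = c("hba1c", "total_cholesterol", "hdl_c", "ldl_c",
             "triglyceride", "glucose", "hemoglobin", "ferritin",
             "neutrophil", "lymphocyte"),
    popMean   = c(8.56, 4.82, 1.25, 2.78, 1.86, 9.0, 12.5, 250, 5.47, 1.87),
    betweenSD = c(1.36, 0.871, 0.362, 0.734, 1.15, 2.5, 1.99, 150, 2.2, 0.7),
    sigmaMean = c(1.28, 0.663, 0.161, 0.553, 0.573, 2.0, 0.8, 40, 1.2, 0.45),
    sigmaSD   = c(0.851, 0.459, 0.100, 0.359, 0.35, 1.0, 0.3, 20, 0.5, 0.2),
    stringsAsFactors = FALSE)
}

#' Default ground-truth log-hazard effects
#'
#' Log-hazard coefficients applied to latent (true) patient features when
#' generating event times. The mortality-relevant magnitudes mirror
#' typical multivariate hazard ratios in diabetic cohorts (age HR 1.04,
#' HbA1c mean HR 1.09, HDL-C mean HR 0.60, NLR HR about 1.015, male HR
#' 1.18), plus a within-patient HbA1c volatility effect of +0.35 per unit
#' SD so that variability genuinely drives risk.
#'
#' @return named numeric vector of log-hazard coefficients.
#' @export
defaultEffectSizes <- function() {
  c(hba1c_sd = 0.35, hba1c_mean = log(1.09), hdl_c_mean = log(0.603),
    nlr = log(1.015), age = log(1.04), sex_male = log(1.18))
}

.drugPrevalence <- c(biguanide = 0.576, sulphonylurea = 0.415,
                     lipid_lowering = 0.424)

.effectKeys <- function(analytes) {
  c(as.vector(outer(analytes$name, c("_baseline", "_mean", "_sd", "_cv"),
                    paste0)),
    "nlr", "age", "sex_male", "anemia", "hypoglycemia_count",
    names(.drugPrevalence))
}

#' Specify a synthetic diabetic cohort
#'
#' Collects and validates the generator's parameters: cohort size,
#' measurement-window and follow-up lengths, the analyte panel, the
#' visit-count distribution, the ground-truth log-hazard effect sizes, the
#' Weibull baseline hazard and the seed. The defaults encode the study
#' conditions the package's tests run under: an 11-year follow-up with
#' administrative censoring, a 5-year lookback measurement window, about
#' 10 visits per patient-analyte, and a baseline hazard giving roughly
#' half the cohort an event by the horizon.
#'
#' @param nPatients positive integer.
#' @param lookbackYears length of the measurement window (years).
#' @param followupYears administrative censoring horizon (years).
#' @param analytes data.frame as [defaultAnalytes()] (a subset is allowed).
#' @param visitsMean,visitsDispersion negative-binomial visit-count
#'   parameters (mean and size), truncated at >= 1.
#' @param effectSizes named numeric: log-hazard coefficient per latent
#'   engineered-feature name (e.g. \code{hba1c_sd}, \code{hdl_c_mean},
#'   \code{nlr}, \code{age}).
#' @param weibullShape,weibullScale baseline hazard
#'   \eqn{H_0(t) = (t/scale)^{shape}}, scale in days.
#' @param dropoutRate optional exponential random-dropout rate per day
#'   (0 = administrative censoring only, the default).
#' @param baselineDate index date; labs are dated in the
#'   \code{lookbackYears} window ending here, survival time counts days
#'   from here.
#' @param seed integer RNG seed; the generator is deterministic given the
#'   spec.
#' @return a validated list of class \code{CohortSpec}.
#' @seealso [simulateCohort()]
#' @export
cohortSpec <- function(nPatients,
                       lookbackYears = 5,
                       followupYears = 11,
                       analytes = defaultAnalytes(),
                       visitsMean = 10,
                       visitsDispersion = 5,
                       effectSizes = defaultEffectSizes(),
                       weibullShape = 1.4,
                       weibullScale = 5334,
                       dropoutRate = 0,
                       baselineDate = as.Date("2009-01-01"),
                       seed = 1L) {
  spec <- list(nPatients = as.integer(nPatients),
               lookbackYears = lookbackYears, followupYears = followupYears,
               analytes = analytes, visitsMean = visitsMean,
               visitsDispersion = visitsDispersion,
               effectSizes = effectSizes, weibullShape = weibullShape,
               weibullScale = weibullScale, dropoutRate = dropoutRate,
               baselineDate = as.Date(baselineDate), seed = as.integer(seed))
  class(spec) <- "CohortSpec"
  .validateCohortSpec(spec)
  spec
}

.validateCohortSpec <- function(spec) {
  if (is.na(spec$nPatients) || spec$nPatients < 1)
    stop("invalid 'nPatients': must be a positive integer")
  if (!is.numeric(spec$followupYears) || spec$followupYears <= 0)
    stop("invalid 'followupYears': must be > 0")
  if (!is.numeric(spec$lookbackYears) || spec$lookbackYears <= 0)
    stop("invalid 'lookbackYears': must be > 0")
  if (spec$weibullShape <= 0 || spec$weibullScale <= 0)
    stop("invalid 'weibullShape'/'weibullScale': must be > 0")
  a <- spec$analytes
  need <- c("name", "popMean", "betweenSD", "sigmaMean", "sigmaSD")
  if (!all(need %in% names(a)))
    stop("invalid 'analytes': columns ", paste(need, collapse = ", "),
         " required")
  if (any(a$betweenSD < 0) || any(a$sigmaMean <= 0) || any(a$sigmaSD < 0))
    stop("invalid 'analytes': betweenSD >= 0, sigmaMean > 0, sigmaSD >= 0")
  if (spec$visitsMean <= 0 || spec$visitsDispersion <= 0)
    stop("invalid 'visitsMean'/'visitsDispersion': must be > 0")
  if (spec$dropoutRate < 0)
    stop("invalid 'dropoutRate': must be >= 0")
  es <- spec$effectSizes
  if (length(es)) {
    bad <- setdiff(names(es), .effectKeys(a))
    if (length(bad))
      stop("invalid 'effectSizes': unknown feature(s) ",
           paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# lognormal (meanlog, sdlog) matching a natural-scale mean and sd
.lnormPars <- function(m, s) {
  cv2 <- (s / m)^2
  sdlog <- sqrt(log1p(cv2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# population-level centre of each latent feature, used to centre the
# linear predictor so the Weibull scale keeps its marginal meaning
.truthCenter <- function(spec, key) {
  a <- spec$analytes
  if (key %in% c("age")) return(63)
  if (key %in% c("sex_male")) return(0.504)
  if (key %in% names(.drugPrevalence)) return(unname(.drugPrevalence[key]))
  if (key == "nlr")
    return(a$popMean[a$name == "neutrophil"] /
           a$popMean[a$name == "lymphocyte"])
  if (key == "anemia") return(0.5)
  if (key == "hypoglycemia_count") {
    i <- which(a$name == "glucose")
    p <- stats::pnorm((3.9 - a$popMean[i]) /
                      sqrt(a$betweenSD[i]^2 + a$sigmaMean[i]^2))
    return(spec$visitsMean * p)
  }
  m <- regmatches(key, regexec("^(.*)_(baseline|mean|sd|cv)$", key))[[1]]
  i <- which(a$name == m[2])
  switch(m[3],
         baseline = , mean = a$popMean[i],
         sd = a$sigmaMean[i],
         cv = 100 * a$sigmaMean[i] / a$popMean[i])
}

# latent per-patient value of an engineered-feature name
.truthFeature <- function(spec, key, mu, sigma, base) {
  a <- spec$analytes
  if (key == "age") return(base$age)
  if (key == "sex_male") return(as.numeric(base$sex == "male"))
  if (key %in% names(.drugPrevalence)) return(base[[key]])
  if (key == "nlr") return(mu[, "neutrophil"] / mu[, "lymphocyte"])
  if (key == "anemia")
    return(as.numeric(mu[, "hemoglobin"] <
                        ifelse(base$sex == "male", 13, 12)))
  if (key == "hypoglycemia_count")
    return(spec$visitsMean *
             stats::pnorm((3.9 - mu[, "glucose"]) / sigma[, "glucose"]))
  m <- regmatches(key, regexec("^(.*)_(baseline|mean|sd|cv)$", key))[[1]]
  switch(m[3],
         baseline = , mean = mu[, m[2]],
         sd = sigma[, m[2]],
         cv = 100 * sigma[, m[2]] / mu[, m[2]])
}

#' Simulate a synthetic diabetic cohort
#'
#' Generates, per patient \eqn{i} and analyte \eqn{a}, a latent mean
#' \eqn{\mu_{ia} \sim N(popMean, betweenSD^2)} (floored at 5\% of the
#' population mean so physiological values stay positive) and a latent
#' within-patient volatility \eqn{\sigma_{ia}} from a log-normal with the
#' stated natural-scale mean and SD; visit counts are negative-binomial
#' truncated at 1, visit dates uniform in the lookback window, and
#' measurements \eqn{y = \mu_{ia} + \sigma_{ia}\varepsilon} with standard
#' normal \eqn{\varepsilon} (floored at 0.01). Event times follow a
#' proportional-hazards Weibull,
#' \eqn{H(t|x) = (t/scale)^{shape} e^{\eta}}, drawn by inverse-transform
#' sampling, where \eqn{\eta} is the centred linear predictor of the
#' latent (true) features named in \code{effectSizes}; censoring is
#' administrative at the follow-up horizon (plus optional exponential
#' dropout). Survival time is days from the baseline date to the event or
#' censoring. Deterministic for a fixed spec.
#'
#' @param spec a [cohortSpec()].
#' @return a [DiabetesCohort-class]: labs (long format), baseline,
#'   outcomes, and the latent truth table (per-analyte \code{mu_*} and
#'   \code{sigma_*}, \code{nlr}, the linear predictor \code{lp}, and the
#'   uncensored event time).
#' @examples
#' sc <- simulateCohort(cohortSpec(50, seed = 7))
#' sc
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  .validateCohortSpec(spec)
  set.seed(spec$seed)
  n <- spec$nPatients
  a <- spec$analytes
  nA <- nrow(a)
  pid <- sprintf("P%05d", seq_len(n))

  baseline <- data.frame(
    patient_id = pid,
    age = pmin(pmax(rnorm(n, 63, 11.5), 25), 95),
    sex = ifelse(runif(n) < 0.504, "male", "female"),
    stringsAsFactors = FALSE)
  for (d in names(.drugPrevalence))
    baseline[[d]] <- rbinom(n, 1L, .drugPrevalence[[d]])

  mu <- matrix(NA_real_, n, nA, dimnames = list(NULL, a$name))
  sigma <- mu
  for (j in seq_len(nA)) {
    mu[, j] <- pmax(rnorm(n, a$popMean[j], a$betweenSD[j]),
                    0.05 * a$popMean[j])
    lp <- .lnormPars(a$sigmaMean[j], max(a$sigmaSD[j], 1e-8))
    sigma[, j] <- stats::rlnorm(n, lp$meanlog, lp$sdlog)
  }

  # visit counts, truncated at >= 1 by redraw
  visits <- matrix(rnbinom(n * nA, mu = spec$visitsMean,
                           size = spec$visitsDispersion), n, nA)
  while (any(z <- visits == 0))
    visits[z] <- rnbinom(sum(z), mu = spec$visitsMean,
                         size = spec$visitsDispersion)

  windowDays <- round(spec$lookbackYears * 365.25)
  windowStart <- spec$baselineDate - windowDays
  labs <- vector("list", nA)
  for (j in seq_len(nA)) {
    k <- visits[, j]
    tot <- sum(k)
    rows <- rep.int(seq_len(n), k)
    labs[[j]] <- data.frame(
      patient_id = pid[rows],
      analyte = a$name[j],
      date = windowStart + floor(runif(tot) * windowDays),
      value = pmax(rnorm(tot, mu[rows, j], sigma[rows, j]), 0.01),
      stringsAsFactors = FALSE)
  }
  labs <- do.call(rbind, labs)
  labs <- labs[order(labs$patient_id, labs$analyte, labs$date), ]
  rownames(labs) <- NULL

  es <- spec$effectSizes
  lp <- numeric(n)
  for (key in names(es))
    lp <- lp + es[[key]] *
      (.truthFeature(spec, key, mu, sigma, baseline) -
         .truthCenter(spec, key))

  u <- runif(n)
  eventTime <- spec$weibullScale * (-log(u) / exp(lp))^(1 / spec$weibullShape)
  horizon <- spec$followupYears * 365.25
  censTime <- if (spec$dropoutRate > 0)
    pmin(horizon, stats::rexp(n, spec$dropoutRate)) else rep(horizon, n)
  outcomes <- data.frame(
    patient_id = pid,
    time_days = pmin(eventTime, censTime),
    event = as.integer(eventTime <= censTime),
    stringsAsFactors = FALSE)

  truth <- data.frame(patient_id = pid, stringsAsFactors = FALSE)
  for (j in seq_len(nA)) {
    truth[[paste0("mu_", a$name[j])]] <- mu[, j]
    truth[[paste0("sigma_", a$name[j])]] <- sigma[, j]
  }
  if (all(c("neutrophil", "lymphocyte") %in% a$name))
    truth$nlr <- mu[, "neutrophil"] / mu[, "lymphocyte"]
  truth$lp <- lp
  truth$event_time <- eventTime

  new("DiabetesCohort", labs = labs, baseline = baseline,
      outcomes = outcomes, truth = truth, spec = unclass(spec))
}

#' Remove baseline covariates at random
#'
#' Masks each baseline-covariate value (age, sex, drug flags)
#' independently with the given probability, to exercise downstream
#' missing-value handling (the \eqn{-1} padding convention). Lab series
#' are untouched. Reproducible for a fixed seed.
#'
#' @param cohort a [DiabetesCohort-class].
#' @param fraction probability in \[0, 1\] that a covariate value is
#'   removed.
#' @param seed integer seed.
#' @return the cohort with \code{NA}s injected into its baseline table.
#' @export
injectMissingness <- function(cohort, fraction, seed = 1L) {
  stopifnot(is(cohort, "DiabetesCohort"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      is.na(fraction) || fraction < 0 || fraction > 1)
    stop("'fraction' must be a single number in [0, 1]")
  if (fraction == 0) return(cohort)
  set.seed(as.integer(seed))
  b <- cohort@baseline
  for (col in setdiff(names(b), "patient_id")) {
    hit <- runif(nrow(b)) < fraction
    b[[col]][hit] <- NA
  }
  cohort@baseline <- b
  cohort
}
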