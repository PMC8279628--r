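# Cohort and outcome derivation from raw patient/episode/lab tables.

#' Study configuration
#'
#' Defines the calendar frame and clinical rules under which a cohort is
#' derived: the index date that starts follow-up, the administrative end of
#' follow-up, the recruitment window inside which diabetes evidence
#' (diagnosis code or anti-diabetic prescription) must fall, the minimum age
#' at index, the laboratory windows used for baseline and window-mean labs,
#' the linkage window (in days) that marks a sudden-cardiac-death episode as
#' AMI-related, and the condition-to-code-prefix lists used to interpret
#' episode codes.
#'
#' All dates are day-precision and all intervals are closed on both ends; a
#' "week" of linkage means 7 days inclusive on either side.
#'
#' @param index_date Start of follow-up (ISO-8601 string or Date).
#' @param follow_up_end Administrative end of follow-up.
#' @param recruitment_window Length-2 vector: window inside which diabetes
#'   evidence must be documented for inclusion.
#' @param min_age Minimum age in years at the index date; inclusion is
#'   strict (`age > min_age`).
#' @param baseline_lab_window Length-2 vector: window for baseline labs.
#' @param mean_lab_window Length-2 vector: window over which window-mean
#'   labs (e.g. mean HbA1c) are averaged.
#' @param ami_scd_link_days An SCD episode with an AMI episode within this
#'   many days (inclusive, either side) is AMI-related.
#' @param code_lists Named list mapping condition names to character vectors
#'   of code prefixes; see [default_code_lists()].
#' @param hba1c_onset_threshold HbA1c (%) above which (strictly) a lab
#'   record counts as diabetes-onset evidence.
#' @param fbg_onset_threshold Fasting blood glucose (mmol/L) above which
#'   (strictly) a lab record counts as diabetes-onset evidence.
#' @return An object of class `study_config`.
#' @export
study_config <- function(index_date = "2009-01-01",
                         follow_up_end = "2019-12-31",
                         recruitment_window = c("2009-01-01", "2009-12-31"),
                         min_age = 40,
                         baseline_lab_window = c("2008-01-01", "2008-12-31"),
                         mean_lab_window = c("2004-01-01", "2008-12-31"),
                         ami_scd_link_days = 7,
                         code_lists = default_code_lists(),
                         hba1c_onset_threshold = 6.5,
                         fbg_onset_threshold = 7) {
  cfg <- list(
    index_date = as.Date(index_date),
    follow_up_end = as.Date(follow_up_end),
    recruitment_window = as.Date(recruitment_window),
    min_age = min_age,
    baseline_lab_window = as.Date(baseline_lab_window),
    mean_lab_window = as.Date(mean_lab_window),
    ami_scd_link_days = as.integer(ami_scd_link_days),
    code_lists = code_lists,
    hba1c_onset_threshold = hba1c_onset_threshold,
    fbg_onset_threshold = fbg_onset_threshold
  )
  if (cfg$ami_scd_link_days <= 0L) stop("ami_scd_link_days must be positive")
  if (!(cfg$index_date <= cfg$recruitment_window[2]))
    stop("index_date must not be after the recruitment window end")
  if (!(cfg$index_date < cfg$follow_up_end))
    stop("index_date must precede follow_up_end")
  class(cfg) <- "study_config"
  cfg
}

#' Default condition-to-code-prefix lists
#'
#' The engine is code-system agnostic: episodes carry free-form codes and a
#' condition is recognised by prefix match against these lists. The defaults
#' use ICD-9-style prefixes for diabetes and the cardiovascular conditions
#' plus a placeholder prefix for anti-diabetic prescriptions; studies supply
#' their own lists.
#'
#' @return Named list of character vectors of code prefixes.
#' @export
default_code_lists <- function() {
  list(
    diabetes = c("250"),
    antidiabetic = c("ADRX"),
    hypertension = c("401", "402", "403", "404", "405"),
    ihd = c("411", "412", "413", "414"),
    heart_failure = c("428"),
    atrial_fibrillation = c("427.3")
  )
}

#' Read the three raw cohort tables
#'
#' Reads `patients.csv`, `episodes.csv` and `labs.csv` from a directory and
#' validates their schemas. Expected headers: patients
#' (`patient_id, sex, birth_date, death_date`), episodes
#' (`patient_id, episode_date, kind, code`), labs
#' (`patient_id, lab_name, value, measured_date`). Dates are ISO-8601;
#' `sex` is `male`/`female`; episode `kind` is one of `AMI`, `SCD`,
#' `diagnosis_code`, `prescription`.
#'
#' @param dir Directory containing the three files.
#' @return List with elements `patients`, `episodes`, `labs`.
#' @export
read_cohort_tables <- function(dir) {
  paths <- file.path(dir, c("patients.csv", "episodes.csv", "labs.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing input table(s): ", paste(missing, collapse = ", "))
  patients <- utils::read.csv(paths[1], stringsAsFactors = FALSE)
  episodes <- utils::read.csv(paths[2], stringsAsFactors = FALSE)
  labs <- utils::read.csv(paths[3], stringsAsFactors = FALSE)
  check_cols <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(what, " table lacks column(s): ", paste(miss, collapse = ", "))
  }
  check_cols(patients, c("patient_id", "sex", "birth_date", "death_date"), "patients")
  check_cols(episodes, c("patient_id", "episode_date", "kind", "code"), "episodes")
  check_cols(labs, c("patient_id", "lab_name", "value", "measured_date"), "labs")
  if (anyDuplicated(patients$patient_id))
    stop("patient_id not unique in patients table")
  bad_kind <- setdiff(unique(episodes$kind), c("AMI", "SCD", "diagnosis_code", "prescription"))
  if (length(bad_kind)) stop("unknown episode kind(s): ", paste(bad_kind, collapse = ", "))
  patients$birth_date <- as.Date(patients$birth_date)
  patients$death_date <- as.Date(ifelse(patients$death_date == "" | is.na(patients$death_date),
                                        NA, patients$death_date))
  if (any(!is.na(patients$death_date) & patients$death_date < patients$birth_date))
    stop("death_date precedes birth_date for some patients")
  episodes$episode_date <- as.Date(episodes$episode_date)
  labs$measured_date <- as.Date(labs$measured_date)
  if (any(!is.finite(labs$value))) stop("non-finite lab values present")
  list(patients = patients, episodes = episodes, labs = labs)
}

code_matches <- function(code, prefixes) {
  if (!length(prefixes)) return(rep(FALSE, length(code)))
  out <- rep(FALSE, length(code))
  for (p in prefixes) out <- out | startsWith(code, p)
  out
}

#' Derive the date of diabetes onset for one patient
#'
#' Onset is the earliest of: the earliest diabetes diagnosis code, the
#' earliest HbA1c record strictly above the configured threshold (default
#' 6.5%), and the earliest fasting blood glucose record strictly above the
#' configured threshold (default 7 mmol/L). Returns `NA` when no record
#' qualifies.
#'
#' @param record One-row data frame (or list) with `birth_date`.
#' @param episodes Episode table rows for this patient.
#' @param labs Lab table rows for this patient; HbA1c rows have
#'   `lab_name == "hba1c"`, fasting glucose rows `lab_name == "fbg"`.
#' @param config A [study_config()].
#' @return A `Date`, or `NA` if no evidence qualifies.
#' @export
derive_diabetes_onset <- function(record, episodes, labs, config) {
  if (nrow(labs) && any(labs$measured_date < record$birth_date))
    stop("lab measured before birth for patient ", record$patient_id)
  cand <- as.Date(character())
  dx <- episodes[episodes$kind == "diagnosis_code" &
                   code_matches(episodes$code, config$code_lists$diabetes), ]
  if (nrow(dx)) cand <- c(cand, min(dx$episode_date))
  hba <- labs[labs$lab_name == "hba1c" & labs$value > config$hba1c_onset_threshold, ]
  if (nrow(hba)) cand <- c(cand, min(hba$measured_date))
  fbg <- labs[labs$lab_name == "fbg" & labs$value > config$fbg_onset_threshold, ]
  if (nrow(fbg)) cand <- c(cand, min(fbg$measured_date))
  if (!length(cand)) return(as.Date(NA))
  min(cand)
}

age_at <- function(birth_date, at) as.numeric(at - birth_date) / 365.25

#' Apply the cohort inclusion criteria
#'
#' Retains patients who are (1) strictly older than `min_age` years at the
#' index date, (2) have documented diabetes evidence — a diabetes diagnosis
#' code or an anti-diabetic prescription — dated inside the recruitment
#' window, and (3) have no AMI or SCD episode dated strictly before the
#' index date. Rules are applied in that order and every excluded patient is
#' counted against the first rule it fails, so the audit is a partition of
#' the input.
#'
#' @param patients,episodes,labs Tables as returned by
#'   [read_cohort_tables()].
#' @param config A [study_config()].
#' @return Data frame of retained patients with `age_at_index` added; the
#'   exclusion audit is attached as `attr(, "audit")`.
#' @export
apply_inclusion <- function(patients, episodes, labs, config) {
  idx <- config$index_date
  age <- age_at(patients$birth_date, idx)
  ok_age <- age > config$min_age

  ev <- episodes[
    (episodes$kind == "diagnosis_code" &
       code_matches(episodes$code, config$code_lists$diabetes)) |
      (episodes$kind == "prescription" &
         code_matches(episodes$code, config$code_lists$antidiabetic)), ]
  ev <- ev[ev$episode_date >= config$recruitment_window[1] &
             ev$episode_date <= config$recruitment_window[2], ]
  ok_dm <- patients$patient_id %in% ev$patient_id

  prior <- episodes[episodes$kind %in% c("AMI", "SCD") & episodes$episode_date < idx, ]
  ok_prior <- !(patients$patient_id %in% prior$patient_id)

  reason <- rep(NA_character_, nrow(patients))
  reason[!ok_age] <- "age_at_index"
  reason[is.na(reason) & !ok_dm] <- "no_diabetes_evidence"
  reason[is.na(reason) & !ok_prior] <- "prior_ami_scd"
  keep <- is.na(reason)

  cohort <- patients[keep, , drop = FALSE]
  cohort$age_at_index <- age[keep]
  rownames(cohort) <- NULL
  audit <- list(
    n_input = nrow(patients),
    n_retained = nrow(cohort),
    exclusions = as.list(table(factor(reason[!keep],
      levels = c("age_at_index", "no_diabetes_evidence", "prior_ami_scd"))))
  )
  if (!nrow(cohort)) warning("inclusion criteria retained no patients")
  attr(cohort, "audit") <- audit
  cohort
}

#' Flag baseline anaemia from haemoglobin and sex
#'
#' Anaemia is haemoglobin strictly below 13 g/dL in males and strictly below
#' 12 g/dL in females. Missing haemoglobin yields a missing flag.
#'
#' @param sex Character vector, `"male"`/`"female"`.
#' @param haemoglobin_g_dl Numeric haemoglobin in g/dL; must be positive
#'   where present.
#' @return Logical vector.
#' @export
flag_anaemia <- function(sex, haemoglobin_g_dl) {
  if (any(haemoglobin_g_dl <= 0, na.rm = TRUE))
    stop("haemoglobin must be positive")
  thr <- ifelse(sex == "male", 13, 12)
  ifelse(is.na(haemoglobin_g_dl), NA, haemoglobin_g_dl < thr)
}

#' Mean of a lab over a calendar window
#'
#' Arithmetic mean of the values of `lab_name` measured inside the closed
#' window; `NA` when there is no in-window value.
#'
#' @param labs Lab rows (one patient's, or any subset).
#' @param lab_name Lab to average.
#' @param window Length-2 vector of dates, closed on both ends.
#' @return Numeric scalar or `NA`.
#' @export
window_mean_lab <- function(labs, lab_name, window) {
  window <- as.Date(window)
  v <- labs$value[labs$lab_name == lab_name &
                    labs$measured_date >= window[1] &
                    labs$measured_date <= window[2]]
  if (!length(v)) return(NA_real_)
  mean(v)
}

# Per-patient window means for a set of labs; returns a data frame keyed by
# patient_id with one column per lab.
window_mean_labs_by_patient <- function(labs, lab_names, window, patient_ids) {
  window <- as.Date(window)
  out <- data.frame(patient_id = patient_ids, stringsAsFactors = FALSE)
  inw <- labs[labs$measured_date >= window[1] & labs$measured_date <= window[2], ]
  for (ln in lab_names) {
    sub <- inw[inw$lab_name == ln, ]
    m <- tapply(sub$value, sub$patient_id, mean)
    out[[ln]] <- as.numeric(m[match(patient_ids, names(m))])
  }
  out
}

#' Derive the survival outcome for each cohort patient
#'
#' For the requested outcome, the event time is the number of days from the
#' index date to the first qualifying episode in `(index, follow_up_end]`;
#' patients without a qualifying episode are censored at the earlier of
#' death and the administrative end of follow-up. For `non_AMI_SCD`, a
#' patient is marked excluded (not censored) when any SCD episode has an AMI
#' episode within `ami_scd_link_days` days on either side (AMI-related SCD),
#' or when any AMI precedes the first SCD episode. `episode_count` counts
#' all qualifying episodes during follow-up.
#'
#' @param cohort Retained patients from [apply_inclusion()].
#' @param episodes Episode table.
#' @param outcome `"AMI"` or `"non_AMI_SCD"`.
#' @param config A [study_config()].
#' @return Data frame with `patient_id`, `time_days`, `event`,
#'   `episode_count`, `excluded`, `exclusion_reason`; the exclusion audit is
#'   attached as `attr(, "audit")`.
#' @export
derive_outcome <- function(cohort, episodes, outcome = c("AMI", "non_AMI_SCD"),
                           config) {
  outcome <- match.arg(outcome)
  idx <- config$index_date
  end <- config$follow_up_end
  kind <- if (outcome == "AMI") "AMI" else "SCD"

  ep <- episodes[episodes$patient_id %in% cohort$patient_id, ]
  target <- ep[ep$kind == kind, ]
  if (any(target$episode_date <= idx))
    stop("found ", kind, " episode on or before index for a retained patient; ",
         "inclusion should have excluded it")
  target <- target[target$episode_date <= end, ]
  ami <- ep[ep$kind == "AMI", ]

  n <- nrow(cohort)
  time_days <- integer(n)
  event <- integer(n)
  count <- integer(n)
  excluded <- logical(n)
  reason <- rep(NA_character_, n)
  span <- as.integer(end - idx)

  tgt_split <- split(as.integer(target$episode_date - idx), target$patient_id)
  ami_split <- split(as.integer(ami$episode_date - idx), ami$patient_id)

  for (i in seq_len(n)) {
    pid <- cohort$patient_id[i]
    tt <- sort(tgt_split[[pid]])
    if (outcome == "non_AMI_SCD" && length(tt)) {
      aa <- ami_split[[pid]]
      if (length(aa)) {
        linked <- any(vapply(tt, function(s) any(abs(aa - s) <= config$ami_scd_link_days),
                             logical(1)))
        prior <- any(aa < tt[1])
        if (linked) { excluded[i] <- TRUE; reason[i] <- "ami_linked_scd" }
        else if (prior) { excluded[i] <- TRUE; reason[i] <- "ami_prior_to_scd" }
        if (excluded[i]) next
      }
    }
    if (length(tt)) {
      time_days[i] <- tt[1]
      event[i] <- 1L
      count[i] <- length(tt)
    } else {
      dd <- cohort$death_date[i]
      time_days[i] <- if (!is.na(dd)) min(as.integer(dd - idx), span) else span
      event[i] <- 0L
      count[i] <- 0L
    }
  }
  out <- data.frame(patient_id = cohort$patient_id, time_days = time_days,
                    event = event, episode_count = count,
                    excluded = excluded, exclusion_reason = reason,
                    stringsAsFactors = FALSE)
  attr(out, "audit") <- list(
    outcome = outcome,
    n = n,
    n_excluded = sum(excluded),
    exclusions = as.list(table(factor(reason[excluded],
      levels = c("ami_linked_scd", "ami_prior_to_scd")))),
    n_events = sum(out$event[!out$excluded])
  )
  out
}

#' Annualized event rate and mean annual event frequency
#'
#' The annualized rate is 100 times the total number of episodes across the
#' cohort divided by the total patient-years of follow-up (365.25 days per
#' year), i.e. episodes per 100 patient-years. The mean annual frequency
#' averages each patient's episodes-per-year over patients who experienced
#' the event; it is `NA` when no patient did. Excluded patients are ignored.
#'
#' @param outcomes Data frame from [derive_outcome()] (or any frame with
#'   `time_days`, `event`, `episode_count`, optionally `excluded`).
#' @return List with `annualized_rate_pct_per_year` and
#'   `mean_annual_frequency`.
#' @export
event_rate_summary <- function(outcomes) {
  if (!is.null(outcomes$excluded)) outcomes <- outcomes[!outcomes$excluded, ]
  if (!nrow(outcomes)) stop("no patients to summarize")
  years <- outcomes$time_days / 365.25
  total_years <- sum(years)
  if (total_years <= 0) stop("zero total patient-years of follow-up")
  rate <- 100 * sum(outcomes$episode_count) / total_years
  ev <- outcomes$event == 1
  freq <- if (any(ev)) mean(outcomes$episode_count[ev] / years[ev]) else NA_real_
  list(annualized_rate_pct_per_year = rate, mean_annual_frequency = freq)
}
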