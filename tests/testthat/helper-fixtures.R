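# Build bottle-level data frames compactly; arguments are recycled to the
# longest length, times are hour offsets from a fixed base.

BASE_TIME <- as.POSIXct("2023-03-01T00:00:00", format = "%Y-%m-%dT%H:%M:%S",
                        tz = "UTC")

bottle_df <- function(patient = "P1", age = 50L, center = "C1",
                      area = "MEDICAL", service = "MED-1", sample = NULL,
                      bottle = NULL, origin = "PV", type = "AEROBIC",
                      hours = 0, status = "NEGATIVE", organisms = "",
                      volume = 8) {
  n <- max(lengths(list(patient, sample, bottle, origin, type, hours,
                        status, organisms, volume, area, service)), 1L)
  if (is.null(sample)) sample <- paste0("S", seq_len(n))
  if (is.null(bottle)) bottle <- sprintf("b%03d", seq_len(n))
  data.frame(
    patient_id = rep_len(patient, n), age_years = rep_len(age, n),
    center = rep_len(center, n), area = rep_len(area, n),
    hospital_service = rep_len(service, n),
    sample_id = rep_len(sample, n), bottle_id = rep_len(bottle, n),
    specimen_origin = rep_len(origin, n), bottle_type = rep_len(type, n),
    collected_at = BASE_TIME + rep_len(hours, n) * 3600,
    status = rep_len(status, n), organisms = rep_len(organisms, n),
    volume_ml = rep_len(volume, n), stringsAsFactors = FALSE)
}

# random cohort whose anchored windows genuinely interact (times spread over
# a few days, several patients and areas)
random_cohort <- function(n_bottles, n_patients = 3, seed = 1) {
  set.seed(seed)
  df <- bottle_df(
    patient = sprintf("P%d", sample.int(n_patients, n_bottles, TRUE)),
    area = sample(c("MEDICAL", "ICU"), n_bottles, TRUE),
    sample = sprintf("S%03d", sample.int(ceiling(n_bottles / 1.5),
                                         n_bottles, TRUE)),
    origin = sample(c("PV", "CVC"), n_bottles, TRUE, prob = c(0.8, 0.2)),
    type = sample(c("AEROBIC", "ANAEROBIC"), n_bottles, TRUE),
    hours = round(runif(n_bottles, 0, 120), 2),
    status = sample(c("POSITIVE", "NEGATIVE"), n_bottles, TRUE,
                    prob = c(0.3, 0.7)))
  df$organisms <- ifelse(df$status == "POSITIVE",
                         sample(c("Escherichia coli",
                                  "Staphylococcus epidermidis",
                                  "Micrococcus luteus"), n_bottles, TRUE),
                         "")
  # sample ids must stay within one patient: make them patient-scoped
  df$sample_id <- paste0(df$patient_id, "_", df$sample_id)
  # a sampling procedure happens at one time and place: collapse each
  # sample group onto its first bottle's time/area/origin
  sp <- split(seq_len(nrow(df)), df$sample_id)
  for (idx in sp) {
    df$collected_at[idx] <- df$collected_at[idx[1]]
    df$area[idx] <- df$area[idx[1]]
    df$specimen_origin[idx] <- df$specimen_origin[idx[1]]
  }
  df
}
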