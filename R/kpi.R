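## KPI computation stratified by center, hospitalization area and hospital
## service.
##
## KPI 1  mean blood volume per bottle (and per episode); bottles without a
##        volume are excluded from numerator and denominator (never imputed
##        as 0) and counted in n_missing.
## KPI 2  solitary episodes / all episodes (PV and CVC alike) x 100.
## KPI 3  unpaired CVC episodes / CVC episodes x 100.
## KPI 4a restrictive contaminations / non-solitary PV episodes x 100.
## KPI 4b (restrictive + confirmed after review) / non-solitary PV x 100.
## Plus auxiliary indicators: positivity, bottles/episode, episodes/patient,
## BC sets per 1,000 patient-days.
##
## Every cell carries its raw numerator and denominator; a zero denominator
## leaves the value undefined (NA) and the cell non-displayable.

KPI_IDS <- c("KPI1_BOTTLE", "KPI1_EPISODE", "KPI2", "KPI3", "KPI4A", "KPI4B",
             "POSITIVITY", "BOTTLES_PER_EPISODE", "EPISODES_PER_PATIENT",
             "SETS_PER_1000PD")

STRATUM_LEVELS <- c("OVERALL", "CENTER", "AREA", "SERVICE", "CENTER_X_AREA")

## display precision per KPI (Table-style): rates 1 decimal, means 2
kpi_display_digits <- function(kpi_id) {
  ifelse(kpi_id %in% c("KPI2", "KPI3", "KPI4A", "KPI4B", "POSITIVITY",
                       "SETS_PER_1000PD"), 1L, 2L)
}

kpi_is_rate <- function(kpi_id) {
  kpi_id %in% c("KPI2", "KPI3", "KPI4A", "KPI4B", "POSITIVITY")
}

stratum_of <- function(df, level) {
  switch(level,
    OVERALL = rep("ALL", nrow(df)),
    CENTER = df$center,
    AREA = df$area,
    SERVICE = paste(df$center, df$hospital_service, sep = "/"),
    CENTER_X_AREA = paste(df$center, df$area, sep = "/"),
    stop("unknown stratification level: ", level))
}

## sum a numerator/denominator pair by stratum and emit cells
ratio_cells <- function(level, labels, num, den, kpi_id, scale = 1,
                        n_missing = NULL) {
  dt <- data.table::data.table(stratum_label = labels, num = num, den = den,
    miss = if (is.null(n_missing)) 0L else n_missing)
  agg <- dt[, .(numerator = sum(num), denominator = sum(den),
                n_missing = sum(miss)), by = stratum_label]
  agg[, value := ifelse(denominator > 0, scale * numerator / denominator,
                        NA_real_)]
  data.frame(stratum_level = rep(level, nrow(agg)),
             stratum_label = agg$stratum_label,
             kpi_id = rep(kpi_id, nrow(agg)), numerator = agg$numerator,
             denominator = agg$denominator, value = agg$value,
             displayable = !is.na(agg$value), n_missing = agg$n_missing,
             stringsAsFactors = FALSE)
}

#' KPI 1: mean blood volume
#'
#' Bottle-level value is the bottle-count-weighted mean of `volume_ml` over
#' bottles with a known volume (so aggregating strata reproduces the
#' overall mean exactly). Episode-level value is the mean, over episodes
#' with at least one known volume, of each episode's summed known volumes.
#' `n_missing` counts volume-less bottles (bottle level) and episodes with
#' no usable volume (episode level).
#'
#' @param episodes a [build_episodes()] result.
#' @param level stratification level(s), subset of
#'   `c("OVERALL","CENTER","AREA","SERVICE","CENTER_X_AREA")`.
#' @return data frame of KPI cells (`KPI1_BOTTLE` and `KPI1_EPISODE`).
#' @export
kpi1_volume <- function(episodes, level = "OVERALL") {
  stopifnot(inherits(episodes, "bc_episodes"))
  b <- episodes$bottles
  e <- episodes$episodes
  known <- !is.na(b$volume_ml)
  ep_known <- !is.na(e$total_volume_ml)
  do.call(rbind, lapply(level, function(lv) {
    rbind(
      ratio_cells(lv, stratum_of(b, lv),
                  num = ifelse(known, b$volume_ml, 0),
                  den = as.numeric(known), kpi_id = "KPI1_BOTTLE",
                  n_missing = as.integer(!known)),
      ratio_cells(lv, stratum_of(e, lv),
                  num = ifelse(ep_known, e$total_volume_ml, 0),
                  den = as.numeric(ep_known), kpi_id = "KPI1_EPISODE",
                  n_missing = as.integer(!ep_known)))
  }))
}

#' KPI 2: rate of solitary episodes
#'
#' Solitary episodes (a single BC set or single bottle) over all episodes,
#' PV and CVC alike, as a percentage.
#'
#' @inheritParams kpi1_volume
#' @return data frame of `KPI2` cells.
#' @export
kpi2_solitary <- function(episodes, level = "OVERALL") {
  stopifnot(inherits(episodes, "bc_episodes"))
  e <- episodes$episodes
  do.call(rbind, lapply(level, function(lv) {
    ratio_cells(lv, stratum_of(e, lv), num = as.numeric(e$is_solitary),
                den = rep(1, nrow(e)), kpi_id = "KPI2", scale = 100)
  }))
}

#' KPI 3: rate of unpaired CVC episodes
#'
#' CVC episodes without any peripheral-vein bottle over all CVC episodes,
#' as a percentage. Strata without CVC episodes are undefined.
#'
#' @inheritParams kpi1_volume
#' @return data frame of `KPI3` cells.
#' @export
kpi3_unpaired_cvc <- function(episodes, level = "OVERALL") {
  stopifnot(inherits(episodes, "bc_episodes"))
  e <- episodes$episodes
  cvc <- e$episode_type == "CVC"
  do.call(rbind, lapply(level, function(lv) {
    ratio_cells(lv, stratum_of(e, lv),
                num = as.numeric(cvc & e$is_unpaired_cvc),
                den = as.numeric(cvc), kpi_id = "KPI3", scale = 100)
  }))
}

#' KPI 4: contamination rates
#'
#' Contaminated episodes over non-solitary PV episodes, as a percentage.
#' Mode `"restrictive"` (KPI 4a) counts `RESTRICTIVE_CONTAMINATION` only;
#' `"after_review"` (KPI 4b) adds `CONFIRMED_AFTER_REVIEW` on the same
#' denominator, so KPI 4b >= KPI 4a in every stratum.
#'
#' @inheritParams kpi1_volume
#' @param assessments a [assess_episodes()] result (with adjudications
#'   applied for `"after_review"`).
#' @param mode `"restrictive"` or `"after_review"`.
#' @return data frame of `KPI4A`/`KPI4B` cells.
#' @export
kpi4_contamination <- function(episodes, assessments,
                               mode = c("restrictive", "after_review"),
                               level = "OVERALL") {
  stopifnot(inherits(episodes, "bc_episodes"),
            inherits(assessments, "bc_assessments"))
  mode <- match.arg(mode)
  e <- episodes$episodes
  cat_of <- assessments$category[match(e$episode_id, assessments$episode_id)]
  eligible <- e$episode_type == "PV" & !e$is_solitary
  contaminated <- if (mode == "restrictive") {
    cat_of == "RESTRICTIVE_CONTAMINATION"
  } else {
    cat_of %in% c("RESTRICTIVE_CONTAMINATION", "CONFIRMED_AFTER_REVIEW")
  }
  kpi_id <- if (mode == "restrictive") "KPI4A" else "KPI4B"
  do.call(rbind, lapply(level, function(lv) {
    ratio_cells(lv, stratum_of(e, lv),
                num = as.numeric(eligible & contaminated),
                den = as.numeric(eligible), kpi_id = kpi_id, scale = 100)
  }))
}

#' Auxiliary indicators
#'
#' `POSITIVITY` (% of episodes with at least one positive bottle;
#' `exclude_contaminated = TRUE` removes confirmed contaminations from the
#' numerator), `BOTTLES_PER_EPISODE`, `EPISODES_PER_PATIENT`, and --- when
#' `patient_days` is supplied --- `SETS_PER_1000PD` (BC sets ordered per
#' 1,000 patient-days).
#'
#' @inheritParams kpi1_volume
#' @param patient_days optional named numeric vector mapping stratum label
#'   to patient-days (use name `"ALL"` for the overall stratum); without
#'   it the `SETS_PER_1000PD` cells are omitted.
#' @param assessments optional, needed for `exclude_contaminated`.
#' @param exclude_contaminated drop confirmed contaminations from the
#'   positivity numerator.
#' @return data frame of auxiliary KPI cells.
#' @export
auxiliary_indicators <- function(episodes, level = "OVERALL",
                                 patient_days = NULL, assessments = NULL,
                                 exclude_contaminated = FALSE) {
  stopifnot(inherits(episodes, "bc_episodes"))
  e <- episodes$episodes
  s <- episodes$sets
  s_idx <- match(s$episode_id, e$episode_id)
  positive <- e$is_positive
  if (exclude_contaminated) {
    if (is.null(assessments)) {
      stop("exclude_contaminated requires assessments")
    }
    cat_of <- assessments$category[match(e$episode_id,
                                         assessments$episode_id)]
    positive <- positive & !cat_of %in%
      c("RESTRICTIVE_CONTAMINATION", "CONFIRMED_AFTER_REVIEW")
  }
  do.call(rbind, lapply(level, function(lv) {
    lab_e <- stratum_of(e, lv)
    out <- rbind(
      ratio_cells(lv, lab_e, num = as.numeric(positive),
                  den = rep(1, nrow(e)), kpi_id = "POSITIVITY", scale = 100),
      ratio_cells(lv, lab_e, num = e$n_bottles, den = rep(1, nrow(e)),
                  kpi_id = "BOTTLES_PER_EPISODE"))
    ## episodes per distinct patient within the stratum
    pat <- data.table::data.table(lab = lab_e, patient_id = e$patient_id)
    agg <- pat[, .(numerator = .N,
                   denominator = data.table::uniqueN(patient_id)), by = lab]
    out <- rbind(out, data.frame(
      stratum_level = rep(lv, nrow(agg)), stratum_label = agg$lab,
      kpi_id = rep("EPISODES_PER_PATIENT", nrow(agg)),
      numerator = agg$numerator,
      denominator = agg$denominator,
      value = agg$numerator / agg$denominator,
      displayable = rep(TRUE, nrow(agg)),
      n_missing = rep(0L, nrow(agg)), stringsAsFactors = FALSE))
    if (!is.null(patient_days)) {
      lab_s <- stratum_of(e, lv)[s_idx]
      nsets <- data.table::data.table(lab = lab_s)[, .(n = .N), by = lab]
      pd <- patient_days[match(nsets$lab, names(patient_days))]
      out <- rbind(out, data.frame(
        stratum_level = rep(lv, nrow(nsets)), stratum_label = nsets$lab,
        kpi_id = rep("SETS_PER_1000PD", nrow(nsets)), numerator = nsets$n,
        denominator = ifelse(is.na(pd), 0, pd),
        value = ifelse(!is.na(pd) & pd > 0, 1000 * nsets$n / pd, NA_real_),
        displayable = !is.na(pd) & pd > 0,
        n_missing = rep(0L, nrow(nsets)), stringsAsFactors = FALSE))
    }
    out
  }))
}

#' Full KPI report
#'
#' Computes all KPI cells at the requested stratification levels and
#' applies the service-level display thresholds. One cell per
#' (stratum, KPI) pair; raw numerators and denominators are always kept.
#'
#' @inheritParams auxiliary_indicators
#' @param assessments a [assess_episodes()] result (adjudications applied
#'   upstream if available); without it the KPI 4 cells are omitted.
#' @param levels stratification levels to compute.
#' @param thresholds display thresholds, see [apply_display_thresholds()].
#' @return object of class `bc_kpi_report`: data frame of cells with
#'   attributes `config` (parameters snapshot) and `generated_at`.
#' @export
kpi_report <- function(episodes, assessments = NULL,
                       levels = c("OVERALL", "CENTER", "AREA", "SERVICE"),
                       patient_days = NULL,
                       thresholds = display_thresholds()) {
  stopifnot(inherits(episodes, "bc_episodes"))
  levels <- match.arg(levels, STRATUM_LEVELS, several.ok = TRUE)
  cells <- rbind(
    kpi1_volume(episodes, levels),
    kpi2_solitary(episodes, levels),
    kpi3_unpaired_cvc(episodes, levels),
    if (!is.null(assessments)) {
      rbind(kpi4_contamination(episodes, assessments, "restrictive", levels),
            kpi4_contamination(episodes, assessments, "after_review", levels))
    },
    auxiliary_indicators(episodes, levels, patient_days = patient_days))
  cells$stratum_level <- factor(cells$stratum_level, levels = STRATUM_LEVELS)
  cells$kpi_id <- factor(cells$kpi_id, levels = KPI_IDS)
  cells <- cells[order(cells$stratum_level, cells$stratum_label,
                       cells$kpi_id), , drop = FALSE]
  cells$stratum_level <- as.character(cells$stratum_level)
  cells$kpi_id <- as.character(cells$kpi_id)
  rownames(cells) <- NULL
  out <- structure(cells, class = c("bc_kpi_report", "data.frame"))
  attr(out, "config") <- list(
    window_hours = episodes$window_hours, grouping = episodes$grouping,
    device_as = episodes$device_as, thresholds = unclass(thresholds))
  attr(out, "generated_at") <- format_timestamp(Sys.time())
  apply_display_thresholds(out, thresholds)
}

#' Display thresholds for service-level cells
#'
#' Representativeness thresholds: KPI 1 and KPI 2 service cells are shown
#' only for services with strictly more than `min_episodes` episodes;
#' KPI 3 only with strictly more than `min_cvc_episodes` CVC episodes.
#'
#' @param min_episodes threshold for KPI 1 and KPI 2 (default 500).
#' @param min_cvc_episodes threshold for KPI 3 (default 75).
#' @return a `bc_thresholds` list.
#' @export
display_thresholds <- function(min_episodes = 500, min_cvc_episodes = 75) {
  structure(list(min_episodes = min_episodes,
                 min_cvc_episodes = min_cvc_episodes),
            class = "bc_thresholds")
}

#' Gray out service-level cells below the representativeness thresholds
#'
#' Sets `displayable = FALSE` for `SERVICE`-level KPI 1/KPI 2 cells whose
#' stratum has `<= min_episodes` episodes and KPI 3 cells with
#' `<= min_cvc_episodes` CVC episodes (strict thresholds). Cells with an
#' undefined value stay non-displayable.
#'
#' @param report a [kpi_report()].
#' @param thresholds a [display_thresholds()].
#' @return the report with updated `displayable` flags.
#' @export
apply_display_thresholds <- function(report,
                                     thresholds = display_thresholds()) {
  stopifnot(inherits(report, "bc_kpi_report"))
  sv <- report$stratum_level == "SERVICE"
  if (any(sv)) {
    ## episode counts per service from the KPI2 denominator, CVC counts
    ## from the KPI3 denominator
    ep_n <- report$denominator[sv & report$kpi_id == "KPI2"]
    names(ep_n) <- report$stratum_label[sv & report$kpi_id == "KPI2"]
    cvc_n <- report$denominator[sv & report$kpi_id == "KPI3"]
    names(cvc_n) <- report$stratum_label[sv & report$kpi_id == "KPI3"]
    k12 <- sv & report$kpi_id %in% c("KPI1_BOTTLE", "KPI1_EPISODE", "KPI2")
    report$displayable[k12] <- report$displayable[k12] &
      ep_n[report$stratum_label[k12]] > thresholds$min_episodes
    k3 <- sv & report$kpi_id == "KPI3"
    report$displayable[k3] <- report$displayable[k3] &
      cvc_n[report$stratum_label[k3]] > thresholds$min_cvc_episodes
  }
  cfg <- attr(report, "config")
  cfg$thresholds <- unclass(thresholds)
  attr(report, "config") <- cfg
  report
}

#' @export
print.bc_kpi_report <- function(x, digits_override = NULL, ...) {
  cat("<bc_kpi_report> ", nrow(x), " cell(s)\n", sep = "")
  ov <- x[x$stratum_level == "OVERALL", , drop = FALSE]
  if (nrow(ov)) {
    cat("Overall:\n")
    for (i in seq_len(nrow(ov))) {
      d <- if (is.null(digits_override)) kpi_display_digits(ov$kpi_id[i])
           else digits_override
      val <- if (is.na(ov$value[i])) "undefined" else
        formatC(round(ov$value[i], d), format = "f", digits = d)
      cat(sprintf("  %-20s %s%s  (%s / %s)\n", ov$kpi_id[i], val,
                  if (kpi_is_rate(ov$kpi_id[i])) "%" else "",
                  format(ov$numerator[i], trim = TRUE),
                  format(ov$denominator[i], trim = TRUE)))
    }
  }
  lv <- setdiff(unique(x$stratum_level), "OVERALL")
  if (length(lv)) {
    cat("Also stratified by:", paste(lv, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a KPI report (machine formats)
#'
#' Long-format CSV (`stratum_level,stratum_label,kpi_id,numerator,
#' denominator,value,displayable,n_missing`) or a JSON mirror carrying the
#' configuration snapshot. The machine CSV contains no timestamp, so
#' re-running the same input and configuration is byte-identical.
#'
#' @param report a [kpi_report()].
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_kpi_report <- function(report, path, format = c("csv", "json")) {
  stopifnot(inherits(report, "bc_kpi_report"))
  format <- match.arg(format)
  df <- as.data.frame(report)
  if (format == "csv") {
    write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  } else {
    jsonlite::write_json(
      list(config = attr(report, "config"), cells = df),
      path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}
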