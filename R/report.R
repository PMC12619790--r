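## End-to-end pipeline driver and service-level report rendering.

#' Run the full KPI pipeline on a bottle-level file
#'
#' read -> adult filter -> sets -> episodes -> contamination assessment
#' (automatic review, optional adjudications) -> KPI cells -> display
#' thresholds. Writes, under `out_dir`: `episodes.csv`, `kpi_report.csv`,
#' `kpi_report.json`, `rejects.csv`, `review_queue.csv`, `heatmap.csv`,
#' `heatmap.html` and `run_config.json`. The machine CSVs carry no
#' timestamp, so re-running the same input and configuration is
#' byte-identical; the generation time lives in `run_log.txt`.
#'
#' @param input path to a bottle-level CSV/JSONL file, or a [bc_cohort()].
#' @param out_dir output directory (created if needed); `NULL` skips file
#'   output and returns the objects only.
#' @param period optional `c(start, end)` ISO-8601 bounds.
#' @param min_age adult filter threshold (inclusive; default 18).
#' @param window_hours,grouping,set_mode,device_as passed to
#'   [build_episodes()].
#' @param panel a [contaminant_panel()].
#' @param set_structure `"mss"` or `"sss"`, see [assess_episodes()].
#' @param adjudications optional adjudications CSV path or data frame.
#' @param levels stratification levels for the report.
#' @param patient_days optional named vector for the sets-per-1,000
#'   patient-days indicator.
#' @param thresholds a [display_thresholds()].
#' @return list of class `bc_run`: `cohort`, `episodes`, `assessments`,
#'   `report`, `ranking`, and `paths` (when files were written).
#' @export
run_compute <- function(input, out_dir = NULL, period = NULL, min_age = 18,
                        window_hours = 24, grouping = "patient_area",
                        set_mode = "strict", device_as = "cvc",
                        panel = contaminant_panel(),
                        set_structure = "mss", adjudications = NULL,
                        levels = c("OVERALL", "CENTER", "AREA", "SERVICE"),
                        patient_days = NULL,
                        thresholds = display_thresholds()) {
  t0 <- Sys.time()
  cohort <- if (inherits(input, "bc_cohort")) {
    input
  } else {
    read_bottles(input,
                 period_start = if (!is.null(period)) period[1],
                 period_end = if (!is.null(period)) period[2])
  }
  cohort <- filter_adults(cohort, min_age = min_age)
  episodes <- build_episodes(cohort, window_hours = window_hours,
                             grouping = grouping, set_mode = set_mode,
                             device_as = device_as)
  assessments <- assess_episodes(episodes, panel = panel,
                                 auto_review = TRUE,
                                 set_structure = set_structure)
  if (!is.null(adjudications)) {
    adj <- if (is.character(adjudications)) read_adjudications(adjudications)
           else adjudications
    assessments <- apply_adjudications(assessments, adj)
  }
  report <- kpi_report(episodes, assessments, levels = levels,
                       patient_days = patient_days, thresholds = thresholds)
  ranking <- contaminant_species_ranking(assessments, panel = panel)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      episodes = file.path(out_dir, "episodes.csv"),
      report_csv = file.path(out_dir, "kpi_report.csv"),
      report_json = file.path(out_dir, "kpi_report.json"),
      rejects = file.path(out_dir, "rejects.csv"),
      review_queue = file.path(out_dir, "review_queue.csv"),
      heatmap_csv = file.path(out_dir, "heatmap.csv"),
      heatmap_html = file.path(out_dir, "heatmap.html"),
      run_config = file.path(out_dir, "run_config.json"),
      run_log = file.path(out_dir, "run_log.txt"))
    write_episodes(episodes, paths[["episodes"]])
    write_kpi_report(report, paths[["report_csv"]], "csv")
    write_kpi_report(report, paths[["report_json"]], "json")
    write_rejects(cohort, paths[["rejects"]])
    export_review_queue(episodes, assessments, paths[["review_queue"]])
    if (any(report$stratum_level == "SERVICE")) {
      render_heatmap(report, paths[["heatmap_csv"]], "csv")
      render_heatmap(report, paths[["heatmap_html"]], "html")
    } else {
      paths <- paths[!names(paths) %in% c("heatmap_csv", "heatmap_html")]
    }
    cfg <- list(min_age = min_age, window_hours = window_hours,
                grouping = grouping, set_mode = set_mode,
                device_as = device_as, set_structure = set_structure,
                levels = levels, thresholds = unclass(thresholds))
    jsonlite::write_json(cfg, paths[["run_config"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    writeLines(c(
      sprintf("generated_at: %s", format_timestamp(Sys.time())),
      sprintf("elapsed_s: %.1f",
              as.numeric(difftime(Sys.time(), t0, units = "secs"))),
      sprintf("bottles: %d (rejected rows: %d)", nrow(cohort$records),
              length(unique(cohort$rejects$row))),
      sprintf("episodes: %d", nrow(episodes$episodes))),
      paths[["run_log"]])
  }
  structure(list(cohort = cohort, episodes = episodes,
                 assessments = assessments, report = report,
                 ranking = ranking, paths = paths),
            class = "bc_run")
}

#' @export
print.bc_run <- function(x, ...) {
  cat("<bc_run>\n")
  print(x$episodes)
  print(x$report)
  invisible(x)
}

## benchmark reference lines drawn on the heatmap (configurable):
## volume per bottle should reach 8.0 mL, solitary rate should stay <= 10%
default_benchmarks <- function() {
  c(KPI1_BOTTLE = 8.0, KPI2 = 10.0)
}

heatmap_kpis <- c("KPI1_BOTTLE", "KPI2", "KPI3", "KPI4A", "KPI4B")

## criticality in [0, 1]: linear between stratum min and max per KPI; low
## volume is worse for KPI 1, high rates are worse for KPIs 2-4
criticality_scores <- function(values, kpi_id) {
  if (all(is.na(values))) return(rep(NA_real_, length(values)))
  rng <- range(values, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) {
    return(ifelse(is.na(values), NA_real_, 0))
  }
  x <- (values - rng[1]) / (rng[2] - rng[1])
  if (kpi_id == "KPI1_BOTTLE") 1 - x else x
}

#' Render the service-level KPI heatmap
#'
#' One row per hospital service, one column per KPI. Cells below the
#' representativeness thresholds are gray/NA; color intensity scales
#' linearly with criticality within each KPI column (low volume is worse
#' for KPI 1, high rates are worse for KPIs 2-4). The CSV variant encodes
#' the value, displayable flag and criticality score as columns; the HTML
#' variant renders a colored table with benchmark reference values
#' (volume >= 8.0 mL, solitary <= 10%) in the column headers.
#'
#' @param report a [kpi_report()] computed with the `SERVICE` level.
#' @param path output file.
#' @param format `"csv"` or `"html"`.
#' @param benchmarks named vector of reference values shown in headers.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(report, path, format = c("csv", "html"),
                           benchmarks = default_benchmarks()) {
  stopifnot(inherits(report, "bc_kpi_report"))
  format <- match.arg(format)
  sv <- report[report$stratum_level == "SERVICE" &
                 report$kpi_id %in% heatmap_kpis, , drop = FALSE]
  if (!nrow(sv)) stop("report has no SERVICE-level cells")
  services <- sort(unique(sv$stratum_label))
  kpis <- intersect(heatmap_kpis, unique(sv$kpi_id))

  grid <- expand.grid(service = services, kpi_id = kpis,
                      stringsAsFactors = FALSE)
  idx <- match(paste(grid$service, grid$kpi_id),
               paste(sv$stratum_label, sv$kpi_id))
  grid$value <- sv$value[idx]
  grid$displayable <- sv$displayable[idx] & !is.na(sv$value[idx])
  grid$value[!grid$displayable] <- NA_real_
  grid$critical <- NA_real_
  for (k in kpis) {
    sel <- grid$kpi_id == k
    grid$critical[sel] <- criticality_scores(grid$value[sel], k)
  }

  if (format == "csv") {
    wide <- data.frame(service = services, stringsAsFactors = FALSE)
    for (k in kpis) {
      sel <- grid$kpi_id == k
      m <- match(services, grid$service[sel])
      wide[[paste0(k, "_value")]] <-
        round(grid$value[sel][m], kpi_display_digits(k))
      wide[[paste0(k, "_displayable")]] <- grid$displayable[sel][m]
      wide[[paste0(k, "_criticality")]] <- round(grid$critical[sel][m], 3)
    }
    write.csv(wide, path, row.names = FALSE, quote = TRUE, na = "")
    return(invisible(path))
  }

  cell_html <- function(value, crit, kpi) {
    if (is.na(value)) {
      return("<td style=\"background:#cccccc;text-align:center\">&ndash;</td>")
    }
    red <- 255
    gb <- round(255 * (1 - ifelse(is.na(crit), 0, crit)))
    sprintf("<td style=\"background:rgb(%d,%d,%d);text-align:right\">%s</td>",
            red, gb, gb,
            formatC(round(value, kpi_display_digits(kpi)), format = "f",
                    digits = kpi_display_digits(kpi)))
  }
  hdr <- vapply(kpis, function(k) {
    bm <- benchmarks[k]
    sprintf("<th>%s%s</th>", k,
            if (!is.na(bm)) sprintf(" (ref %s)", format(bm)) else "")
  }, character(1))
  rows <- vapply(services, function(s) {
    cells <- vapply(kpis, function(k) {
      g <- grid[grid$service == s & grid$kpi_id == k, ]
      cell_html(g$value, g$critical, k)
    }, character(1))
    sprintf("<tr><td>%s</td>%s</tr>", s, paste(cells, collapse = ""))
  }, character(1))
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"><title>BC KPI heatmap</title>",
    "<style>table{border-collapse:collapse}td,th{border:1px solid #888;padding:4px 8px;font-family:sans-serif;font-size:13px}</style>",
    "</head><body>",
    "<table>",
    sprintf("<tr><th>hospital service</th>%s</tr>", paste(hdr, collapse = "")),
    rows,
    "</table>",
    "<p>Gray cells: below the representativeness threshold. Red intensity scales with criticality (low volume / high rates).</p>",
    "</body></html>")
  writeLines(html, path)
  invisible(path)
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file mirroring the arguments of [run_compute()] (and a
#' `panel:` section mirroring [contaminant_panel()]). Unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path YAML file.
#' @return named list of `run_compute()` arguments.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("input", "out_dir", "period", "min_age", "window_hours",
               "grouping", "set_mode", "device_as", "set_structure",
               "adjudications", "levels", "patient_days", "thresholds",
               "panel", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$thresholds)) {
    cfg$thresholds <- do.call(display_thresholds, cfg$thresholds)
  }
  if (!is.null(cfg$panel)) {
    cfg$panel <- do.call(contaminant_panel, cfg$panel)
  }
  if (!is.null(cfg$patient_days)) {
    cfg$patient_days <- unlist(cfg$patient_days)
  }
  cfg
}
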