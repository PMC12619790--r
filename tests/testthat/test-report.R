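fixture_path <- function() {
  system.file("extdata", "bc_fixture_30.csv", package = "bckpi")
}

test_that("run_compute writes the full output set and is byte-stable", {
  out1 <- tempfile("run1_"); out2 <- tempfile("run2_")
  r1 <- suppressMessages(run_compute(fixture_path(), out_dir = out1,
                                     levels = c("OVERALL", "AREA",
                                                "SERVICE")))
  r2 <- suppressMessages(run_compute(fixture_path(), out_dir = out2,
                                     levels = c("OVERALL", "AREA",
                                                "SERVICE")))
  for (f in c("episodes.csv", "kpi_report.csv", "rejects.csv",
              "review_queue.csv", "heatmap.csv", "heatmap.html",
              "run_config.json")) {
    expect_true(file.exists(file.path(out1, f)), info = f)
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), info = f)
  }
  expect_s3_class(r1$report, "bc_kpi_report")
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("every number in the heatmap traces back to a report cell", {
  out <- tempfile("run_")
  r <- suppressMessages(run_compute(
    fixture_path(), out_dir = out, levels = c("OVERALL", "SERVICE"),
    thresholds = display_thresholds(min_episodes = 0, min_cvc_episodes = 0)))
  hm <- read.csv(file.path(out, "heatmap.csv"), check.names = FALSE)
  rep <- r$report
  expect_gt(nrow(hm), 0)
  n_checked <- 0
  for (k in c("KPI2", "KPI3")) {
    col <- paste0(k, "_value")
    for (i in seq_len(nrow(hm))) {
      cell <- rep[rep$stratum_level == "SERVICE" &
                    rep$stratum_label == hm$service[i] &
                    rep$kpi_id == k, ]
      if (!is.na(hm[[col]][i])) {
        expect_equal(hm[[col]][i], round(cell$value, 1))
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gt(n_checked, 4)
  unlink(out, recursive = TRUE)
})

test_that("heatmap criticality ranks higher rates as worse and grays
           sub-threshold cells", {
  mk_service <- function(svc, n, n_solitary) {
    samples <- sprintf("%s_S%04d", svc, seq_len(2 * n - n_solitary))
    # n_solitary single-set episodes, the rest two-set episodes
    sets_per_ep <- c(rep(1, n_solitary), rep(2, n - n_solitary))
    ep_of_set <- rep(seq_len(n), sets_per_ep)
    bottle_df(patient = sprintf("%s_P%03d", svc, ep_of_set),
              service = svc, sample = samples,
              bottle = sprintf("%s_b%04d", svc, seq_along(samples)),
              hours = (seq_along(samples) %% 2) * 0.5)
  }
  df <- rbind(mk_service("HI", 30, 20), mk_service("LO", 30, 5))
  ep <- build_episodes(bc_cohort(df))
  rep <- kpi_report(ep, levels = c("OVERALL", "SERVICE"),
                    thresholds = display_thresholds(min_episodes = 10,
                                                    min_cvc_episodes = 5))
  path <- tempfile(fileext = ".csv")
  render_heatmap(rep, path, "csv")
  hm <- read.csv(path, check.names = FALSE)
  hi <- hm[hm$service == "C1/HI", ]; lo <- hm[hm$service == "C1/LO", ]
  expect_gt(hi$KPI2_value, lo$KPI2_value)
  expect_gt(hi$KPI2_criticality, lo$KPI2_criticality)
  # no CVC episodes anywhere: KPI3 grayed
  expect_true(all(is.na(hm$KPI3_value)))
  html <- tempfile(fileext = ".html")
  render_heatmap(rep, html, "html")
  txt <- readLines(html)
  expect_true(any(grepl("<table>", txt)))
  expect_true(any(grepl("background:#cccccc", txt)))   # gray cells present
  unlink(c(path, html))
})

test_that("the review workflow round-trips adjudications and moves KPI 4b by
           exactly the applied decisions", {
  sim <- generate_cohort(simulation_config(seed = 4, n_patients = 50,
                                           p_contaminated = 0))
  sim <- inject_review_cases(sim, n_cases = 3)
  out <- tempfile("rev_")
  r <- suppressMessages(run_compute(sim$cohort, out_dir = out))
  queue <- read.csv(file.path(out, "review_queue.csv"),
                    colClasses = "character")
  expect_equal(nrow(queue), 6)    # 3 auto-confirmed + 3 open candidates

  k4b_before <- r$report[r$report$stratum_level == "OVERALL" &
                           r$report$kpi_id == "KPI4B", "numerator"]
  open <- queue$episode_id[queue$auto_rule_result == "FALSE"]
  adj_path <- tempfile(fileext = ".csv")
  write.csv(data.frame(episode_id = open[1], decision = "CONTAMINATED",
                       reviewer = "rv", note = ""),
            adj_path, row.names = FALSE)
  r2 <- suppressMessages(run_compute(sim$cohort, adjudications = adj_path))
  k4b_after <- r2$report[r2$report$stratum_level == "OVERALL" &
                           r2$report$kpi_id == "KPI4B", "numerator"]
  expect_equal(k4b_after, k4b_before + 1)

  # malformed adjudication rows are dropped, valid ones applied
  write.csv(data.frame(episode_id = c(open[2], ""),
                       decision = c("NOT_CONTAMINATED", "MAYBE")),
            adj_path, row.names = FALSE)
  adj <- suppressMessages(read_adjudications(adj_path))
  expect_equal(nrow(adj), 1)
  expect_equal(nrow(attr(adj, "rejected")), 1)
  unlink(c(out, adj_path), recursive = TRUE)
})

test_that("YAML run configs load and reject unknown keys", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "window_hours: 12",
    "grouping: patient_service",
    "thresholds:",
    "  min_episodes: 100",
    "  min_cvc_episodes: 10",
    "panel:",
    "  cons_excluded: ['Staphylococcus lugdunensis']"), path)
  cfg <- load_run_config(path)
  expect_equal(cfg$window_hours, 12)
  expect_s3_class(cfg$thresholds, "bc_thresholds")
  expect_equal(cfg$thresholds$min_episodes, 100)
  expect_s3_class(cfg$panel, "bc_panel")

  writeLines("windw_hours: 12", path)
  expect_error(load_run_config(path), "unknown config key")
  unlink(path)
})

test_that("empty input after the adult filter yields a report of undefined cells", {
  df <- bottle_df(patient = c("P1", "P2"), age = c(10L, 15L))
  path <- tempfile(fileext = ".csv")
  write_cohort(bc_cohort(df), path)
  r <- suppressMessages(run_compute(path))
  expect_equal(nrow(r$episodes$episodes), 0)
  expect_true(all(is.na(r$report$value)))
  unlink(path)
})
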