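test_that("bottle-level volume is the weighted mean, not a mean of means", {
  df <- bottle_df(patient = c("P1", "P1", "P2"),
                  area = c("MEDICAL", "MEDICAL", "ICU"),
                  sample = c("S1", "S1", "S2"),
                  type = c("AEROBIC", "ANAEROBIC", "AEROBIC"),
                  volume = c(8, 8, 5))
  ep <- build_episodes(bc_cohort(df))
  cells <- kpi1_volume(ep, level = c("OVERALL", "AREA"))
  ov <- cells[cells$stratum_level == "OVERALL" &
                cells$kpi_id == "KPI1_BOTTLE", ]
  expect_equal(ov$value, 7)          # (8+8+5)/3, not (8+5)/2 = 6.5 or 6.75
  expect_equal(ov$numerator, 21)
  expect_equal(ov$denominator, 3)
})

test_that("missing volumes are excluded, counted, never imputed as zero", {
  df <- bottle_df(sample = c("S1", "S1"), type = c("AEROBIC", "ANAEROBIC"),
                  volume = c(10, NA))
  ep <- build_episodes(bc_cohort(df))
  cell <- kpi1_volume(ep)
  bot <- cell[cell$kpi_id == "KPI1_BOTTLE", ]
  expect_equal(bot$value, 10)
  expect_equal(bot$denominator, 1)
  expect_equal(bot$n_missing, 1)

  # a stratum with no volume-bearing bottles is undefined
  df2 <- bottle_df(volume = NA_real_)
  cell2 <- kpi1_volume(build_episodes(bc_cohort(df2)))
  expect_true(all(is.na(cell2$value)))
  expect_false(any(cell2$displayable))
})

test_that("episode-level volume averages summed known volumes over usable episodes", {
  df <- rbind(
    bottle_df(patient = "P1", sample = c("S1", "S1"),
              type = c("AEROBIC", "ANAEROBIC"), volume = c(10, 8)),
    bottle_df(patient = "P2", sample = "S2", bottle = "b9",
              volume = NA_real_))
  ep <- build_episodes(bc_cohort(df))
  cell <- kpi1_volume(ep)
  epi <- cell[cell$kpi_id == "KPI1_EPISODE", ]
  expect_equal(epi$value, 18)        # one usable episode with 10+8
  expect_equal(epi$denominator, 1)
  expect_equal(epi$n_missing, 1)     # one episode with no usable volume
})

test_that("solitary and unpaired-CVC rates use the documented denominators", {
  df <- rbind(
    bottle_df(patient = "P1", sample = "S1"),                    # solitary PV
    bottle_df(patient = "P2", sample = c("S2", "S3"), hours = c(0, 1),
              bottle = c("c1", "c2")),                           # 2-set PV
    bottle_df(patient = "P3", sample = c("S4", "S4"), origin = "CVC",
              type = c("AEROBIC", "ANAEROBIC"), bottle = c("d1", "d2")))
  ep <- build_episodes(bc_cohort(df))
  k2 <- kpi2_solitary(ep)
  expect_equal(k2$numerator, 2)      # solitary PV + solitary CVC
  expect_equal(k2$denominator, 3)    # all episodes, PV and CVC alike
  expect_equal(k2$value, 200 / 3)
  k3 <- kpi3_unpaired_cvc(ep)
  expect_equal(k3$numerator, 1)
  expect_equal(k3$denominator, 1)    # CVC episodes only
  expect_equal(k3$value, 100)
})

test_that("KPI 4 modes share one denominator and 4b dominates 4a", {
  sim <- generate_cohort(simulation_config(
    seed = 5, n_patients = 300, p_contaminated = 0.2,
    p_contaminant_multibottle = 0.5))
  ep <- build_episodes(sim$cohort)
  a <- assess_episodes(ep)
  lv <- c("OVERALL", "CENTER", "AREA")
  k4a <- kpi4_contamination(ep, a, "restrictive", lv)
  k4b <- kpi4_contamination(ep, a, "after_review", lv)
  key <- paste(k4a$stratum_level, k4a$stratum_label)
  expect_equal(key, paste(k4b$stratum_level, k4b$stratum_label))
  expect_equal(k4a$denominator, k4b$denominator)
  expect_true(all(k4b$numerator >= k4a$numerator))
  ok <- k4a$denominator > 0
  expect_true(all(k4b$value[ok] >= k4a$value[ok]))
  # denominator is the non-solitary PV episode count
  e <- ep$episodes
  expect_equal(k4a$denominator[k4a$stratum_level == "OVERALL"],
               sum(e$episode_type == "PV" & !e$is_solitary))
})

test_that("KPI numerators and denominators add across strata", {
  sim <- generate_cohort(simulation_config(seed = 8, n_patients = 400,
                                           centers = c(C1 = 2, C2 = 1),
                                           p_volume_missing = 0.05))
  ep <- build_episodes(sim$cohort)
  a <- assess_episodes(ep)
  rep <- kpi_report(ep, a, levels = c("OVERALL", "CENTER", "AREA"))
  additive <- setdiff(unique(rep$kpi_id), "EPISODES_PER_PATIENT")
  for (lv in c("CENTER", "AREA")) {
    for (k in additive) {
      part <- rep[rep$stratum_level == lv & rep$kpi_id == k, ]
      whole <- rep[rep$stratum_level == "OVERALL" & rep$kpi_id == k, ]
      expect_equal(sum(part$numerator), whole$numerator,
                   info = paste(lv, k))
      expect_equal(sum(part$denominator), whole$denominator,
                   info = paste(lv, k))
    }
  }
  # all rates within [0, 100]
  rates <- rep[rep$kpi_id %in% c("KPI2", "KPI3", "KPI4A", "KPI4B",
                                 "POSITIVITY"), ]
  expect_true(all(is.na(rates$value) |
                    (rates$value >= 0 & rates$value <= 100)))
})

test_that("service-level display thresholds are strict at 500 and 75", {
  mk_service <- function(svc, n_episodes, n_cvc) {
    n <- n_episodes
    origin <- c(rep("CVC", n_cvc), rep("PV", n - n_cvc))
    bottle_df(patient = sprintf("%s_P%04d", svc, seq_len(n)),
              service = svc,
              sample = sprintf("%s_S%04d", svc, seq_len(n)),
              bottle = sprintf("%s_b%04d", svc, seq_len(n)),
              origin = origin)
  }
  df <- rbind(mk_service("SV500", 500, 75), mk_service("SV501", 501, 76))
  ep <- build_episodes(bc_cohort(df))
  rep <- kpi_report(ep, levels = c("OVERALL", "SERVICE"))
  cell <- function(svc, kpi) {
    rep[rep$stratum_level == "SERVICE" & rep$stratum_label ==
          paste0("C1/", svc) & rep$kpi_id == kpi, ]
  }
  expect_false(cell("SV500", "KPI2")$displayable)    # 500 is not > 500
  expect_true(cell("SV501", "KPI2")$displayable)
  expect_false(cell("SV500", "KPI1_BOTTLE")$displayable)
  expect_true(cell("SV501", "KPI1_BOTTLE")$displayable)
  expect_false(cell("SV500", "KPI3")$displayable)    # 75 is not > 75
  expect_true(cell("SV501", "KPI3")$displayable)
})

test_that("auxiliary indicators: bottles/episode, episodes/patient, sets per
           1,000 patient-days", {
  df <- rbind(
    bottle_df(patient = "P1", sample = c("S1", "S1"),
              type = c("AEROBIC", "ANAEROBIC")),
    bottle_df(patient = "P1", sample = "S2", bottle = "b9", hours = 30),
    bottle_df(patient = "P2", sample = "S3", bottle = "b8"))
  ep <- build_episodes(bc_cohort(df))
  aux <- auxiliary_indicators(ep, patient_days = c(ALL = 1000))
  g <- function(k) aux[aux$kpi_id == k, ]
  expect_equal(g("BOTTLES_PER_EPISODE")$value, 4 / 3)
  expect_equal(g("EPISODES_PER_PATIENT")$value, 3 / 2)
  expect_equal(g("SETS_PER_1000PD")$value, 3)        # 3 sets / 1000 pd
  # without patient-days the cell is absent
  aux2 <- auxiliary_indicators(ep)
  expect_false("SETS_PER_1000PD" %in% aux2$kpi_id)
})

test_that("positivity can exclude confirmed contaminations", {
  df <- rbind(
    bottle_df(patient = "P1", sample = c("S1", "S1", "S2", "S2"),
              type = rep(c("AEROBIC", "ANAEROBIC"), 2),
              hours = c(0, 0, 1, 1),
              status = c("POSITIVE", rep("NEGATIVE", 3)),
              organisms = c("Staphylococcus epidermidis", "", "", "")),
    bottle_df(patient = "P2", sample = "S3", bottle = "b9",
              status = "POSITIVE", organisms = "Escherichia coli"))
  ep <- build_episodes(bc_cohort(df))
  a <- assess_episodes(ep)
  all_pos <- auxiliary_indicators(ep)
  excl <- auxiliary_indicators(ep, assessments = a,
                               exclude_contaminated = TRUE)
  expect_equal(all_pos[all_pos$kpi_id == "POSITIVITY", "numerator"], 2)
  expect_equal(excl[excl$kpi_id == "POSITIVITY", "numerator"], 1)
})
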