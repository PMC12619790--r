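test_that("the default panel matches and excludes the documented organisms", {
  panel <- contaminant_panel()
  yes <- c("Staphylococcus epidermidis", "staphylococcus  hominis",
           "Micrococcus luteus", "Cutibacterium acnes",
           "Corynebacterium amycolatum", "Bacillus cereus", "Bacillus sp.",
           "Lactobacillus rhamnosus", "Aerococcus viridans",
           "coagulase-negative staphylococci")
  no <- c("Staphylococcus lugdunensis", "Staphylococcus aureus",
          "Corynebacterium jeikeium", "Corynebacterium striatum",
          "Escherichia coli", "Cutibacterium avidum", "Candida albicans")
  expect_true(all(is_contaminant(yes, panel)))
  expect_false(any(is_contaminant(no, panel)))
})

test_that("assessment implements the restrictive criteria and candidate queue", {
  # non-solitary PV, S. epidermidis in 1 of 4 bottles -> restrictive
  df <- bottle_df(sample = c("S1", "S1", "S2", "S2"),
                  type = rep(c("AEROBIC", "ANAEROBIC"), 2),
                  hours = c(0, 0, 0.5, 0.5),
                  status = c("POSITIVE", rep("NEGATIVE", 3)),
                  organisms = c("Staphylococcus epidermidis", "", "", ""))
  a <- assess_episodes(build_episodes(bc_cohort(df)))
  expect_equal(a$category, "RESTRICTIVE_CONTAMINATION")

  # same organism in 3 bottles -> review candidate (auto rule cannot fire)
  df2 <- bottle_df(sample = c("S1", "S1", "S2", "S2"),
                   type = rep(c("AEROBIC", "ANAEROBIC"), 2),
                   hours = c(0, 0, 0.5, 0.5),
                   status = c(rep("POSITIVE", 3), "NEGATIVE"),
                   organisms = c(rep("Staphylococcus hominis", 3), ""))
  a2 <- assess_episodes(build_episodes(bc_cohort(df2)))
  expect_equal(a2$category, "REVIEW_CANDIDATE")
  expect_false(a2$auto_review)

  # only a true pathogen -> no panel organism
  df3 <- bottle_df(sample = c("S1", "S1", "S2", "S2"),
                   type = rep(c("AEROBIC", "ANAEROBIC"), 2),
                   hours = c(0, 0, 0.5, 0.5),
                   status = c("POSITIVE", rep("NEGATIVE", 3)),
                   organisms = c("Escherichia coli", "", "", ""))
  a3 <- assess_episodes(build_episodes(bc_cohort(df3)))
  expect_equal(a3$category, "NO_PANEL_ORGANISM")
})

test_that("solitary and CVC episodes are NOT_ELIGIBLE, not NO_PANEL_ORGANISM", {
  solitary <- bottle_df(sample = "S1", status = "POSITIVE",
                        organisms = "Staphylococcus epidermidis")
  a1 <- assess_episodes(build_episodes(bc_cohort(solitary)))
  expect_equal(a1$category, "NOT_ELIGIBLE")

  cvc <- bottle_df(sample = c("S1", "S2"), origin = c("CVC", "PV"),
                   hours = c(0, 0.2), status = c("POSITIVE", "NEGATIVE"),
                   organisms = c("Staphylococcus epidermidis", ""))
  a2 <- assess_episodes(build_episodes(bc_cohort(cvc)))
  expect_equal(a2$category, "NOT_ELIGIBLE")
})

test_that("two panel organisms in one bottle each stay restrictive; a mixed
           pathogen bottle does not change the category", {
  df <- bottle_df(sample = c("S1", "S1", "S2", "S2"),
                  type = rep(c("AEROBIC", "ANAEROBIC"), 2),
                  hours = c(0, 0, 0.5, 0.5),
                  status = c("POSITIVE", "POSITIVE", "POSITIVE", "NEGATIVE"),
                  organisms = c("Staphylococcus epidermidis",
                                "Micrococcus luteus",
                                "Escherichia coli", ""))
  a <- assess_episodes(build_episodes(bc_cohort(df)))
  expect_equal(a$category, "RESTRICTIVE_CONTAMINATION")
  expect_equal(a$panel_organisms,
               "micrococcus luteus;staphylococcus epidermidis")
})

test_that("the automatic review rule fires only for a same-set pair and
           nothing else", {
  mk <- function(hit_bottles) {
    df <- bottle_df(sample = rep(c("S1", "S2", "S3"), each = 2),
                    type = rep(c("AEROBIC", "ANAEROBIC"), 3),
                    hours = rep(c(0, 0.4, 0.8), each = 2))
    df$status <- ifelse(seq_len(6) %in% hit_bottles, "POSITIVE", "NEGATIVE")
    df$organisms <- ifelse(seq_len(6) %in% hit_bottles,
                           "Staphylococcus epidermidis", "")
    build_episodes(bc_cohort(df))
  }
  # both bottles of one set, nowhere else -> fires
  a <- assess_episodes(mk(c(1, 2)))
  expect_equal(a$category, "CONFIRMED_AFTER_REVIEW")
  expect_true(a$auto_review)
  # two bottles of different sets -> does not fire
  b <- assess_episodes(mk(c(1, 3)))
  expect_equal(b$category, "REVIEW_CANDIDATE")
  expect_false(b$auto_review)
  # three bottles including one full set -> does not fire
  c3 <- assess_episodes(mk(c(1, 2, 3)))
  expect_equal(c3$category, "REVIEW_CANDIDATE")
  expect_false(c3$auto_review)
})

test_that("under a single-sampling strategy the review rule is not evaluable", {
  df <- bottle_df(sample = rep(c("S1", "S2"), each = 2),
                  type = rep(c("AEROBIC", "ANAEROBIC"), 2),
                  hours = rep(c(0, 0.4), each = 2),
                  status = c("POSITIVE", "POSITIVE", "NEGATIVE", "NEGATIVE"),
                  organisms = c(rep("Staphylococcus epidermidis", 2), "", ""))
  ep <- build_episodes(bc_cohort(df))
  a <- assess_episodes(ep, set_structure = "sss")
  expect_equal(a$category, "REVIEW_CANDIDATE")
  expect_true(is.na(a$auto_review))
  expect_true(all(is.na(auto_review_rule(ep, a, set_structure = "sss"))))
})

test_that("assessment agrees with exhaustive enumeration when both organisms
           are panel members (small layouts)", {
  enum <- enumerate_contamination_cases(
    n_values = 2:4, org_b = "Micrococcus luteus", b_is_panel = TRUE,
    case_prefix = "PP")
  co <- bc_cohort(enum$records)
  ep <- build_episodes(co)
  a <- assess_episodes(ep)
  pat <- ep$episodes$patient_id[match(a$episode_id, ep$episodes$episode_id)]
  got <- setNames(a$category, pat)
  expect_equal(unname(got), unname(enum$expected[names(got)]))
})

test_that("assessment is invariant to bottle row order", {
  df <- bottle_df(sample = rep(c("S1", "S2", "S3"), each = 2),
                  type = rep(c("AEROBIC", "ANAEROBIC"), 3),
                  hours = rep(c(0, 0.4, 0.8), each = 2),
                  status = c("POSITIVE", "POSITIVE", "POSITIVE", "NEGATIVE",
                             "NEGATIVE", "NEGATIVE"),
                  organisms = c("Staphylococcus epidermidis",
                                "Staphylococcus epidermidis",
                                "Escherichia coli", "", "", ""))
  base <- assess_episodes(build_episodes(bc_cohort(df)))
  set.seed(42)
  for (i in 1:5) {
    shuf <- assess_episodes(build_episodes(bc_cohort(df[sample.int(6), ])))
    expect_equal(shuf$category, base$category)
    expect_equal(shuf$panel_organisms, base$panel_organisms)
  }
})

test_that("adjudications override the automatic rule and reject bad targets", {
  df <- bottle_df(sample = rep(c("S1", "S2"), each = 2),
                  type = rep(c("AEROBIC", "ANAEROBIC"), 2),
                  hours = rep(c(0, 0.4), each = 2),
                  status = c("POSITIVE", "POSITIVE", "NEGATIVE", "NEGATIVE"),
                  organisms = c(rep("Staphylococcus capitis", 2), "", ""))
  ep <- build_episodes(bc_cohort(df))
  a <- assess_episodes(ep)       # auto rule fires -> CONFIRMED_AFTER_REVIEW
  expect_equal(a$category, "CONFIRMED_AFTER_REVIEW")

  # human dismissal wins over the automatic confirmation
  dismissed <- suppressMessages(apply_adjudications(a, data.frame(
    episode_id = a$episode_id, decision = "NOT_CONTAMINATED",
    reviewer = "rev1")))
  expect_equal(dismissed$category, "REVIEWED_NOT_CONTAMINATED")

  # re-confirmation flips it back
  confirmed <- suppressMessages(apply_adjudications(dismissed, data.frame(
    episode_id = a$episode_id, decision = "CONTAMINATED")))
  expect_equal(confirmed$category, "CONFIRMED_AFTER_REVIEW")

  # unknown episodes and non-candidates are rejected with a diagnostic
  out <- suppressMessages(apply_adjudications(a, data.frame(
    episode_id = "nope", decision = "CONTAMINATED")))
  expect_equal(nrow(attr(out, "rejected_adjudications")), 1)
  expect_equal(out$category, a$category)
})

test_that("the contaminant ranking uses largest-remainder shares summing to 100", {
  # 9 CoNS + 1 Micrococcus -> 90 / 10
  mk_one <- function(i, org) {
    bottle_df(patient = sprintf("Q%02d", i),
              sample = sprintf("Q%02d_S%d", i, c(1, 1, 2, 2)),
              bottle = sprintf("Q%02d_b%d", i, 1:4),
              type = rep(c("AEROBIC", "ANAEROBIC"), 2),
              hours = rep(c(0, 0.4), each = 2),
              status = c("POSITIVE", rep("NEGATIVE", 3)),
              organisms = c(org, "", "", ""))
  }
  df <- do.call(rbind, c(
    lapply(1:9, mk_one, org = "Staphylococcus epidermidis"),
    list(mk_one(10, "Micrococcus luteus"))))
  a <- assess_episodes(build_episodes(bc_cohort(df)))
  r <- contaminant_species_ranking(a)
  expect_equal(r$group, c("CoNS", "Micrococcus spp."))
  expect_equal(r$share_pct, c(90, 10))
  expect_equal(sum(r$share_pct), 100)

  # a single contamination is a single 100% entry
  r1 <- contaminant_species_ranking(
    assess_episodes(build_episodes(bc_cohort(mk_one(1, "Bacillus cereus")))))
  expect_equal(r1$share_pct, 100)

  # thirds cannot round naively to 100; largest remainder forces it
  expect_equal(sum(largest_remainder_round(rep(100 / 3, 3))), 100)
  expect_equal(sort(largest_remainder_round(rep(100 / 3, 3))), c(33, 33, 34))
})
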