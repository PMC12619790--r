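# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package internals.

# Anchored-window partition: within each (center, patient, area) group,
# repeatedly take the earliest unassigned bottle as anchor and collect every
# unassigned bottle at most `window_hours` later (closed bound). Returns a
# canonical partition: sorted list of sorted bottle_id vectors.
oracle_partition <- function(records, window_hours = 24) {
  out <- list()
  keys <- unique(paste(records$center, records$patient_id, records$area,
                       sep = "|"))
  for (key in keys) {
    rows <- records[paste(records$center, records$patient_id, records$area,
                          sep = "|") == key, , drop = FALSE]
    assigned <- rep(FALSE, nrow(rows))
    while (any(!assigned)) {
      open <- which(!assigned)
      tmin <- min(rows$collected_at[open])
      cand <- open[rows$collected_at[open] == tmin]
      anchor <- cand[order(rows$bottle_id[cand])][1]
      members <- open[as.numeric(rows$collected_at[open]) <=
                        as.numeric(rows$collected_at[anchor]) +
                        window_hours * 3600]
      out[[length(out) + 1]] <- sort(rows$bottle_id[members])
      assigned[members] <- TRUE
    }
  }
  out[order(vapply(out, `[`, character(1), 1))]
}

package_partition <- function(episodes) {
  b <- episodes$bottles
  parts <- lapply(split(b$bottle_id, b$episode_id), sort)
  names(parts) <- NULL
  parts[order(vapply(parts, `[`, character(1), 1))]
}

# Literal contamination categorization for one episode described by the
# per-bottle organism lists (list of character vectors), the per-bottle set
# index, and the episode's eligibility. Returns the expected category.
oracle_category <- function(bottle_orgs, set_of, eligible,
                            panel_species = c("Staphylococcus epidermidis",
                                              "Micrococcus luteus")) {
  if (!eligible) return("NOT_ELIGIBLE")
  hits <- list()
  for (i in seq_along(bottle_orgs)) {
    for (org in bottle_orgs[[i]]) {
      if (org %in% panel_species) hits[[org]] <- c(hits[[org]], i)
    }
  }
  if (!length(hits)) return("NO_PANEL_ORGANISM")
  counts <- vapply(hits, length, integer(1))
  if (all(counts == 1)) return("RESTRICTIVE_CONTAMINATION")
  for (org in names(hits)) {
    b <- hits[[org]]
    if (length(b) == 2 && set_of[b[1]] == set_of[b[2]]) {
      return("CONFIRMED_AFTER_REVIEW")
    }
  }
  "REVIEW_CANDIDATE"
}

# Enumerate every episode layout with `n` bottles, a set structure given as
# sizes in {1,2}, and each bottle carrying any subset of two organisms.
# Returns a data frame of cases (one row per bottle) plus the per-case
# oracle category.
enumerate_contamination_cases <- function(n_values = 2:6,
                                          org_a = "Staphylococcus epidermidis",
                                          org_b = "Escherichia coli",
                                          b_is_panel = FALSE,
                                          case_prefix = "CASE") {
  set_structures <- function(n) {
    if (n == 0) return(list(integer()))
    out <- list()
    for (tail in set_structures(n - 1)) out[[length(out) + 1]] <- c(1L, tail)
    if (n >= 2) {
      for (tail in set_structures(n - 2)) out[[length(out) + 1]] <- c(2L, tail)
    }
    out
  }
  ## literal categorization from presence vectors (same rule as
  ## oracle_category, specialized to two organisms for speed)
  literal_category <- function(has_a, has_b, set_of, eligible, b_is_panel) {
    if (!eligible) return("NOT_ELIGIBLE")
    counts <- c(a = sum(has_a), b = if (b_is_panel) sum(has_b) else 0L)
    counts <- counts[counts > 0L]
    if (!length(counts)) return("NO_PANEL_ORGANISM")
    if (all(counts == 1L)) return("RESTRICTIVE_CONTAMINATION")
    same_set_pair <- function(present) {
      sum(present) == 2L && length(unique(set_of[present])) == 1L
    }
    if (("a" %in% names(counts) && counts["a"] > 1L && same_set_pair(has_a)) ||
        ("b" %in% names(counts) && counts["b"] > 1L && same_set_pair(has_b))) {
      return("CONFIRMED_AFTER_REVIEW")
    }
    "REVIEW_CANDIDATE"
  }
  n_structures <- vapply(n_values, function(n) length(set_structures(n)),
                         integer(1))
  n_cases <- sum(n_structures * 4^n_values)
  rows <- vector("list", n_cases)
  expected <- character(n_cases)
  case_ids <- character(n_cases)
  case_i <- 0
  for (n in n_values) {
    pow4 <- 4^(seq_len(n) - 1)
    for (sizes in set_structures(n)) {
      set_of <- rep(seq_along(sizes), sizes)
      types <- unlist(lapply(sizes, function(s)
        c("AEROBIC", "ANAEROBIC")[seq_len(s)]))
      times <- BASE_TIME + (set_of - 1) * 600 +
        (seq_len(n) - cumsum(c(0, sizes))[set_of] - 1) * 60
      eligible <- length(sizes) >= 2   # non-solitary PV (all PV below)
      for (pat in 0:(4^n - 1)) {
        digits <- (pat %/% pow4) %% 4
        has_a <- digits %% 2 == 1
        has_b <- digits >= 2
        case_i <- case_i + 1
        cid <- sprintf("%s%06d", case_prefix, case_i)
        case_ids[case_i] <- cid
        expected[case_i] <- literal_category(has_a, has_b, set_of, eligible,
                                             b_is_panel)
        rows[[case_i]] <- list(
          patient_id = rep(cid, n), age_years = rep(50L, n),
          center = rep("C1", n), area = rep("MEDICAL", n),
          hospital_service = rep("MED-1", n),
          sample_id = paste0(cid, "_S", set_of),
          bottle_id = paste0(cid, "_b", seq_len(n)),
          specimen_origin = rep("PV", n),
          bottle_type = types,
          collected_at = times,
          status = ifelse(has_a | has_b, "POSITIVE", "NEGATIVE"),
          organisms = ifelse(has_a & has_b, paste(org_a, org_b, sep = ";"),
                             ifelse(has_a, org_a,
                                    ifelse(has_b, org_b, ""))),
          volume_ml = rep(8, n))
      }
    }
  }
  list(records = as.data.frame(data.table::rbindlist(rows)),
       expected = setNames(expected, case_ids))
}
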