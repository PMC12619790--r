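## BC sets (one sampling procedure) and 24-hour anchored episodes.
##
## Episode rule: within a grouping key (default patient x area, within
## center), bottles are sorted by collection time (ties by bottle_id); the
## earliest unassigned bottle anchors an episode at hour 0 and every bottle
## with collected_at <= anchor + window belongs to it; the next unassigned
## bottle anchors the next episode. Fixed anchored windows: no sliding, no
## chaining. The window is closed at both ends ("within 24 h" read
## inclusively), so a bottle at exactly anchor + 24 h joins the episode.

#' Group bottles into BC sets
#'
#' A BC set is the pair of bottles (aerobic and anaerobic), or a single
#' bottle, obtained from the same sampling procedure, identified by the
#' progressive `sample_id`. Sets are keyed by
#' `(patient_id, sample_id, specimen_origin)` so a set never mixes
#' specimen origins. In `"strict"` mode a key holding more than one bottle
#' of the same `bottle_type` (which cannot be one venipuncture) is split
#' into singleton sets and counted in the `n_split` attribute; `"lenient"`
#' keeps the group intact.
#'
#' @param cohort a [bc_cohort()].
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return object of class `bc_sets`: list with `bottles` (records plus
#'   `set_id`), `sets` (one row per set: `set_id`, `sample_id`,
#'   `patient_id`, `specimen_origin`, `n_bottles`, `collection_time`) and
#'   `n_split`.
#' @export
build_sets <- function(cohort, mode = c("strict", "lenient")) {
  stopifnot(inherits(cohort, "bc_cohort"))
  mode <- match.arg(mode)
  b <- data.table::as.data.table(cohort$records)

  ## fatal: one sampling procedure cannot span patients
  chk <- b[, .(n_pat = data.table::uniqueN(patient_id)), by = sample_id]
  bad <- chk[chk$n_pat > 1L]
  if (nrow(bad)) {
    stop("sample_id shared across patients: ",
         paste(head(bad$sample_id, 5L), collapse = ", "))
  }

  b[, set_id := paste(patient_id, sample_id, specimen_origin, sep = "|")]
  n_split <- 0L
  if (mode == "strict") {
    dupes <- b[, .(dup = anyDuplicated(bottle_type) > 0L), by = set_id]
    split_ids <- dupes$set_id[dupes$dup]
    n_split <- length(split_ids)
    if (n_split) {
      b[set_id %in% split_ids, set_id := paste0(set_id, "|", bottle_id)]
      message(sprintf(
        "build_sets: split %d sample group(s) with repeated bottle types into singleton sets",
        n_split))
    }
  }
  sets <- if (nrow(b)) {
    b[order(collected_at, bottle_id),
      .(sample_id = sample_id[1L], patient_id = patient_id[1L],
        specimen_origin = specimen_origin[1L], n_bottles = .N,
        collection_time = min(collected_at)),
      by = set_id]
  } else {
    data.table::data.table(
      set_id = character(), sample_id = character(),
      patient_id = character(), specimen_origin = character(),
      n_bottles = integer(),
      collection_time = as.POSIXct(character(), tz = "UTC"))
  }
  structure(list(bottles = as.data.frame(b), sets = as.data.frame(sets),
                 mode = mode, n_split = n_split),
            class = "bc_sets")
}

#' @export
print.bc_sets <- function(x, ...) {
  cat("<bc_sets>\n")
  cat(sprintf("  %d set(s) over %d bottle(s) [%s mode, %d group(s) split]\n",
              nrow(x$sets), nrow(x$bottles), x$mode, x$n_split))
  invisible(x)
}

## anchored-window scan over sorted times (numeric seconds); closed bound
anchor_scan <- function(times, window_s) {
  n <- length(times)
  out <- integer(n)
  i <- 1L
  k <- 0L
  while (i <= n) {
    k <- k + 1L
    upper <- times[i] + window_s
    j <- i
    while (j < n && times[j + 1L] <= upper) j <- j + 1L
    out[i:j] <- k
    i <- j + 1L
  }
  out
}

#' Group a cohort into 24-hour anchored episodes
#'
#' Implements the episode definition (all bottles from one patient in one
#' hospital area collected within `window_hours` of the first index sample)
#' and classifies each episode: type (`"CVC"` iff at least one bottle is
#' from an intravascular device, else `"PV"`), solitary (exactly one BC
#' set, covering both the single-set and single-bottle cases), positive
#' (at least one POSITIVE bottle), unpaired CVC (CVC episode with no
#' peripheral-vein bottle). Episode center, area and hospital service are
#' attributed from the index (anchor) bottle.
#'
#' @param cohort a [bc_cohort()].
#' @param window_hours episode window length in hours (default 24).
#' @param grouping grouping key: `"patient_area"` (default; patient within
#'   center and area), `"patient_service"`, or `"patient_only"`.
#' @param set_mode passed to [build_sets()].
#' @param device_as how `OTHER_DEVICE` specimen origins enter episode
#'   typing: as CVC-like devices (`"cvc"`, default), as peripheral draws
#'   (`"pv"`), or dropped from typing (`"exclude"`).
#' @return object of class `bc_episodes`: list with `episodes` (one row
#'   per episode), `bottles` (records plus `set_id`, `episode_id`), `sets`,
#'   and the grouping parameters. `n_straddling_sets` counts sets whose
#'   bottles ended up in more than one episode (possible only when a set's
#'   bottles genuinely exceed the window or cross grouping keys).
#' @export
build_episodes <- function(cohort, window_hours = 24,
                           grouping = c("patient_area", "patient_service",
                                        "patient_only"),
                           set_mode = c("strict", "lenient"),
                           device_as = c("cvc", "pv", "exclude")) {
  stopifnot(inherits(cohort, "bc_cohort"), window_hours > 0)
  grouping <- match.arg(grouping)
  device_as <- match.arg(device_as)
  sets <- build_sets(cohort, mode = set_mode)
  b <- data.table::as.data.table(sets$bottles)
  if (!nrow(b)) {
    return(structure(list(
      episodes = empty_episode_frame(), bottles = as.data.frame(b),
      sets = sets$sets, window_hours = window_hours, grouping = grouping,
      device_as = device_as, n_straddling_sets = 0L),
      class = "bc_episodes"))
  }

  b[, group_key := switch(grouping,
    patient_area = paste(center, patient_id, area, sep = "|"),
    patient_service = paste(center, patient_id, hospital_service, sep = "|"),
    patient_only = paste(center, patient_id, sep = "|"))]

  window_s <- window_hours * 3600
  data.table::setorder(b, group_key, collected_at, bottle_id)
  b[, episode_idx := anchor_scan(as.numeric(collected_at), window_s),
    by = group_key]
  b[, anchor_time := collected_at[1L], by = .(group_key, episode_idx)]
  b[, episode_id := paste(group_key, format_timestamp(anchor_time), sep = "|")]

  is_device <- switch(device_as,
    cvc = b$specimen_origin %in% c("CVC", "OTHER_DEVICE"),
    pv = b$specimen_origin == "CVC",
    exclude = b$specimen_origin == "CVC")
  b[, device := is_device]

  eps <- b[, .(
    patient_id = patient_id[1L], center = center[1L], area = area[1L],
    hospital_service = hospital_service[1L], anchor_time = anchor_time[1L],
    n_bottles = .N, n_sets = data.table::uniqueN(set_id),
    episode_type = if (any(device)) "CVC" else "PV",
    is_positive = any(status == "POSITIVE"),
    has_pv = any(specimen_origin == "PV"),
    total_volume_ml = if (all(is.na(volume_ml))) NA_real_ else
      sum(volume_ml, na.rm = TRUE),
    n_missing_volume = sum(is.na(volume_ml))),
    by = episode_id]
  eps[, is_solitary := n_sets == 1L]
  eps[, is_unpaired_cvc := episode_type == "CVC" & !has_pv]
  eps[, has_pv := NULL]
  data.table::setorder(eps, center, patient_id, anchor_time)

  straddle <- b[, .(n_ep = data.table::uniqueN(episode_id)), by = set_id]
  n_straddle <- sum(straddle$n_ep > 1L)
  if (n_straddle) {
    message(sprintf("build_episodes: %d set(s) straddle episode boundaries",
                    n_straddle))
  }
  b[, c("group_key", "device") := NULL]

  sets_df <- data.table::as.data.table(sets$sets)
  set_ep <- b[, .(episode_id = episode_id[1L]), by = set_id]
  sets_df <- merge(sets_df, set_ep, by = "set_id", all.x = TRUE)

  structure(list(
    episodes = as.data.frame(eps), bottles = as.data.frame(b),
    sets = as.data.frame(sets_df), window_hours = window_hours,
    grouping = grouping, device_as = device_as, set_mode = sets$mode,
    n_split_sets = sets$n_split, n_straddling_sets = n_straddle),
    class = "bc_episodes")
}

empty_episode_frame <- function() {
  data.frame(
    episode_id = character(), patient_id = character(), center = character(),
    area = character(), hospital_service = character(),
    anchor_time = as.POSIXct(character(), tz = "UTC"),
    n_bottles = integer(), n_sets = integer(), episode_type = character(),
    is_positive = logical(), total_volume_ml = numeric(),
    n_missing_volume = integer(), is_solitary = logical(),
    is_unpaired_cvc = logical(), stringsAsFactors = FALSE)
}

#' @export
print.bc_episodes <- function(x, ...) {
  e <- x$episodes
  cat("<bc_episodes>\n")
  cat(sprintf("  %d episode(s) / %d set(s) / %d bottle(s) [window %g h, %s]\n",
              nrow(e), nrow(x$sets), nrow(x$bottles), x$window_hours,
              x$grouping))
  if (nrow(e)) {
    cat(sprintf("  CVC: %d (%.1f%%)  solitary: %d (%.1f%%)  positive: %d (%.1f%%)\n",
                sum(e$episode_type == "CVC"),
                100 * mean(e$episode_type == "CVC"),
                sum(e$is_solitary), 100 * mean(e$is_solitary),
                sum(e$is_positive), 100 * mean(e$is_positive)))
  }
  invisible(x)
}

#' Identify unpaired CVC episodes
#'
#' An unpaired CVC episode is a CVC episode that does not include any
#' peripheral-vein bottle, so differential time to positivity cannot be
#' interpreted. PV episodes are `FALSE` by definition.
#'
#' @param episodes a `bc_episodes` object or its `episodes` data frame.
#' @return logical vector, one element per episode.
#' @export
is_unpaired_cvc <- function(episodes) {
  e <- if (inherits(episodes, "bc_episodes")) episodes$episodes else episodes
  e$is_unpaired_cvc
}

#' Export episodes to CSV or JSONL
#'
#' One row per episode with its derived flags.
#'
#' @param episodes a `bc_episodes` object.
#' @param path output file.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(episodes, path, format = c("csv", "jsonl")) {
  stopifnot(inherits(episodes, "bc_episodes"))
  format <- match.arg(format)
  e <- episodes$episodes
  e$anchor_time <- format_timestamp(e$anchor_time)
  if (format == "csv") {
    write.csv(e, path, row.names = FALSE, quote = TRUE, na = "")
  } else {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(e))) {
      rec <- lapply(as.list(e[i, , drop = FALSE]),
                    function(x) if (is.na(x)) NULL else x)
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
    }
  }
  invisible(path)
}
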