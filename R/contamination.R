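## Contaminant-organism panel and contamination categorization.
##
## Eligibility: only non-solitary PV episodes can be contaminated under the
## restrictive criteria; CVC and solitary episodes are marked NOT_ELIGIBLE
## (not NO_PANEL_ORGANISM) so every denominator stays auditable.
##
## Categories over eligible episodes:
##   NO_PANEL_ORGANISM          no panel organism among positive bottles
##   RESTRICTIVE_CONTAMINATION  >=1 panel organism, each in exactly 1 bottle
##   REVIEW_CANDIDATE           some panel organism in >1 bottle
##   CONFIRMED_AFTER_REVIEW     candidate confirmed (auto rule or reviewer)
##   REVIEWED_NOT_CONTAMINATED  candidate dismissed by a reviewer

CATEGORY_LEVELS <- c("NOT_ELIGIBLE", "NO_PANEL_ORGANISM",
                     "RESTRICTIVE_CONTAMINATION", "REVIEW_CANDIDATE",
                     "CONFIRMED_AFTER_REVIEW", "REVIEWED_NOT_CONTAMINATED")

default_cons_species <- function() {
  c("Staphylococcus epidermidis", "Staphylococcus hominis",
    "Staphylococcus haemolyticus", "Staphylococcus capitis",
    "Staphylococcus caprae", "Staphylococcus warneri",
    "Staphylococcus saprophyticus", "Staphylococcus cohnii",
    "Staphylococcus simulans", "Staphylococcus pasteuri",
    "Staphylococcus pettenkoferi",
    "coagulase-negative staphylococci")
}

#' Contaminant-organism panel
#'
#' Builds the panel of skin-flora organisms counted as possible BC
#' contaminants. The default reproduces the standard panel: coagulase-
#' negative staphylococci (CoNS, excluding *S. lugdunensis*),
#' *Micrococcus* spp., *Cutibacterium acnes* (species-level rule),
#' *Corynebacterium* spp. (excluding *C. jeikeium* and *C. striatum*),
#' *Bacillus* spp., *Lactobacillus* spp. and *Aerococcus* spp.
#'
#' CoNS membership is a species list (the group name alone does not
#' identify species); the default covers the common clinical CoNS and the
#' literal label "coagulase-negative staphylococci". All matching is
#' case-insensitive after whitespace normalization; genus-level entries
#' such as `"Bacillus sp."` match their genus rule.
#'
#' @param genus_rules named list: genus -> character vector of excluded
#'   species (full binomials).
#' @param species_rules character vector of species-level panel members.
#' @param cons_species CoNS species list.
#' @param cons_excluded CoNS species excluded from the panel.
#' @return object of class `bc_panel`.
#' @export
contaminant_panel <- function(
    genus_rules = list(
      "Micrococcus" = character(),
      "Corynebacterium" = c("Corynebacterium jeikeium",
                            "Corynebacterium striatum"),
      "Bacillus" = character(),
      "Lactobacillus" = character(),
      "Aerococcus" = character()),
    species_rules = "Cutibacterium acnes",
    cons_species = default_cons_species(),
    cons_excluded = "Staphylococcus lugdunensis") {
  stopifnot(is.list(genus_rules), !is.null(names(genus_rules)))
  structure(list(
    genus_rules = lapply(genus_rules, normalize_species),
    genera = normalize_species(names(genus_rules)),
    species_rules = normalize_species(species_rules),
    cons_species = normalize_species(cons_species),
    cons_excluded = normalize_species(cons_excluded)),
    class = "bc_panel")
}

#' @export
print.bc_panel <- function(x, ...) {
  cat("<bc_panel>\n")
  cat("  genus rules:   ", paste(x$genera, collapse = ", "), "\n")
  cat("  species rules: ", paste(x$species_rules, collapse = ", "), "\n")
  cat(sprintf("  CoNS species:   %d (excluding %s)\n",
              length(x$cons_species), paste(x$cons_excluded, collapse = ", ")))
  invisible(x)
}

#' Test species names against the contaminant panel
#'
#' @param species_name character vector of species names (vectorized).
#' @param panel a [contaminant_panel()].
#' @return logical vector: `TRUE` where the name matches a genus rule and
#'   is not among that rule's exclusions, or is a CoNS species not
#'   excluded, or matches a species-level rule. Unknown names are `FALSE`.
#' @export
is_contaminant <- function(species_name, panel = contaminant_panel()) {
  stopifnot(inherits(panel, "bc_panel"))
  nm <- normalize_species(species_name)
  genus <- sub("^([^ ]+).*$", "\\1", nm)
  out <- logical(length(nm))
  ## CoNS species rule
  out <- out | (nm %in% panel$cons_species & !nm %in% panel$cons_excluded)
  ## species-level rules
  out <- out | nm %in% panel$species_rules
  ## genus rules with exclusions
  gi <- match(genus, panel$genera)
  has_genus <- !is.na(gi)
  if (any(has_genus)) {
    excluded <- mapply(function(name, idx) name %in% panel$genus_rules[[idx]],
                       nm[has_genus], gi[has_genus])
    out[has_genus] <- out[has_genus] | !excluded
  }
  out[!nzchar(nm)] <- FALSE
  out
}

## long table of (episode_id, set_id, bottle_id, organism) over positive
## bottles with at least one identification
positive_organism_table <- function(episodes) {
  b <- data.table::as.data.table(episodes$bottles)
  b <- b[status == "POSITIVE"]
  orgs <- split_organisms(b$organisms)
  n <- lengths(orgs)
  data.table::data.table(
    episode_id = rep(b$episode_id, n),
    set_id = rep(b$set_id, n),
    bottle_id = rep(b$bottle_id, n),
    organism = normalize_species(unlist(orgs, use.names = FALSE)))
}

#' Categorize episodes for contamination
#'
#' Builds, per episode, the map of panel organisms to the positive bottles
#' where they were found, and assigns the contamination category:
#' `RESTRICTIVE_CONTAMINATION` when at least one panel organism is present
#' and every panel organism occurs in exactly one bottle (the restrictive
#' contamination criteria); `REVIEW_CANDIDATE` when any panel organism
#' occurs in more than one bottle; `NO_PANEL_ORGANISM` otherwise. Episodes
#' that are not non-solitary PV episodes are `NOT_ELIGIBLE`.
#'
#' With `auto_review = TRUE` (default) the automatic review criterion is
#' applied to candidates, see [auto_review_rule()].
#'
#' @param episodes a [build_episodes()] result.
#' @param panel a [contaminant_panel()].
#' @param auto_review apply the automatic review rule to candidates.
#' @param set_structure `"mss"` (multi-sampling: set identity is
#'   meaningful, default) or `"sss"` (single-sampling: the review rule is
#'   not evaluable and `auto_review` is `NA` for every candidate).
#' @return data frame of class `bc_assessments`: one row per episode with
#'   `episode_id`, `eligible`, `category`, `panel_organisms`
#'   (semicolon-separated), `n_panel_bottles`, `auto_review`
#'   (`TRUE`/`FALSE`/`NA`), `rationale`.
#' @export
assess_episodes <- function(episodes, panel = contaminant_panel(),
                            auto_review = TRUE,
                            set_structure = c("mss", "sss")) {
  stopifnot(inherits(episodes, "bc_episodes"))
  set_structure <- match.arg(set_structure)
  e <- data.table::as.data.table(episodes$episodes)
  out <- data.table::data.table(
    episode_id = e$episode_id,
    eligible = e$episode_type == "PV" & !e$is_solitary,
    category = "NO_PANEL_ORGANISM",
    panel_organisms = "",
    n_panel_bottles = 0L,
    auto_review = NA,
    rationale = "")
  out[eligible == FALSE, category := "NOT_ELIGIBLE"]
  out[eligible == FALSE, rationale := "not a non-solitary PV episode"]

  hits <- positive_organism_table(episodes)
  if (nrow(hits)) {
    uniq <- unique(hits$organism)
    panel_members <- uniq[is_contaminant(uniq, panel)]
    hits <- hits[hits$organism %in% panel_members]
  }
  if (nrow(hits)) {
    ## occurrences per (episode, organism): bottles and distinct sets
    occ <- hits[, .(n_bottles_hit = data.table::uniqueN(bottle_id),
                    n_sets_hit = data.table::uniqueN(set_id)),
                by = .(episode_id, organism)]
    per_ep <- occ[, .(
      panel_organisms = paste(sort(organism), collapse = ";"),
      n_panel_bottles = sum(n_bottles_hit),
      any_multi = any(n_bottles_hit > 1L),
      auto_fire = any(n_bottles_hit == 2L & n_sets_hit == 1L)),
      by = episode_id]
    out[per_ep, on = "episode_id", `:=`(
      panel_organisms = i.panel_organisms,
      n_panel_bottles = i.n_panel_bottles)]
    elig <- out$eligible & out$episode_id %in% per_ep$episode_id
    multi <- per_ep$episode_id[per_ep$any_multi]
    out[elig & !episode_id %in% multi,
        `:=`(category = "RESTRICTIVE_CONTAMINATION",
             rationale = "panel organism(s), each in exactly one bottle")]
    out[elig & episode_id %in% multi,
        `:=`(category = "REVIEW_CANDIDATE",
             rationale = "panel organism in more than one bottle")]
    if (set_structure == "mss") {
      fire <- per_ep$episode_id[per_ep$auto_fire]
      out[category == "REVIEW_CANDIDATE",
          auto_review := episode_id %in% fire]
      if (auto_review) {
        out[category == "REVIEW_CANDIDATE" & auto_review == TRUE,
            `:=`(category = "CONFIRMED_AFTER_REVIEW",
                 rationale = "same contaminant in both bottles of one set and nowhere else")]
      }
    }
  }
  out <- as.data.frame(out)
  attr(out, "panel") <- panel
  attr(out, "set_structure") <- set_structure
  class(out) <- c("bc_assessments", "data.frame")
  out
}

#' Automatic manual-review criterion
#'
#' A review candidate is automatically confirmed as contaminated when some
#' panel organism is positive in exactly two bottles of the episode, both
#' belonging to the same BC set, and in no other bottle collected during
#' the episode. The rule requires set identity, i.e. a multi-sampling
#' strategy; for single-sampling data it is not evaluable and returns `NA`.
#'
#' @param episodes a [build_episodes()] result.
#' @param assessments a [assess_episodes()] result (computed with
#'   `auto_review = FALSE` if you want the raw candidate queue).
#' @param set_structure `"mss"` or `"sss"`.
#' @return logical vector along `assessments` rows: `TRUE`/`FALSE` for
#'   review candidates (`NA` under `"sss"`), `NA` for non-candidates.
#' @export
auto_review_rule <- function(episodes, assessments,
                             set_structure = c("mss", "sss")) {
  stopifnot(inherits(episodes, "bc_episodes"),
            inherits(assessments, "bc_assessments"))
  set_structure <- match.arg(set_structure)
  is_cand <- assessments$category %in%
    c("REVIEW_CANDIDATE", "CONFIRMED_AFTER_REVIEW",
      "REVIEWED_NOT_CONTAMINATED")
  if (set_structure == "sss") {
    out <- rep(NA, nrow(assessments))
    return(out)
  }
  panel <- attr(assessments, "panel")
  if (is.null(panel)) panel <- contaminant_panel()
  hits <- positive_organism_table(episodes)
  if (nrow(hits)) {
    uniq <- unique(hits$organism)
    hits <- hits[hits$organism %in% uniq[is_contaminant(uniq, panel)]]
  }
  fire_ids <- character()
  if (nrow(hits)) {
    occ <- hits[, .(n_bottles_hit = data.table::uniqueN(bottle_id),
                    n_sets_hit = data.table::uniqueN(set_id)),
                by = .(episode_id, organism)]
    fire_ids <- unique(
      occ$episode_id[occ$n_bottles_hit == 2L & occ$n_sets_hit == 1L])
  }
  out <- rep(NA, nrow(assessments))
  out[is_cand] <- assessments$episode_id[is_cand] %in% fire_ids
  out
}

#' Apply human adjudications to the review queue
#'
#' Decisions from manual review override the automatic rule: a candidate
#' adjudicated `CONTAMINATED` becomes `CONFIRMED_AFTER_REVIEW`, one
#' adjudicated `NOT_CONTAMINATED` becomes `REVIEWED_NOT_CONTAMINATED`.
#' Adjudications that do not target a review candidate (including unknown
#' episode ids) are rejected and reported in the `rejected` attribute.
#'
#' @param assessments a [assess_episodes()] result.
#' @param adjudications data frame with columns `episode_id`, `decision`
#'   (`CONTAMINATED`/`NOT_CONTAMINATED`) and optionally `reviewer`, `note`
#'   (the review-queue import dialect, see [read_adjudications()]).
#' @return the updated `bc_assessments`; rejected adjudication rows are in
#'   `attr(, "rejected_adjudications")`.
#' @export
apply_adjudications <- function(assessments, adjudications) {
  stopifnot(inherits(assessments, "bc_assessments"))
  adj <- as.data.frame(adjudications, stringsAsFactors = FALSE)
  stopifnot(all(c("episode_id", "decision") %in% names(adj)))
  adj$decision <- toupper(trimws(adj$decision))

  candidate_ids <- assessments$episode_id[
    assessments$category %in% c("REVIEW_CANDIDATE", "CONFIRMED_AFTER_REVIEW",
                                "REVIEWED_NOT_CONTAMINATED")]
  ok_decision <- adj$decision %in% c("CONTAMINATED", "NOT_CONTAMINATED")
  ok_target <- adj$episode_id %in% candidate_ids
  rejected <- adj[!(ok_decision & ok_target), , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- ifelse(!ok_decision[!(ok_decision & ok_target)],
                              "invalid_decision", "not_a_review_candidate")
    message(sprintf("apply_adjudications: rejected %d adjudication(s)",
                    nrow(rejected)))
  }
  adj <- adj[ok_decision & ok_target, , drop = FALSE]
  if (nrow(adj)) {
    ## last decision per episode wins
    adj <- adj[!duplicated(adj$episode_id, fromLast = TRUE), , drop = FALSE]
    idx <- match(adj$episode_id, assessments$episode_id)
    overridden <- which(
      (assessments$category[idx] == "CONFIRMED_AFTER_REVIEW" &
         adj$decision == "NOT_CONTAMINATED") |
        (assessments$category[idx] == "REVIEWED_NOT_CONTAMINATED" &
           adj$decision == "CONTAMINATED"))
    if (length(overridden)) {
      message(sprintf(
        "apply_adjudications: %d human decision(s) override the automatic rule",
        length(overridden)))
    }
    assessments$category[idx] <- ifelse(adj$decision == "CONTAMINATED",
                                        "CONFIRMED_AFTER_REVIEW",
                                        "REVIEWED_NOT_CONTAMINATED")
    assessments$rationale[idx] <- paste0(
      "manual review: ", tolower(adj$decision),
      ifelse("reviewer" %in% names(adj) & nzchar(as.character(adj$reviewer)),
             paste0(" (", adj$reviewer, ")"), ""))
  }
  attr(assessments, "rejected_adjudications") <- rejected
  assessments
}

panel_group_of <- function(organism, panel = contaminant_panel()) {
  nm <- normalize_species(organism)
  genus <- sub("^([^ ]+).*$", "\\1", nm)
  out <- rep(NA_character_, length(nm))
  out[nm %in% setdiff(panel$cons_species, panel$cons_excluded)] <- "CoNS"
  out[is.na(out) & nm %in% panel$species_rules & genus == "cutibacterium"] <-
    "Cutibacterium acnes"
  out[is.na(out) & genus == "corynebacterium"] <- "Corynebacterium spp."
  out[is.na(out) & genus == "micrococcus"] <- "Micrococcus spp."
  out[is.na(out) & genus %in% c("bacillus", "lactobacillus", "aerococcus")] <-
    "Others"
  out
}

#' Rank contaminant groups among confirmed contaminations
#'
#' Groups confirmed contaminations (restrictive plus after review) by
#' panel group (CoNS, *Corynebacterium* spp., *Micrococcus* spp.,
#' *Cutibacterium acnes*, others) and returns percentage shares in
#' decreasing order. Shares are rounded with the largest-remainder method
#' so they sum to exactly 100 at the requested precision.
#'
#' @param assessments a [assess_episodes()] result (adjudications applied).
#' @param panel the panel used for grouping.
#' @param digits decimal places of the rounded shares (default 0).
#' @return data frame `group`, `n`, `share_pct` (descending); zero rows
#'   when there are no confirmed contaminations.
#' @export
contaminant_species_ranking <- function(assessments,
                                        panel = contaminant_panel(),
                                        digits = 0) {
  stopifnot(inherits(assessments, "bc_assessments"))
  conf <- assessments[assessments$category %in%
                        c("RESTRICTIVE_CONTAMINATION",
                          "CONFIRMED_AFTER_REVIEW"), , drop = FALSE]
  if (!nrow(conf)) {
    return(data.frame(group = character(), n = integer(),
                      share_pct = numeric(), stringsAsFactors = FALSE))
  }
  orgs <- split_organisms(conf$panel_organisms)
  long <- data.frame(
    episode_id = rep(conf$episode_id, lengths(orgs)),
    group = panel_group_of(unlist(orgs, use.names = FALSE), panel),
    stringsAsFactors = FALSE)
  long <- long[!is.na(long$group), , drop = FALSE]
  long <- unique(long)  # one count per (episode, group)
  tab <- sort(table(long$group), decreasing = TRUE)
  shares <- largest_remainder_round(100 * as.numeric(tab) / sum(tab),
                                    digits = digits, total = 100)
  data.frame(group = names(tab), n = as.integer(tab), share_pct = shares,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Largest-remainder rounding to a fixed total
#'
#' Rounds a vector of shares to `digits` decimals so that the rounded
#' values sum exactly to `total`: floor everything at the target precision,
#' then distribute the remaining units to the largest remainders.
#'
#' @param x numeric shares summing (approximately) to `total`.
#' @param digits decimals to keep.
#' @param total required sum of the rounded vector.
#' @return rounded numeric vector summing to `total`.
#' @export
largest_remainder_round <- function(x, digits = 0, total = 100) {
  if (!length(x)) return(numeric())
  scale <- 10^digits
  scaled <- x * scale
  fl <- floor(scaled)
  rem <- round(total * scale) - sum(fl)
  if (rem > 0) {
    give <- order(scaled - fl, decreasing = TRUE)[seq_len(rem)]
    fl[give] <- fl[give] + 1
  }
  fl / scale
}

#' Export the manual-review queue
#'
#' Writes one row per review candidate with the per-bottle context needed
#' for adjudication.
#'
#' @param episodes a [build_episodes()] result.
#' @param assessments a [assess_episodes()] result.
#' @param path output CSV path.
#' @return the exported data frame, invisibly.
#' @export
export_review_queue <- function(episodes, assessments, path) {
  stopifnot(inherits(episodes, "bc_episodes"),
            inherits(assessments, "bc_assessments"))
  cand <- assessments[assessments$category %in%
                        c("REVIEW_CANDIDATE", "CONFIRMED_AFTER_REVIEW"), ,
                      drop = FALSE]
  e <- episodes$episodes
  idx <- match(cand$episode_id, e$episode_id)
  panel <- attr(assessments, "panel")
  if (is.null(panel)) panel <- contaminant_panel()
  hits <- positive_organism_table(episodes)
  if (nrow(hits)) {
    uniq <- unique(hits$organism)
    hits <- hits[hits$organism %in% uniq[is_contaminant(uniq, panel)]]
  }
  bottles_of <- vapply(cand$episode_id, function(id) {
    paste(sort(unique(hits$bottle_id[hits$episode_id == id])), collapse = ";")
  }, character(1))
  out <- data.frame(
    episode_id = cand$episode_id,
    patient_id = e$patient_id[idx],
    anchor_time = format_timestamp(e$anchor_time[idx]),
    organism = cand$panel_organisms,
    bottle_ids = bottles_of,
    auto_rule_result = cand$auto_review,
    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(out)
}

#' Read an adjudications file
#'
#' Expects the review-queue import dialect:
#' `episode_id,decision,reviewer,note`. Malformed rows (missing episode_id
#' or unknown decision) are dropped with a message and reported in the
#' `rejected` attribute; valid rows are returned.
#'
#' @param path CSV path.
#' @return data frame of valid adjudication rows.
#' @export
read_adjudications <- function(path) {
  adj <- read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("episode_id", "decision")
  if (!all(need %in% names(adj))) {
    stop("adjudications file must have columns episode_id, decision")
  }
  if (!"reviewer" %in% names(adj)) adj$reviewer <- ""
  if (!"note" %in% names(adj)) adj$note <- ""
  adj$decision <- toupper(trimws(adj$decision))
  ok <- nzchar(adj$episode_id) &
    adj$decision %in% c("CONTAMINATED", "NOT_CONTAMINATED")
  if (any(!ok)) {
    message(sprintf("read_adjudications: dropped %d malformed row(s)",
                    sum(!ok)))
  }
  out <- adj[ok, , drop = FALSE]
  attr(out, "rejected") <- adj[!ok, , drop = FALSE]
  out
}
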