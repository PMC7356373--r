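#' Default domestication-signature rule set
#'
#' The rule set is data, not code: each signature is named and users can
#' supply alternative sets. The default signatures are the horizontally
#' acquired regions A/B/C, an aquaporin inactivation of a known
#' domesticated type, the presence of RTM1, the presence of STA1, and a MEL
#' array of four or more copies. A MAL-expansion signature can be added by
#' users via the generic copy-number mechanism; it is not part of the
#' default set because no threshold is established for it.
#'
#' @return named list of rules; each rule is a predicate description with
#'   `field`, `op` and `value`
#' @export
default_lifestyle_rules <- function() {
  list(
    region_A_present = list(field = "region_a", op = "state_present"),
    region_B_present = list(field = "region_b", op = "state_present"),
    region_C_present = list(field = "region_c", op = "state_present"),
    aqy_domesticated_lesion = list(field = "aqy_type", op = "known_type"),
    rtm1_present = list(field = "rtm1", op = "state_present"),
    sta1_present = list(field = "sta1", op = "state_present"),
    mel_expansion = list(field = "mel_copy_number", op = "ge", value = 4)
  )
}

#' Write / read a lifestyle rule set
#'
#' @param rules rule set list
#' @param path YAML file path
#' @export
write_rules <- function(rules, path) {
  yaml::write_yaml(rules, path)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) yaml::read_yaml(path)

rule_fires <- function(rule, profile_row, known_aqy_types) {
  val <- profile_row[[rule$field]]
  switch(rule$op,
    state_present = !is.na(val) &&
      val %in% c("present_intact", "present_inactivated", "present_deleted"),
    known_type = !is.na(val) && val %in% known_aqy_types,
    ge = !is.na(val) && !identical(val, "unknown") &&
      suppressWarnings(as.numeric(val)) >= rule$value,
    abort(sprintf("unknown rule operation '%s'", rule$op))
  )
}

#' Join upstream results into per-strain marker profiles
#'
#' One row per strain combining marker-screen states, the aquaporin
#' inactivation type, copy numbers, MEL assignment, ploidy hints and
#' user-supplied niche metadata. Missing upstream values become "unknown"
#' with a warning; duplicated strain ids are an error.
#'
#' @param calls marker-screen calls ([screen_markers()])
#' @param aqy aquaporin type calls ([aqy_type_calls()])
#' @param copy_numbers copy-number tibble for the MEL gene
#'   ([copy_number()]; rows with `gene == "MEL"` are used)
#' @param mel MEL assignments ([mel_typing()])
#' @param ploidy ploidy hints ([flag_het_excess()])
#' @param niche tibble `strain`, `niche` (isolation-record metadata; one of
#'   "arboreal_low_sugar", "high_sugar", "fermentation", "unknown")
#' @return profile tibble, one row per strain
#' @export
profile_panel <- function(calls, aqy, copy_numbers, mel, ploidy, niche) {
  if (anyDuplicated(niche$strain)) abort("duplicate strain ids in niche")
  wide <- calls |>
    select("strain", "marker", "state") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "state") |>
    rename(region_a = "region_A", region_b = "region_B",
           region_c = "region_C", aqy1 = "AQY1", aqy2 = "AQY2",
           suc2 = "SUC2", rtm1 = "RTM1", bio1 = "BIO1", bio6 = "BIO6",
           sta1 = "STA1", mel_state = "MEL",
           sta1_promoter = "STA1_promoter")
  if (anyDuplicated(wide$strain)) abort("duplicate strain ids in calls")
  prom <- calls |>
    filter(.data$marker == "STA1_promoter") |>
    select("strain", sta1_promoter_deletion = "promoter_deletion")
  cn <- copy_numbers |>
    filter(.data$gene == "MEL") |>
    select("strain", mel_copy_number = "rounded")
  out <- wide |>
    left_join(prom, by = "strain") |>
    left_join(select(aqy, "strain", "aqy_type"), by = "strain") |>
    left_join(cn, by = "strain") |>
    left_join(select(mel, "strain", mel_group = "group",
                     mel_functional = "functional"), by = "strain") |>
    left_join(select(ploidy, "strain", "ploidy_hint"), by = "strain") |>
    left_join(niche, by = "strain")
  out <- select(out, "strain", "aqy1", "aqy2", "suc2", "rtm1", "bio1",
                "bio6", "sta1", "sta1_promoter", "sta1_promoter_deletion",
                "region_a", "region_b", "region_c", "mel_state",
                "mel_group", "mel_functional", "mel_copy_number",
                "aqy_type", "ploidy_hint", "niche")
  known_missing <- c("mel_copy_number", "ploidy_hint", "niche")
  for (col in known_missing) {
    if (!col %in% names(out)) out[[col]] <- NA
    if (anyNA(out[[col]])) {
      warn(sprintf("missing %s for %d strain(s); set to \"unknown\"",
                   col, sum(is.na(out[[col]]))))
      out[[col]] <- as.character(out[[col]])
      out[[col]][is.na(out[[col]])] <- "unknown"
    }
  }
  arrange(out, .data$strain)
}

#' Classify strains as wild, domesticated or feral
#'
#' Applies the domestication-signature rules to each profile:
#' a fermentation-niche strain with at least one signature is
#' `domesticated`; an arboreal (low-sugar) strain with at least one
#' signature is `feral` (domesticated genomic ancestry in a wild niche); a
#' strain from a natural niche (arboreal or high-sugar) with no signature
#' is `wild` — a high-sugar wild strain may carry an aquaporin inactivation
#' of a novel type without losing wild status, since such inactivations
#' also arise naturally in high-sugar niches; anything else is
#' `unclassified`. Every fired rule is recorded as evidence.
#'
#' @param profiles profile tibble from [profile_panel()]
#' @param rules rule set (default [default_lifestyle_rules()])
#' @param known_aqy_types labels counted as domesticated-type aquaporin
#'   lesions
#' @return tibble: `strain`, `call`, `n_signatures`, `evidence` (list of
#'   fired rule names)
#' @export
classify_lifestyle <- function(profiles, rules = default_lifestyle_rules(),
                               known_aqy_types = c("wine", "sake")) {
  for (r in rules) {
    if (!r$op %in% c("state_present", "known_type", "ge"))
      abort(sprintf("unknown rule operation '%s'", r$op))
  }
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    p <- profiles[i, ]
    fired <- names(rules)[vapply(rules, rule_fires, logical(1),
                                 profile_row = p,
                                 known_aqy_types = known_aqy_types)]
    k <- length(fired)
    call <- if (p$niche == "fermentation" && k >= 1) "domesticated"
      else if (p$niche == "arboreal_low_sugar" && k >= 1) "feral"
      else if (p$niche %in% c("arboreal_low_sugar", "high_sugar") && k == 0)
        "wild"
      else "unclassified"
    tibble(strain = p$strain, call = call, n_signatures = k,
           evidence = list(fired))
  })
  bind_rows(rows)
}
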