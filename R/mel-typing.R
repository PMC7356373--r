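MEL_GROUPS <- c("Asian I", "Asian II", "Asian-American", "European",
                "African I", "African II", "South American")

#' Synthetic MEL allele reference panel
#'
#' Builds labelled alpha-galactosidase reference sequences reproducing the
#' divergence structure reported for the seven allele groups: roughly 10%
#' pairwise divergence among Asian I, Asian II, Asian-American and
#' European, and roughly 20% between that block and the African I/II and
#' South American block. African II references carry a premature stop (the
#' allele is a pseudogene). Outgroup sequences stand in for MEL genes of a
#' sister species.
#'
#' @param catalog marker catalog providing the base MEL sequence
#' @param n_per_group references per group
#' @param seed integer seed
#' @return tibble: `group`, `id`, `seq`, `functional`, `outgroup`
#' @export
make_mel_panel <- function(catalog = NULL, n_per_group = 2, seed = 7) {
  if (is.null(catalog)) catalog <- default_marker_catalog()
  base <- catalog$seq[catalog$marker == "MEL"]
  withr::with_seed(seed, {
    anc <- list(
      "Asian I" = mutate_cds(base, 0.05),
      "Asian II" = mutate_cds(base, 0.05),
      "Asian-American" = mutate_cds(base, 0.05),
      "European" = mutate_cds(base, 0.05)
    )
    afr_anc <- mutate_cds(base, 0.15)
    anc[["African I"]] <- mutate_cds(afr_anc, 0.015)
    anc[["African II"]] <- mutate_cds(afr_anc, 0.015)
    anc[["South American"]] <- mutate_cds(afr_anc, 0.015)
    rows <- lapply(MEL_GROUPS, function(g) {
      seqs <- vapply(seq_len(n_per_group),
                     function(i) mutate_cds(anc[[g]], 0.005), character(1))
      functional <- rep(TRUE, n_per_group)
      if (g == "African II") {  # pseudogene allele
        seqs <- vapply(seqs, function(s)
          apply_lesion(s, "premature_stop", seed = 511L)$seq, character(1),
          USE.NAMES = FALSE)
        functional[] <- FALSE
      }
      tibble(group = g, id = sprintf("%s_ref%d", gsub(" ", "", g),
                                     seq_len(n_per_group)),
             seq = seqs, functional = functional, outgroup = FALSE)
    })
    out <- tibble(group = "outgroup",
                  id = sprintf("S_paradoxus_%d", 1:2),
                  seq = c(mutate_cds(afr_anc, 0.02), mutate_cds(afr_anc, 0.02)),
                  functional = TRUE, outgroup = TRUE)
    bind_rows(c(rows, list(out)))
  })
}

#' Project a query onto the panel's alignment frame
#'
#' Queries of the panel's common length pass through; others are globally
#' aligned to the named reference, insertions relative to it removed and
#' deletions written as N, so every downstream comparison is positional.
#' @keywords internal
align_to_frame <- function(query, frame_ref) {
  if (nchar(query) == nchar(frame_ref)) return(query)
  s <- aligned_strings(align_global(frame_ref, query))
  vp <- seq_chars(s$pattern); vs <- seq_chars(s$subject)
  keep <- vp != "-"
  v <- vs[keep]
  v[v == "-"] <- "N"
  chars_seq(v)
}

#' Assign a MEL query sequence to its nearest allele group
#'
#' The group minimizing the mean Tamura-92 distance to its references wins;
#' the margin to the second-best group is reported and assignments with a
#' margin below `ambiguous_margin` are flagged ambiguous.
#'
#' @param query MEL sequence
#' @param panel MEL reference panel (see [make_mel_panel()]); outgroup rows
#'   are ignored for assignment
#' @param ambiguous_margin margin threshold (T92 units)
#' @return one-row tibble: `group`, `distance`, `margin`, `ambiguous`
#' @export
assign_mel_group <- function(query, panel, ambiguous_margin = 0.01) {
  panel <- filter(panel, !.data$outgroup)
  query <- align_to_frame(query, panel$seq[1])
  if (nchar(query) != nchar(panel$seq[1]))
    abort("query cannot be aligned to the panel frame")
  means <- panel |>
    mutate(d = map_dbl(.data$seq, function(r) {
      d <- t92_distance(query, r)
      if (is.na(d)) p_distance(query, r) else d  # saturation fallback
    })) |>
    group_by(.data$group) |>
    summarise(d = mean(.data$d), .groups = "drop") |>
    arrange(.data$d)
  margin <- means$d[2] - means$d[1]
  tibble(group = means$group[1], distance = means$d[1], margin = margin,
         ambiguous = margin < ambiguous_margin)
}

#' Detect recombinant (chimeric) MEL alleles by sliding windows
#'
#' Computes the nearest allele group in overlapping windows; the allele is
#' called recombinant when a contiguous prefix and a contiguous suffix of
#' windows are won by two different groups, each spanning at least
#' `min_span` of all windows. The breakpoint is reported as the base range
#' between the last prefix window and the first suffix window.
#'
#' @param query MEL sequence (length >= 2 windows)
#' @param panel MEL reference panel
#' @param window window size in bp
#' @param step step size in bp
#' @param min_span minimum fraction of windows for each flank
#' @return one-row tibble: `recombinant`, `group_5p`, `group_3p`,
#'   `breakpoint_start`, `breakpoint_end` (bases; NA when not recombinant)
#' @export
detect_recombinant <- function(query, panel, window = 200, step = 50,
                               min_span = 0.25) {
  panel <- filter(panel, !.data$outgroup)
  query <- align_to_frame(query, panel$seq[1])
  L <- nchar(query)
  if (L < 2 * window) abort("query shorter than two windows")
  starts <- seq(1, L - window + 1, by = step)
  winners <- vapply(starts, function(s0) {
    q <- substr(query, s0, s0 + window - 1)
    refs <- substr(panel$seq, s0, s0 + window - 1)
    d <- vapply(refs, function(r) {
      dd <- suppressWarnings(tryCatch(t92_distance(q, r),
                                      error = function(e) NA_real_))
      if (is.na(dd)) p_distance(q, r) else dd
    }, numeric(1))
    means <- tapply(d, panel$group, mean)
    names(which.min(means))
  }, character(1))
  n <- length(winners)
  pre_len <- rle(winners)$lengths[1]
  suf_len <- tail(rle(winners)$lengths, 1)
  g5 <- winners[1]; g3 <- winners[n]
  if (g5 != g3 && pre_len >= min_span * n && suf_len >= min_span * n &&
      pre_len + suf_len == n) {
    bp_start <- starts[pre_len] + window  # end of last prefix window + 1
    bp_end <- starts[pre_len + 1]         # start of first suffix window
    tibble(recombinant = TRUE, group_5p = g5, group_3p = g3,
           breakpoint_start = min(bp_start, bp_end),
           breakpoint_end = max(bp_start, bp_end))
  } else {
    tibble(recombinant = FALSE, group_5p = NA_character_,
           group_3p = NA_character_, breakpoint_start = NA_integer_,
           breakpoint_end = NA_integer_)
  }
}

#' MEL gene tree from the reference panel plus query sequences
#'
#' Neighbor-joining on Tamura-92 distances with column-bootstrap supports.
#'
#' @param panel MEL reference panel
#' @param queries optional named character vector of query sequences
#' @param replicates bootstrap replicates
#' @param seed integer seed
#' @return list with `tree` and `support` (see [bootstrap_support()])
#' @export
mel_tree <- function(panel, queries = NULL, replicates = 1000, seed = 1) {
  seqs <- setNames(panel$seq, panel$id)
  if (!is.null(queries)) {
    queries <- vapply(queries, align_to_frame, character(1),
                      frame_ref = panel$seq[1])
    seqs <- c(seqs, queries)
  }
  if (length(seqs) < 3) abort("need at least 3 sequences")
  bootstrap_support(seqs, metric = "t92", replicates = replicates,
                    seed = seed)
}

#' Type every MEL-positive strain of a screened panel
#'
#' Takes each strain's MEL copy from the marker screen's stored alignment,
#' assigns its allele group, tests for recombination, and reports
#' functionality from the CDS-integrity lesions.
#'
#' @param calls output of [screen_markers()] (run with a `mel_panel`)
#' @param panel MEL reference panel
#' @param ... passed to [detect_recombinant()]
#' @return tibble: `strain`, `group`, `distance`, `margin`, `ambiguous`,
#'   `recombinant`, `functional`
#' @export
mel_typing <- function(calls, panel, ...) {
  mel_calls <- filter(calls, .data$marker == "MEL")
  rows <- list()
  for (i in seq_len(nrow(mel_calls))) {
    cl <- mel_calls[i, ]
    if (cl$state == "absent" || is.null(cl$alignment[[1]])) {
      rows[[i]] <- tibble(strain = cl$strain, group = NA_character_,
                          distance = NA_real_, margin = NA_real_,
                          ambiguous = NA, recombinant = NA,
                          functional = NA)
      next
    }
    aln <- cl$alignment[[1]]
    vp <- seq_chars(aln$pattern); vs <- seq_chars(aln$subject)
    v <- vs[vp != "-"]; v[v == "-"] <- "N"
    copy <- chars_seq(v)
    asg <- assign_mel_group(copy, panel)
    rec <- detect_recombinant(copy, panel, ...)
    integ <- cds_integrity(aln)
    rows[[i]] <- bind_cols(tibble(strain = cl$strain), asg,
                           tibble(recombinant = rec$recombinant,
                                  functional =
                                    integ$state == "present_intact"))
  }
  bind_rows(rows)
}
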