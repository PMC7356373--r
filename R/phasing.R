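#' Count qualifying heterozygous sites per strain
#'
#' A site qualifies when the consensus call is a two-base IUPAC code and, if
#' a quality string is present, its Phred score is at or above the
#' threshold.
#'
#' @param consensus consensus tibble (`strain`, `chrom`, `seq`, optional
#'   `qual`)
#' @param q_threshold Phred threshold (default 40)
#' @return tibble with `strain`, `n_het`
#' @export
count_het_sites <- function(consensus, q_threshold = 40) {
  has_qual <- "qual" %in% names(consensus)
  consensus |>
    mutate(k = map_int(seq_len(n()), function(i) {
      v <- seq_chars(.data$seq[i])
      het <- is_het_code(v)
      if (has_qual && !is.na(.data$qual[i]))
        het <- het & (phred_to_int(.data$qual[i]) >= q_threshold)
      sum(het)
    })) |>
    group_by(.data$strain) |>
    summarise(n_het = sum(.data$k), .groups = "drop")
}

#' Select strains for read-backed phasing
#'
#' Strains with strictly more than `min_het_sites` qualifying heterozygous
#' sites (genome-wide) are selected; exactly `min_het_sites` is not enough.
#'
#' @inheritParams count_het_sites
#' @param min_het_sites selection threshold (default 20,000)
#' @return tibble with `strain`, `n_het`, `selected`
#' @export
select_for_phasing <- function(consensus, min_het_sites = 20000,
                               q_threshold = 40) {
  count_het_sites(consensus, q_threshold) |>
    mutate(selected = .data$n_het > min_het_sites)
}

#' Flag strains with an excess of heterozygous sites
#'
#' Strains whose qualifying het-site count exceeds `factor` times the panel
#' median are flagged as possibly of ploidy above 2n.
#'
#' @inheritParams count_het_sites
#' @param factor multiple of the panel median (default 2)
#' @return tibble with `strain`, `n_het`, `ploidy_hint` ("2n" or ">2n")
#' @export
flag_het_excess <- function(consensus, factor = 2, q_threshold = 40) {
  count_het_sites(consensus, q_threshold) |>
    mutate(ploidy_hint = ifelse(.data$n_het > factor * median(.data$n_het),
                                ">2n", "2n"))
}

#' Simulate sequencing fragments over heterozygous sites
#'
#' Emulates the informative content of mapped read pairs: each fragment
#' reports the alleles of a run of consecutive heterozygous sites on one of
#' the two true haplotypes, with an optional per-allele error rate. Each
#' adjacent site pair is covered by `redundancy` fragments on average.
#'
#' @param truth tibble with `site` (index), `hap1`, `hap2` (alleles)
#' @param redundancy mean number of fragments linking an adjacent site pair
#' @param span sites covered per fragment (default 3)
#' @param error_rate probability an allele is misread as the other allele
#' @param seed integer seed
#' @return tibble with `fragment`, `site`, `allele`
#' @export
simulate_fragments <- function(truth, redundancy = 5, span = 3,
                               error_rate = 0, seed = 1) {
  n <- nrow(truth)
  if (n < 2) abort("need at least two het sites")
  withr::with_seed(seed, {
    n_frag <- ceiling(redundancy * (n - 1) / (span - 1))
    starts <- sample.int(max(1L, n - span + 1L), n_frag, replace = TRUE)
    rows <- lapply(seq_len(n_frag), function(f) {
      idx <- starts[f]:min(n, starts[f] + span - 1L)
      hap <- sample(c("hap1", "hap2"), 1)
      allele <- truth[[hap]][idx]
      other <- ifelse(hap == "hap1", 1, 0)
      flip <- runif(length(idx)) < error_rate
      allele[flip] <- ifelse(truth$hap1[idx] == allele,
                             truth$hap2[idx], truth$hap1[idx])[flip]
      tibble(fragment = f, site = truth$site[idx], allele = allele)
    })
    bind_rows(rows)
  })
}

#' Phase heterozygous sites from fragment co-occurrence
#'
#' Greedy read-backed phasing: sites are processed in genomic order; within
#' each connected component of the site-fragment graph, a new site joins the
#' phase supported by the majority of fragments linking it to already-phased
#' sites (ties break toward phase 0). Fragments that conflict with both
#' inferred phases at two or more sites are discarded (emulating the
#' exclusion of misaligned-read errors) and the component is re-phased once
#' without them.
#'
#' @param fragments tibble with `fragment`, `site`, `allele`
#' @param sites tibble with `site`, `allele0`, `allele1` (the two observed
#'   bases per heterozygous site); sites must be in genomic order
#' @return list with `phase` (tibble `site`, `component`, `phase`,
#'   `hap_a`, `hap_b`) and `n_dropped_fragments`
#' @export
phase_fragments <- function(fragments, sites) {
  unknown <- setdiff(fragments$site, sites$site)
  if (length(unknown))
    abort(sprintf("fragment cites unknown site %s", unknown[1]))
  bad_allele <- fragments |>
    left_join(sites, by = "site") |>
    filter(.data$allele != .data$allele0 & .data$allele != .data$allele1)
  if (nrow(bad_allele))
    abort("fragment allele not among the site's two observed bases")

  res <- phase_pass(fragments, sites)
  # conflict filter: drop fragments disagreeing with both phases at >= 2
  # sites, then re-phase
  drop_ids <- conflicting_fragments(fragments, sites, res)
  if (length(drop_ids)) {
    fragments2 <- filter(fragments, !.data$fragment %in% drop_ids)
    if (nrow(fragments2)) res <- phase_pass(fragments2, sites)
  }
  list(phase = res, n_dropped_fragments = length(drop_ids))
}

phase_pass <- function(fragments, sites) {
  n <- nrow(sites)
  idx_of <- setNames(seq_len(n), as.character(sites$site))
  frag_sites <- split(match(fragments$site, sites$site), fragments$fragment)
  frag_alle <- split(fragments$allele, fragments$fragment)
  # fragments indexed by the sites they touch
  by_site <- vector("list", n)
  for (f in seq_along(frag_sites))
    for (s in frag_sites[[f]])
      by_site[[s]] <- c(by_site[[s]], f)

  phase <- rep(NA_integer_, n)
  comp <- rep(NA_integer_, n)
  comp_id <- 0L
  for (s in seq_len(n)) {
    votes <- 0L; n_votes <- 0L
    for (f in by_site[[s]]) {
      fs <- frag_sites[[f]]; fa <- frag_alle[[f]]
      prev <- fs[!is.na(phase[fs]) & fs != s]
      if (!length(prev)) next
      # this fragment's allele at the new site
      a_new <- fa[match(s, fs)]
      new_is0 <- a_new == sites$allele0[s]
      for (p in prev) {
        a_prev <- fa[match(p, fs)]
        prev_is0 <- a_prev == sites$allele0[p]
        # same fragment = same haplotype: infer phase of s from p
        implied <- if (xor(new_is0, prev_is0)) 1L - phase[p] else phase[p]
        votes <- votes + (if (implied == 0L) 1L else -1L)
        n_votes <- n_votes + 1L
      }
    }
    if (n_votes == 0L) {
      comp_id <- comp_id + 1L
      comp[s] <- comp_id
      phase[s] <- 0L
    } else {
      # join the component of the linked sites
      linked <- unlist(lapply(by_site[[s]], function(f)
        frag_sites[[f]][!is.na(phase[frag_sites[[f]]])]))
      target <- min(comp[linked])
      comp[comp %in% comp[linked]] <- target  # merge joined components
      comp[s] <- target
      phase[s] <- if (votes >= 0L) 0L else 1L
    }
  }
  tibble(site = sites$site, component = comp, phase = phase,
         hap_a = ifelse(phase == 0L, sites$allele0, sites$allele1),
         hap_b = ifelse(phase == 0L, sites$allele1, sites$allele0))
}

conflicting_fragments <- function(fragments, sites, res) {
  joined <- fragments |>
    left_join(res, by = "site")
  per_frag <- joined |>
    group_by(.data$fragment) |>
    summarise(
      mis_a = sum(.data$allele != .data$hap_a),
      mis_b = sum(.data$allele != .data$hap_b),
      .groups = "drop"
    )
  per_frag$fragment[pmin(per_frag$mis_a, per_frag$mis_b) >= 2]
}

#' Randomly choose one haplotype per phased component
#'
#' Mirrors the analysis step in which a single haplotype per strain enters
#' the phylogeny: within every connected component, haplotype A or B is
#' chosen uniformly at random (seeded), and the choice is recorded.
#'
#' @param phase phase tibble from [phase_fragments()]
#' @param seed integer seed
#' @return list with `haplotype` (tibble `site`, `allele`) and `choices`
#'   (tibble `component`, `chosen`)
#' @export
choose_haplotype <- function(phase, seed = 1) {
  comps <- sort(unique(phase$component))
  withr::with_seed(seed, {
    chosen <- sample(c("A", "B"), length(comps), replace = TRUE)
  })
  choices <- tibble(component = comps, chosen = chosen)
  hap <- phase |>
    left_join(choices, by = "component") |>
    mutate(allele = ifelse(.data$chosen == "A", .data$hap_a, .data$hap_b)) |>
    select("site", "allele")
  list(haplotype = hap, choices = choices)
}

#' Switch-error rate of an inferred phasing against truth
#'
#' Fraction of adjacent het-site pairs (within a component) whose inferred
#' phase relationship disagrees with the true haplotypes.
#'
#' @param phase phase tibble from [phase_fragments()]
#' @param truth tibble with `site`, `hap1`, `hap2`
#' @return switch-error rate in `[0, 1]` (NA when no comparable pairs)
#' @export
switch_error_rate <- function(phase, truth) {
  d <- left_join(phase, truth, by = "site")
  # orientation of each site: does hap_a carry the truth-hap1 allele?
  d$orient <- d$hap_a == d$hap1
  n_pair <- 0L; n_switch <- 0L
  for (cmp in unique(d$component)) {
    sub <- d[d$component == cmp, ]
    if (nrow(sub) < 2) next
    o <- sub$orient
    n_pair <- n_pair + (nrow(sub) - 1L)
    n_switch <- n_switch + sum(o[-1] != o[-length(o)])
  }
  if (n_pair == 0L) return(NA_real_)
  n_switch / n_pair
}
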