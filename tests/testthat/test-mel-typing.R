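test_that("the synthetic panel reproduces the published divergence
           structure", {
  mp <- shared_mel_panel()
  asian_block <- c("Asian I", "Asian II", "Asian-American", "European")
  afr_block <- c("African I", "African II", "South American")
  ref1 <- function(g) mp$seq[mp$group == g][1]
  within <- t92_distance(ref1("Asian I"), ref1("European"))
  expect_gt(within, 0.06)
  expect_lt(within, 0.15)
  across <- t92_distance(ref1("Asian I"), ref1("African I"))
  expect_gt(across, 0.15)
  expect_lt(across, 0.30)
  # African II is a pseudogene, everything else translates cleanly
  for (i in seq_len(nrow(mp))) {
    aa <- domestiscan:::translate_cds(mp$seq[i])
    has_stop <- grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE)
    expect_equal(has_stop, mp$group[i] == "African II")
  }
})

test_that("queries are assigned to their nearest allele group", {
  mp <- shared_mel_panel()
  eur <- mp$seq[mp$group == "European"][1]
  hit <- assign_mel_group(eur, mp)
  expect_equal(hit$group, "European")
  expect_lt(hit$distance, 0.012)  # mean over the group's 2 references
  expect_false(hit$ambiguous)

  # ~3% diverged queries from every group recover their source
  withr::with_seed(41, {
    for (g in unique(mp$group[!mp$outgroup])) {
      q <- domestiscan:::mutate_cds(mp$seq[mp$group == g][1], 0.03)
      expect_equal(assign_mel_group(q, mp)$group, g, info = g)
    }
  })
})

test_that("ties are flagged ambiguous", {
  mp <- shared_mel_panel()
  # a 50/50 chimera is nearly equidistant between its two parents
  a2 <- mp$seq[mp$group == "Asian II"][1]
  am <- mp$seq[mp$group == "Asian-American"][1]
  half <- nchar(a2) %/% 2
  chim <- paste0(substr(a2, 1, half), substr(am, half + 1, nchar(am)))
  hit <- assign_mel_group(chim, mp)
  expect_lt(hit$margin, 0.02)
})

test_that("chimeric alleles are detected with a junction-window breakpoint", {
  mp <- shared_mel_panel()
  a2 <- mp$seq[mp$group == "Asian II"][1]
  am <- mp$seq[mp$group == "Asian-American"][1]
  junction <- 700L
  chim <- paste0(substr(a2, 1, junction), substr(am, junction + 1,
                                                 nchar(am)))
  rec <- detect_recombinant(chim, mp)
  expect_true(rec$recombinant)
  expect_equal(rec$group_5p, "Asian II")
  expect_equal(rec$group_3p, "Asian-American")
  expect_lte(rec$breakpoint_start, junction)
  expect_gte(rec$breakpoint_end, junction - 200L)

  # pure sequences yield none; so does every panel member
  expect_false(detect_recombinant(a2, mp)$recombinant)
  for (i in seq_len(nrow(mp)))
    expect_false(detect_recombinant(mp$seq[i], mp)$recombinant)

  # a short foreign tail (< 25% of windows) is below the span rule
  tail_len <- floor(nchar(a2) * 0.1)
  mostly <- paste0(substr(a2, 1, nchar(a2) - tail_len),
                   substr(am, nchar(am) - tail_len + 1, nchar(am)))
  expect_false(detect_recombinant(mostly, mp)$recombinant)
})

test_that("the MEL tree keeps allele groups monophyletic and places
           queries with their group", {
  mp <- shared_mel_panel()
  q <- withr::with_seed(5,
    domestiscan:::mutate_cds(mp$seq[mp$group == "Asian I"][1], 0.02))
  mt <- mel_tree(mp, queries = c(query_asianI = q), replicates = 100,
                 seed = 2)
  rooted <- root_with_outgroup(mt$tree, "S_paradoxus_1")
  for (g in setdiff(unique(mp$group[!mp$outgroup]), "Asian I")) {
    expect_true(clade_is_monophyletic(rooted, mp$id[mp$group == g]),
                info = g)
  }
  # the query nests inside Asian I, so the clade includes it
  expect_true(clade_is_monophyletic(
    rooted, c(mp$id[mp$group == "Asian I"], "query_asianI")))
  mt2 <- mel_tree(mp, queries = c(query_asianI = q), replicates = 100,
                  seed = 2)
  expect_identical(mt$support, mt2$support)
})

test_that("functionality tracks CDS integrity on the typed panel", {
  p <- shared_panel()
  mel <- mel_typing(shared_calls(), p$mel_panel)
  typed <- mel[!is.na(mel$group), ]
  expect_true(all(typed$functional))  # planted copies are intact
  expect_false(any(typed$recombinant))
  want <- setNames(p$truth$mel_group, p$truth$strain)
  got <- setNames(mel$group, mel$strain)
  expect_equal(got[names(want)], want)

  # an inactivated European copy (wine-strain pattern) is non-functional
  mp <- p$mel_panel
  eur_dead <- apply_lesion(mp$seq[mp$group == "European"][1],
                           "premature_stop", seed = 12)$seq
  genome <- paste0(rand_dna_str(4000, 61), eur_dead, rand_dna_str(4000, 62))
  hit <- find_marker(genome, mp$seq[mp$group == "European"][1])
  integ <- cds_integrity(hit$alignment[[1]])
  expect_equal(integ$state, "present_inactivated")
  # ... as is the African II pseudogene reference itself
  afr2 <- mp$seq[mp$group == "African II"][1]
  expect_false(mp$functional[mp$group == "African II"][1])
})
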