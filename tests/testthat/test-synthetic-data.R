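test_that("reference generation is deterministic and hits target GC", {
  r1 <- make_reference(1, 10000, 0.5, seed = 7)
  r2 <- make_reference(1, 10000, 0.5, seed = 7)
  expect_identical(r1, r2)
  expect_equal(nchar(r1$seq), 10000)

  r <- make_reference(2, 50000, 0.38, seed = 1)
  for (s in r$seq) {
    gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
    expect_gte(gc, 0.36)
    expect_lte(gc, 0.40)
  }

  expect_error(make_reference(0, 10000, 0.5, 1))
  expect_error(make_reference(1, 5000, 0.5, 1))
  expect_error(make_reference(1, 10000, 1.2, 1))
})

test_that("lesions have the constructed effect on the gene product", {
  cds <- withr::with_seed(11, domestiscan:::random_cds(900))

  stop_les <- apply_lesion(cds, "premature_stop", seed = 3)
  aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  aa_mut <- as.character(Biostrings::translate(
    Biostrings::DNAString(stop_les$seq)))
  first_stop <- regexpr("*", aa_mut, fixed = TRUE)
  expect_lt(first_stop, nchar(aa_ref))  # truncated product
  expect_equal(first_stop[1], stop_les$lesion$codon)

  fs <- apply_lesion(cds, "frameshift", seed = 4)
  expect_true(abs(nchar(fs$seq) - nchar(cds)) %% 3 != 0)
  # downstream translation differs from the reference
  aa_fs <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(fs$seq, 1, (nchar(fs$seq) %/% 3) * 3)),
    if.fuzzy.codon = "X"))
  expect_false(identical(aa_fs, aa_ref))

  prom <- rand_dna_str(2000, 5)
  del <- apply_lesion(prom, "promoter_deletion", seed = 6,
                      deletion_len = 1162L)
  expect_equal(nchar(del$seq), 838)
  expect_error(apply_lesion(prom, "promoter_deletion", deletion_len = 2000L))
  expect_error(apply_lesion(substr(cds, 1, 150), "premature_stop"))
})

test_that("panel bookkeeping: strains, records and truth rows line up", {
  presets <- dplyr::bind_rows(
    population_preset("pop_a", "wild", "arboreal_low_sugar", 0.01, 100),
    population_preset("pop_b", "domesticated", "fermentation", 0.02, 100,
                      rtm1 = "present")
  )
  p <- simulate_panel(presets, n_per_preset = 3, seed = 9,
                      chrom_len = 30000L)
  expect_equal(nrow(p$truth), 6)
  expect_equal(nrow(p$consensus), 6)          # one chromosome
  expect_equal(anyDuplicated(p$truth$strain), 0)
  expect_equal(nrow(p$assemblies), 6)
  # clade signal: strains within a preset share >= 80% of derived variants
  v <- p$variants
  for (ps in c("pop_a", "pop_b")) {
    sts <- p$truth$strain[p$truth$preset == ps]
    k1 <- paste(v$chrom, v$pos)[v$strain == sts[1]]
    k2 <- paste(v$chrom, v$pos)[v$strain == sts[2]]
    expect_gte(length(intersect(k1, k2)) / length(k1), 0.8)
  }
})

test_that("heterozygous sites are emitted at the preset's target count", {
  p <- shared_panel()
  tr <- p$truth
  weak <- tr$strain[tr$preset == "beer2_sta1_weak"]
  cons <- p$consensus[p$consensus$strain == weak, ]
  n_het <- sum(strsplit(cons$seq, "")[[1]] %in%
                 c("M", "R", "W", "S", "Y", "K"))
  expect_lte(abs(n_het - 25000) / 25000, 0.05)
  expect_equal(tr$het_sites[tr$strain == weak], n_het)
})

test_that("recorded variants reproduce the emitted haplotypes byte-exactly", {
  p <- shared_panel()
  ref <- strsplit(p$reference$seq[1], "")[[1]]
  for (st in p$truth$strain[1:3]) {
    vv <- p$variants[p$variants$strain == st, ]
    for (hp in 1:2) {
      rr <- ref
      rr[vv$pos] <- vv[[paste0("hap", hp)]]
      emitted <- p$haplotypes$seq[p$haplotypes$strain == st &
                                    p$haplotypes$hap == hp]
      expect_identical(paste(rr, collapse = ""), emitted)
    }
  }
})

test_that("fixed seed gives byte-identical panels", {
  presets <- population_preset("pop", "wild", "arboreal_low_sugar",
                               0.01, 50)
  a <- simulate_panel(presets, seed = 5, chrom_len = 30000L)
  b <- simulate_panel(presets, seed = 5, chrom_len = 30000L)
  expect_identical(a$consensus, b$consensus)
  expect_identical(a$coverage, b$coverage)
  expect_identical(a$truth, b$truth)
})

test_that("coverage tracks conserve depth and scale with copy number", {
  cov1 <- simulate_gene_coverage(60000, 20001, 21500, multiplicity = 1,
                                 depth = 50, seed = 3)
  d <- cov1$depth[[1]]
  expect_lte(abs(mean(d) - 50) / 50, 0.05)

  cov11 <- simulate_gene_coverage(60000, 20001, 21413, multiplicity = 11,
                                  depth = 50, seed = 3)
  gene_mean <- mean(cov11$depth[[1]][20001:21413])
  expect_gte(gene_mean, 495)
  expect_lte(gene_mean, 605)
})

test_that("preset invariants are enforced", {
  expect_error(population_preset("x", "wild", "arboreal_low_sugar",
                                 0.06, 10))
  expect_error(population_preset("x", "wild", "arboreal_low_sugar",
                                 0.01, -1))
  expect_error(population_preset("x", "wild", "arboreal_low_sugar",
                                 0.01, 10, mel_copies = 2L))
  bad <- population_preset("x", "wild", "arboreal_low_sugar", 0.01, 10,
                           mel_group = "Asian I", mel_copies = 1L)
  bad$mel_group <- "Atlantis"
  expect_error(simulate_panel(bad, seed = 1, chrom_len = 30000L),
               "unknown MEL group")
})
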