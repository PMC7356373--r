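embed_marker <- function(marker, seed, flank = 4000) {
  left <- rand_dna_str(flank, seed)
  right <- rand_dna_str(flank, seed + 1)
  list(genome = paste0(left, marker, right), start = flank + 1,
       end = flank + nchar(marker))
}

test_that("k-mer seeding finds exact, diverged and absent markers", {
  cat <- shared_catalog()
  rtm1 <- cat$seq[cat$marker == "RTM1"]

  em <- embed_marker(rtm1, 101)
  hit <- find_marker(em$genome, rtm1)
  expect_equal(hit$state, "present")
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$kmer_fraction, 1.0)
  expect_equal(c(hit$start, hit$end), c(em$start, em$end))

  miss <- find_marker(rand_dna_str(10000, 55), rtm1)
  expect_equal(miss$state, "absent")
  expect_lt(miss$kmer_fraction, 0.1)

  # 2% substituted copy: still present, identity ~ 0.98
  div <- withr::with_seed(9, domestiscan:::mutate_dna(rtm1, 0.02))
  n_sub <- sum(strsplit(div, "")[[1]] != strsplit(rtm1, "")[[1]])
  hit2 <- find_marker(embed_marker(div, 102)$genome, rtm1)
  expect_equal(hit2$state, "present")
  expect_equal(hit2$identity, 1 - n_sub / nchar(rtm1), tolerance = 0.005)

  # presence bands are monotone in the k-mer fraction thresholds
  hit3 <- find_marker(embed_marker(div, 103)$genome, rtm1,
                      present_min = 0.9)
  expect_true(hit3$state %in% c("partial", "absent"))
  expect_equal(hit2$kmer_fraction, hit3$kmer_fraction)
})

test_that("divergent alleles are present-but-flagged, not absent", {
  cat <- shared_catalog()
  rtm1 <- cat$seq[cat$marker == "RTM1"]
  div <- withr::with_seed(77, domestiscan:::mutate_dna(rtm1, 0.06))
  asm <- tibble::tibble(strain = "s1", chrom = "c1",
                        seq = embed_marker(div, 104)$genome)
  calls <- screen_markers(asm, cat[cat$marker == "RTM1", ])
  row <- calls[calls$marker == "RTM1", ]
  expect_true(row$state != "absent")
  expect_lt(row$identity, 0.95)
  expect_true(row$divergent)
})

test_that("CDS integrity detects planted stops and frameshifts", {
  cat <- shared_catalog()
  suc2 <- cat$seq[cat$marker == "SUC2"]
  n_codon <- nchar(suc2) / 3

  # premature stop at codon 120 of the SUC2 stand-in
  v <- strsplit(suc2, "")[[1]]
  v[(119 * 3 + 1):(119 * 3 + 3)] <- c("T", "A", "A")
  stopped <- paste(v, collapse = "")
  hit <- find_marker(embed_marker(stopped, 105)$genome, suc2)
  integ <- cds_integrity(hit$alignment[[1]])
  expect_equal(integ$state, "present_inactivated")
  expect_equal(integ$lesions$kind, "premature_stop")
  expect_equal(integ$lesions$codon, 120L)
  expect_lt(integ$lesions$codon, n_codon)

  # 1-bp deletion at position 300: frameshift
  fs <- paste0(substr(suc2, 1, 299), substr(suc2, 301, nchar(suc2)))
  hit2 <- find_marker(embed_marker(fs, 106)$genome, suc2)
  integ2 <- cds_integrity(hit2$alignment[[1]])
  expect_equal(integ2$state, "present_inactivated")
  expect_true("frameshift" %in% integ2$lesions$kind)

  # intact copy
  hit3 <- find_marker(embed_marker(suc2, 107)$genome, suc2)
  expect_equal(cds_integrity(hit3$alignment[[1]])$state, "present_intact")
  expect_error(cds_integrity(NULL), "aligned copy")
})

test_that("promoter scan returns the exact constructed deletion length", {
  cat <- shared_catalog()
  prom <- cat$seq[cat$marker == "STA1_promoter"]
  for (len in c(1L, 3L, 50L, 1162L, 1999L)) {
    del <- apply_lesion(prom, "promoter_deletion", seed = len,
                        deletion_len = len)$seq
    expect_equal(sta1_promoter_scan(del, prom), len,
                 info = sprintf("deletion %d", len))
  }
  expect_equal(sta1_promoter_scan(prom, prom), 0L)
  # in-genome scan (internal deletion with flanks on both sides)
  em <- embed_marker(
    apply_lesion(prom, "promoter_deletion", seed = 4,
                 deletion_len = 1162L)$seq, 108)
  expect_equal(sta1_promoter_scan(em$genome, prom), 1162L)
  expect_warning(del <- sta1_promoter_scan(rand_dna_str(12000, 5), prom),
                 "unrecoverable")
  expect_true(is.na(del))
})

test_that("diastase genotype follows STA1 state and promoter", {
  expect_equal(diastase_genotype("present_intact", 0L), "diastase-positive")
  expect_equal(diastase_genotype("present_intact", 1162L),
               "weak/negative diastase")
  expect_equal(diastase_genotype("absent", NA_integer_), "no STA1")
})

test_that("aquaporin lesions match known signatures or come out novel", {
  sig <- default_aqy_signatures(shared_catalog())
  wine <- sig[sig$type == "wine", ]
  lesions <- dplyr::select(wine, "marker", "kind", "pos", "len", "codon")
  expect_equal(aqy_type(lesions, sig), "wine")

  unseen <- tibble::tibble(marker = "AQY1", kind = "premature_stop",
                           pos = 13L, len = 3L, codon = 5L)
  expect_equal(aqy_type(unseen, sig), "novel")
  expect_true(is.na(aqy_type(lesions[0, ], sig)))
})

test_that("the screen recovers every planted marker state on the panel", {
  p <- shared_panel()
  calls <- shared_calls()
  col_of <- c(AQY1 = "aqy1", AQY2 = "aqy2", SUC2 = "suc2", RTM1 = "rtm1",
              BIO1 = "bio1", BIO6 = "bio6", STA1 = "sta1",
              region_A = "region_a", region_B = "region_b",
              region_C = "region_c", MEL = "mel")
  for (m in names(col_of)) {
    got <- calls$state[calls$marker == m]
    names(got) <- calls$strain[calls$marker == m]
    want <- p$truth[[col_of[[m]]]]
    names(want) <- p$truth$strain
    expect_equal(got[names(want)], want, info = m)
  }
  # promoter deletion lengths match truth
  prom <- calls[calls$marker == "STA1_promoter", ]
  want_del <- setNames(p$truth$sta1_promoter_deletion, p$truth$strain)
  got_del <- setNames(prom$promoter_deletion, prom$strain)
  got_del[is.na(got_del)] <- 0L
  expect_equal(got_del[names(want_del)], want_del)
})

test_that("aquaporin typing recovers the planted inactivation types", {
  p <- shared_panel()
  aqy <- aqy_type_calls(shared_calls(), default_aqy_signatures(p$catalog))
  want <- p$truth$aqy_type
  want[!is.na(want) & want == "malaysia"] <- "novel"  # type not in table
  names(want) <- p$truth$strain
  got <- setNames(aqy$aqy_type, aqy$strain)
  expect_equal(got[names(want)], want)
})
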