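test_that("Tamura-92 distance matches hand-derived cases", {
  expect_equal(t92_distance("ACGT", "ACGT"), 0)

  # engineered pair: P = 0.1, Q = 0.05, pooled GC = 0.5
  a <- c(rep("A", 30), rep("T", 20), rep("G", 30), rep("C", 20))
  b <- a
  b[1:5] <- "G"      # 5 transitions A->G
  b[51:55] <- "A"    # 5 transitions G->A
  b[6:10] <- "T"     # 5 transversions A->T (GC-neutral)
  d <- t92_distance(paste(a, collapse = ""), paste(b, collapse = ""))
  expect_equal(d, 0.17018, tolerance = 1e-4)
  expect_equal(d, -0.5 * log(1 - 0.1 / 0.5 - 0.05) - 0.25 * log(1 - 0.1),
               tolerance = 1e-12)

  # saturation: log argument <= 0
  expect_true(is.na(t92_distance(strrep("A", 10), strrep("G", 10))))
  expect_error(t92_distance("NNN", "ACG"), "no comparable")
  expect_error(t92_distance("AC", "ACG"), "equal length")
})

test_that("Tamura-92 agrees with the reference implementation", {
  withr::with_seed(13, {
    a <- sample(c("A", "C", "G", "T"), 2000, replace = TRUE)
    b <- a
    mut <- sample(2000, 150)
    b[mut] <- vapply(b[mut], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  })
  mine <- t92_distance(paste(a, collapse = ""), paste(b, collapse = ""))
  bin <- ape::as.DNAbin(rbind(a = tolower(a), b = tolower(b)))
  ref <- as.numeric(ape::dist.dna(bin, model = "T92"))
  expect_equal(mine, ref, tolerance = 1e-8)
})

test_that("p-distance uses pairwise deletion", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("ANGT", "ACGT"), 0)  # 3 comparable sites
  expect_error(p_distance("NNNN", "ACGT"), "no comparable")
})

test_that("the correction never deflates: t92 >= p", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      a <- sample(c("A", "C", "G", "T"), 500, replace = TRUE)
      b <- a
      mut <- sample(500, 60)
      b[mut] <- vapply(b[mut], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    })
    sa <- paste(a, collapse = ""); sb <- paste(b, collapse = "")
    d <- t92_distance(sa, sb)
    if (!is.na(d)) expect_gte(d, p_distance(sa, sb))
  }
})

test_that("NJ recovers the additive 4-taxon topology found by the
           four-point condition", {
  for (seed in 1:10) {
    # random additive tree ((A,B),(C,D)) with positive branch lengths
    withr::with_seed(seed, e <- runif(5, 0.1, 2))
    # e: pendant A, B, C, D and internal edge
    d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    d["A", "B"] <- d["B", "A"] <- e[1] + e[2]
    d["C", "D"] <- d["D", "C"] <- e[3] + e[4]
    d["A", "C"] <- d["C", "A"] <- e[1] + e[5] + e[3]
    d["A", "D"] <- d["D", "A"] <- e[1] + e[5] + e[4]
    d["B", "C"] <- d["C", "B"] <- e[2] + e[5] + e[3]
    d["B", "D"] <- d["D", "B"] <- e[2] + e[5] + e[4]
    # oracle: the pairing with the smallest sum is the cherry split
    sums <- c(AB_CD = d["A", "B"] + d["C", "D"],
              AC_BD = d["A", "C"] + d["B", "D"],
              AD_BC = d["A", "D"] + d["B", "C"])
    expect_equal(names(which.min(sums)), "AB_CD")
    tr <- nj_tree(d)
    want <- ape::read.tree(text = "((A,B),(C,D));")
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(want)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("3-taxon branch lengths follow the closed form", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(lens[c("a", "b", "c")]), c(0.5, 1.5, 2.5))
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ topology is invariant to input label order", {
  withr::with_seed(3, m <- matrix(runif(36, 0.1, 1), 6))
  m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(letters[1:6], letters[1:6])
  t1 <- nj_tree(m)
  perm <- c(4, 2, 6, 1, 3, 5)
  t2 <- nj_tree(m[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("bootstrap supports a clean deep split and is reproducible", {
  withr::with_seed(17, {
    n_col <- 300
    groupA <- sprintf("a%d", 1:4); groupB <- sprintf("b%d", 1:4)
    informative <- 1:200
    base <- sample(c("A", "C", "G", "T"), n_col, replace = TRUE)
    mk <- function(nm, grp) {
      v <- base
      if (grp == "B") v[informative] <- ifelse(v[informative] == "A",
                                               "G", "A")
      flip <- sample(201:300, 15)
      v[flip] <- vapply(v[flip], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
      paste(v, collapse = "")
    }
    aln <- c(
      setNames(vapply(groupA, mk, "", grp = "A"), groupA),
      setNames(vapply(groupB, mk, "", grp = "B"), groupB)
    )
  })
  boot <- bootstrap_support(aln, metric = "p", replicates = 200, seed = 4)
  expect_gte(clade_support(boot, sprintf("a%d", 1:4)), 0.95)
  boot2 <- bootstrap_support(aln, metric = "p", replicates = 200, seed = 4)
  expect_identical(boot$support, boot2$support)

  none <- bootstrap_support(aln, metric = "p", replicates = 0)
  expect_null(none$support)
  expect_equal(ape::dist.topo(none$tree, boot$tree), 0, ignore_attr = TRUE)
})

test_that("Newick output round-trips topology, lengths and supports", {
  withr::with_seed(8, tr <- ape::rtree(8))
  tr$node.label <- c("", sprintf("%.3f", runif(tr$Nnode - 1)))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- read_newick(path)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-9)
  expect_identical(back$node.label, tr$node.label)
})

test_that("outgroup rooting splits the pendant edge and is idempotent", {
  tr <- ape::read.tree(text = "((A:1,B:1):0.5,(C:1,O:2):0.5);")
  r1 <- root_with_outgroup(tr, "O")
  expect_true(ape::is.rooted(r1))
  root_children <- r1$edge[r1$edge[, 1] == ape::Ntip(r1) + 1L, 2]
  expect_true(which(r1$tip.label == "O") %in% root_children)
  # pendant edge split at its midpoint
  e_tip <- which(r1$edge[, 2] == which(r1$tip.label == "O"))
  e_sib <- setdiff(which(r1$edge[, 1] == ape::Ntip(r1) + 1L), e_tip)
  expect_equal(r1$edge.length[e_tip], r1$edge.length[e_sib])
  r2 <- root_with_outgroup(r1, "O")
  expect_equal(ape::dist.topo(ape::unroot(r1), ape::unroot(r2)), 0,
               ignore_attr = TRUE)
  expect_error(root_with_outgroup(tr, "Z"), "not among")
})
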