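PURINES <- c("A", "G")

comparable_mask <- function(va, vb) (va %in% DNA_BASES) & (vb %in% DNA_BASES)

# vector-level metrics (hot path for bootstrap replicates)
p_dist_vec <- function(va, vb) {
  ok <- comparable_mask(va, vb)
  if (!any(ok)) abort("no comparable sites")
  mean(va[ok] != vb[ok])
}

t92_dist_vec <- function(va, vb) {
  ok <- comparable_mask(va, vb)
  if (!any(ok)) abort("no comparable sites")
  va <- va[ok]; vb <- vb[ok]
  n <- length(va)
  diff <- va != vb
  transition <- diff & ((va %in% PURINES) == (vb %in% PURINES))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  theta <- (sum(va %in% c("G", "C")) + sum(vb %in% c("G", "C"))) / (2 * n)
  h <- 2 * theta * (1 - theta)
  arg1 <- 1 - P / h - Q
  arg2 <- 1 - 2 * Q
  if (h <= 0 || arg1 <= 0 || arg2 <= 0) return(NA_real_)
  -h * log(arg1) - (1 - h) / 2 * log(arg2)
}

#' Tamura (1992) three-parameter distance between two sequences
#'
#' `d = -h ln(1 - P/h - Q) - (1 - h)/2 ln(1 - 2Q)` with `h = 2 theta (1 -
#' theta)`, where P and Q are the transition and transversion proportions
#' and theta is the GC fraction of the two sequences pooled. Sites where
#' either sequence is ambiguous are pairwise-deleted. Returns `NA` when the
#' correction saturates (a log argument <= 0).
#'
#' @param seq_a,seq_b equal-length sequence strings
#' @return distance in substitutions/site, or `NA` on saturation
#' @export
#' @examples
#' t92_distance("ACGT", "ACGT")  # 0
t92_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) abort("sequences must have equal length")
  t92_dist_vec(seq_chars(seq_a), seq_chars(seq_b))
}

#' Proportion of differing sites (p-distance) with pairwise deletion
#'
#' @inheritParams t92_distance
#' @return fraction of comparable sites at which the sequences differ
#' @export
p_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) abort("sequences must have equal length")
  p_dist_vec(seq_chars(seq_a), seq_chars(seq_b))
}

#' Pairwise distance matrix over an alignment
#'
#' @param alignment named character vector of equal-length sequences
#' @param metric "p" (proportion differing) or "t92" (Tamura 1992)
#' @return symmetric numeric matrix with zero diagonal
#' @export
distance_matrix <- function(alignment, metric = c("p", "t92")) {
  metric <- match.arg(metric)
  if (is.null(names(alignment))) abort("alignment sequences must be named")
  rows <- strsplit(alignment, "", fixed = TRUE)
  dist_matrix_rows(rows, names(alignment), metric)
}

dist_matrix_rows <- function(rows, labs, metric) {
  fn <- if (metric == "p") p_dist_vec else t92_dist_vec
  n <- length(rows)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- fn(rows[[i]], rows[[j]])
  }
  if (anyNA(d)) abort("distance saturation (NA) in matrix; use metric = 'p'")
  d
}

#' Neighbor-joining tree
#'
#' Standard NJ on a distance matrix; taxa are processed in label order so
#' ties resolve deterministically, and negative branch lengths are clamped
#' to zero.
#'
#' @param d symmetric distance matrix with at least 3 labels
#' @return `phylo` tree (unrooted)
#' @export
nj_tree <- function(d) {
  if (nrow(d) < 3) abort("neighbor-joining needs at least 3 taxa")
  d <- d[order(rownames(d)), order(colnames(d))]
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Column-bootstrap support for a tree builder
#'
#' Resamples alignment columns with replacement, rebuilds the tree for each
#' replicate, and annotates each internal bipartition of the reference tree
#' with the fraction of replicates containing it (stored in `node.label`).
#'
#' @param alignment named character vector of equal-length sequences
#' @param metric distance metric passed to [distance_matrix()]
#' @param replicates number of bootstrap replicates (0 = no supports)
#' @param seed integer seed
#' @return list with `tree` (`phylo`, node labels = support fractions) and
#'   `support` (numeric vector per internal node, NA for the root)
#' @export
bootstrap_support <- function(alignment, metric = "p", replicates = 1000,
                              seed = 1) {
  rows <- strsplit(alignment, "", fixed = TRUE)
  labs <- names(alignment)
  n_col <- length(rows[[1]])
  if (n_col < 1) abort("alignment must have at least one column")
  build <- function(idx) {
    nj_tree(dist_matrix_rows(lapply(rows, `[`, idx), labs, metric))
  }
  ref <- build(seq_len(n_col))
  if (replicates == 0)
    return(list(tree = ref, support = NULL))
  boots <- withr::with_seed(seed, {
    lapply(seq_len(replicates), function(b) {
      build(sample.int(n_col, replace = TRUE))
    })
  })
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  support <- counts / replicates
  ref$node.label <- ifelse(is.na(support), "", format(support, digits = 3))
  list(tree = ref, support = support)
}

#' Root a tree on the outgroup's pendant edge
#'
#' The root is placed at the midpoint of the edge leading to the outgroup
#' leaf; idempotent in topology.
#'
#' @param tree `phylo` object
#' @param outgroup outgroup tip label
#' @return rooted `phylo`
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    abort(sprintf("outgroup '%s' not among tip labels", outgroup))
  r <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  tip <- which(r$tip.label == outgroup)
  root_node <- ape::Ntip(r) + 1L
  e_tip <- which(r$edge[, 1] == root_node & r$edge[, 2] == tip)
  e_sib <- which(r$edge[, 1] == root_node & r$edge[, 2] != tip)
  if (length(e_tip) == 1 && length(e_sib) == 1) {
    total <- r$edge.length[e_tip] + r$edge.length[e_sib]
    r$edge.length[e_tip] <- total / 2
    r$edge.length[e_sib] <- total / 2
  }
  r
}

#' Write / read Newick with support labels
#'
#' Thin wrappers over the standard Newick serialization; supports are
#' carried as internal node labels and round-trip losslessly.
#'
#' @param tree `phylo`
#' @param path file path
#' @return `write_newick` returns the path invisibly; `read_newick` a
#'   `phylo`
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Are a set of tips monophyletic in a tree?
#'
#' @param tree `phylo`
#' @param tips tip labels
#' @return logical
#' @export
clade_is_monophyletic <- function(tree, tips) {
  ape::is.monophyletic(tree, tips)
}

#' Bootstrap support of the smallest clade containing a set of tips
#'
#' @param boot result of [bootstrap_support()]
#' @param tips tip labels forming the putative clade
#' @return support fraction, or NA if the tips are not monophyletic
#' @export
clade_support <- function(boot, tips) {
  tr <- boot$tree
  if (!ape::is.monophyletic(tr, tips)) return(NA_real_)
  node <- ape::getMRCA(tr, tips)
  boot$support[node - ape::Ntip(tr)]
}
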