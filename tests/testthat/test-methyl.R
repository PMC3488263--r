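test_that("clustering: singletons, single-linkage chains, planted families", {
  th <- rm_thresholds()
  no_hits <- search_hits(character(), character(), 1)
  cl0 <- cluster_by_identity(no_hits, c("a", "b", "c"))
  expect_equal(length(unique(cl0$cluster_id)), 3L)

  # chain a-b, b-c qualify; a-c does not: one cluster by transitivity
  mk <- function(q, s, id, cq, cs) data.frame(
    query_id = q, subject_id = s, identity = id,
    coverage_query = cq, coverage_subject = cs, coverage_longer = cq,
    aln_length = 100L, score = 50, evalue = 1e-6)
  hits <- rbind(mk("a", "b", 0.45, 0.7, 0.7), mk("b", "c", 0.50, 0.8, 0.8),
                mk("a", "c", 0.30, 0.9, 0.9))
  cl <- cluster_by_identity(hits, c("a", "b", "c", "d"))
  expect_equal(length(unique(cl$cluster_id[cl$gene_id %in%
                                             c("a", "b", "c")])), 1L)
  expect_false(cl$cluster_id[cl$gene_id == "d"] %in%
                 cl$cluster_id[cl$gene_id == "a"])

  # boundary: exactly 40% identity or exactly 60% coverage do not link
  b1 <- cluster_by_identity(mk("a", "b", 0.40, 0.7, 0.7), c("a", "b"))
  expect_equal(length(unique(b1$cluster_id)), 2L)
  b2 <- cluster_by_identity(mk("a", "b", 0.45, 0.60, 0.7), c("a", "b"))
  expect_equal(length(unique(b2$cluster_id)), 2L)

  # planted solitary and Type IV families at background inter-identity
  set.seed(81)
  famA <- generate_family(150, 4, 0.10)$members
  famB <- generate_family(150, 4, 0.10)$members
  seqs <- c(stats::setNames(famA, paste0("sol", 1:4)),
            stats::setNames(famB, paste0("t4_", 1:4)))
  cats <- c(rep("solitary", 4), rep("methyl_directed", 4))
  names(cats) <- names(seqs)
  hits2 <- search_hits(seqs, seqs, th$typeiv_evalue)
  cl2 <- cluster_by_identity(hits2, names(seqs), cats)
  expect_equal(length(unique(cl2$cluster_id)), 2L)
  expect_false(any(cl2$mixed))
  # clustering is independent of input order
  perm <- sample(names(seqs))
  cl3 <- cluster_by_identity(hits2, perm, cats)
  grp <- function(cl) unname(split(cl$gene_id, cl$cluster_id))
  expect_setequal(vapply(grp(cl2), paste, "", collapse = ","),
                  vapply(grp(cl3), paste, "", collapse = ","))

  # a solitary RE planted inside the Type IV family flags the cluster mixed
  seqs_mix <- c(seqs, sol_x = mutate_protein(famB[[1]], 0.1))
  cats_mix <- c(cats, sol_x = "solitary")
  hm <- search_hits(seqs_mix, seqs_mix, th$typeiv_evalue)
  clm <- cluster_by_identity(hm, names(seqs_mix), cats_mix)
  t4_cluster <- clm$cluster_id[clm$gene_id == "t4_1"]
  expect_true(all(clm$mixed[clm$cluster_id == t4_cluster]))
})

test_that("progressive MSA: trivial cases and input recovery", {
  m2 <- progressive_msa(c(x = "MACDEF", y = "MACDEF"))
  expect_equal(unname(m2$aligned), c("MACDEF", "MACDEF"))

  m <- progressive_msa(c(a = "ACDE", b = "ACE"))
  expect_equal(ncol(m$matrix), 4L)
  expect_equal(sum(m$matrix == "-"), 1L)   # one gap column
  expect_equal(gsub("-", "", m$aligned[["a"]]), "ACDE")
  expect_equal(gsub("-", "", m$aligned[["b"]]), "ACE")

  m1 <- progressive_msa(c(solo = "MKLV"))
  expect_equal(unname(m1$aligned), "MKLV")

  set.seed(82)
  fam <- generate_family(120, 5, 0.10, indel_rate = 0.005)$members
  msa <- progressive_msa(fam)
  for (nm in names(fam))
    expect_equal(gsub("-", "", msa$aligned[[nm]]), fam[[nm]])
})

test_that("MSA majority column matches the ancestor at low divergence", {
  set.seed(83)
  fam <- generate_family(200, 5, 0.10)
  msa <- progressive_msa(fam$members)
  maj <- apply(msa$matrix, 2, function(col) {
    tb <- table(col[col != "-"])
    names(tb)[which.max(tb)]
  })
  anc <- strsplit(fam$root, "")[[1]]
  # substitution-only members stay colinear with the root
  expect_equal(length(maj), length(anc))
  expect_gte(mean(maj == anc), 0.90)
})

test_that("NJ: three-taxon closed form and additive exactness", {
  d3 <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  # three-point formulas: a = (dAB + dAC - dBC)/2 etc.
  bl <- stats::setNames(t3$edge.length[order(t3$edge[, 2])][1:3],
                        t3$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(2, 3, 7))

  t4 <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):1);")
  rec4 <- nj_tree(tree_dist(t4))
  expect_true(rf_zero(rec4, t4))
  expect_equal(tree_dist(rec4), tree_dist(t4), tolerance = 1e-8)

  set.seed(84)
  t8 <- ape::rtree(8, br = function(n) runif(n, 0.5, 3))
  rec8 <- nj_tree(tree_dist(t8))
  expect_true(rf_zero(rec8, t8))
  expect_equal(tree_dist(rec8), tree_dist(t8), tolerance = 1e-8)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ matches the independent ape reference on random matrices", {
  set.seed(85)
  for (k in 1:10) {
    n <- sample(5:12, 1)
    m <- matrix(runif(n * n, 0.1, 2), n, n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    rownames(m) <- colnames(m) <- paste0("t", 1:n)
    mine <- nj_tree(m)
    ref <- ape::nj(as.dist(m))
    expect_true(rf_zero(mine, ref))
  }
})

test_that("bootstrap: degenerate, two-clade and single-replicate behavior", {
  # identical sequences: zero distances, star tree, vacuous supports
  m_id <- matrix(rep(strsplit("MACDEF", "")[[1]], each = 4), nrow = 4)
  rownames(m_id) <- paste0("s", 1:4)
  bs0 <- bootstrap_support(m_id, n_reps = 5, seed = 1)
  expect_true(all(bs0$support == 1))     # vacuously: no internal edges
  expect_length(bs0$support, 0)

  # two clearly separated clades: the split edge is near-certain
  set.seed(86)
  cladeA <- generate_family(150, 3, 0.04)$members
  cladeB <- generate_family(150, 3, 0.04)$members
  seqs <- c(stats::setNames(cladeA, paste0("A", 1:3)),
            stats::setNames(cladeB, paste0("B", 1:3)))
  msa <- progressive_msa(seqs)
  bs <- bootstrap_support(msa, n_reps = 200, seed = 7)
  key <- vapply(strsplit(names(bs$support), "|", fixed = TRUE),
                function(x) paste(sort(x), collapse = ","), "")
  split_edge <- names(bs$support)[key %in% c("A1,A2,A3", "B1,B2,B3")]
  expect_gte(max(bs$support[split_edge]), 0.95)

  # single replicate: supports are 0 or 1; deterministic under seed
  bs1 <- bootstrap_support(msa, n_reps = 1, seed = 3)
  expect_true(all(bs1$support %in% c(0, 1)))
  bs1b <- bootstrap_support(msa, n_reps = 1, seed = 3)
  expect_identical(bs1$support, bs1b$support)
})

test_that("bootstrap supports are equivariant under leaf relabeling", {
  set.seed(87)
  fam <- generate_family(120, 5, 0.15)$members
  names(fam) <- paste0("x", 1:5)
  msa <- progressive_msa(fam)
  bs <- bootstrap_support(msa, n_reps = 50, seed = 11)
  # relabel leaves: x1..x5 -> y5..y1 (reverse order names)
  relab <- stats::setNames(paste0("y", 5:1), paste0("x", 1:5))
  m2 <- msa$matrix
  rownames(m2) <- unname(relab[rownames(m2)])
  bs2 <- bootstrap_support(m2, n_reps = 50, seed = 11)
  rename_part <- function(p) vapply(
    strsplit(p, "|", fixed = TRUE),
    function(x) paste(sort(unname(relab[x])), collapse = "|"), "")
  canon <- function(s, all_labs) {
    # normalize each bipartition to the side not containing the smallest label
    vapply(strsplit(s, "|", fixed = TRUE), function(side) {
      other <- setdiff(all_labs, side)
      pick <- if (min(all_labs) %in% side) other else side
      paste(sort(pick), collapse = "|")
    }, "")
  }
  labs <- sort(rownames(m2))
  s1 <- stats::setNames(bs$support, canon(rename_part(names(bs$support)),
                                          labs))
  s2 <- stats::setNames(bs2$support, canon(names(bs2$support), labs))
  expect_equal(s1[sort(names(s1))], s2[sort(names(s2))])
})
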