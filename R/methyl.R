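# Screen of solitary REs against methyl-directed (Type IIM/IV) REs:
# single-linkage clustering of similarity hits, progressive multiple
# alignment, neighbor-joining trees and column-resampling bootstrap.
# The screen reports mixed clusters and tree placements; it never
# auto-reclassifies a solitary RE as methyl-directed.

#' Single-linkage clusters from similarity hits
#'
#' Two sequences are linked when a hit between them has identity strictly
#' above `cluster_identity` (40\%) and coverage of *each* sequence strictly
#' above `cluster_coverage` (60\%). Clusters are the connected components of
#' the link graph; sequences without qualifying links form singleton
#' clusters. A cluster is `mixed` when its members span more than one
#' category (e.g. solitary REs and Type IV REs).
#'
#' @param hits AlignmentHit data.frame (typically from [search_hits()] at
#'   the Type IV screen E-value).
#' @param ids character vector: the full sequence universe.
#' @param categories named character vector mapping ids to categories.
#' @param thresholds an [rm_thresholds()] list.
#' @return data.frame: `cluster_id`, `gene_id`, `category`, `mixed`.
#' @export
cluster_by_identity <- function(hits, ids, categories = NULL,
                                thresholds = rm_thresholds()) {
  ids <- sort(unique(ids))
  keep <- hits[hit_meets(hits, thresholds$cluster_identity,
                         thresholds$cluster_coverage, "each") &
                 hits$query_id %in% ids & hits$subject_id %in% ids, ,
               drop = FALSE]
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(ids)
  if (nrow(keep))
    g <- igraph::add_edges(g, rbind(keep$query_id, keep$subject_id))
  memb <- igraph::membership(igraph::components(g))
  # stable cluster numbering: by smallest member id
  first <- vapply(split(names(memb), as.integer(memb)), min, "")
  renum <- rank(first)[as.character(as.integer(memb))]
  out <- data.frame(cluster_id = sprintf("c%03d", as.integer(renum)),
                    gene_id = names(memb), stringsAsFactors = FALSE)
  out$category <- if (!is.null(categories))
    unname(categories[out$gene_id]) else NA_character_
  mixed_by <- tapply(out$category, out$cluster_id,
                     function(x) length(unique(stats::na.omit(x))) > 1L)
  out$mixed <- unname(mixed_by[out$cluster_id])
  out[order(out$cluster_id, out$gene_id), , drop = FALSE]
}

## ---- neighbor joining -----------------------------------------------------

# canonical newick-safe check
.check_dist <- function(d) {
  if (!is.matrix(d)) d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(d < 0)) stop("distances must be non-negative")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <-
      paste0("t", seq_len(nrow(d)))
  d
}

fmt_bl <- function(x) sprintf("%.12g", max(0, x))

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration (Studier-Keppler Q-criterion). On an
#' additive distance matrix the generating topology and branch lengths are
#' recovered exactly. Ties in the Q matrix are broken by the smallest index
#' pair, making runs deterministic; negative branch lengths are clamped to
#' zero. Taxa at pairwise distance zero are merged before the agglomeration
#' and re-attached as zero-length pendants (with fewer than three distinct
#' taxa the result degenerates to a star/cherry of zero-length branches).
#'
#' @param d symmetric, zero-diagonal, non-negative distance matrix (or
#'   `dist`) over at least 3 taxa.
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- .check_dist(d)
  n0 <- nrow(d)
  if (n0 < 3L) stop("need at least 3 taxa")
  labs <- rownames(d)
  # merge zero-distance duplicates
  gz <- igraph::graph_from_adjacency_matrix(d == 0, mode = "undirected",
                                            diag = FALSE)
  memb <- igraph::membership(igraph::components(gz))
  reps <- vapply(split(labs, as.integer(memb)), `[[`, "", 1L)
  sub_label <- vapply(split(labs, as.integer(memb)), function(g) {
    if (length(g) == 1L) g else
      paste0("(", paste0(g, ":0", collapse = ","), ")")
  }, "")
  D <- d[reps, reps, drop = FALSE]
  k <- length(reps)
  lab <- unname(sub_label)
  if (k == 1L)
    return(ape::read.tree(text = paste0(
      "(", paste0(labs, ":0", collapse = ","), ");")))
  if (k == 2L) {
    h <- D[1L, 2L] / 2
    return(ape::read.tree(text = sprintf("(%s:%s,%s:%s);",
      lab[1L], fmt_bl(h), lab[2L], fmt_bl(h))))
  }
  while (k > 3L) {
    r <- rowSums(D)
    Q <- (k - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # smallest index pair among minima (row-major i<j)
    m <- min(Q)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      j <- which(Q[i, (i + 1L):k] <= m + 1e-12)
      if (length(j)) { best <- c(i, i + j[1L]); break }
    }
    i <- best[1L]; j <- best[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    lj <- D[i, j] - li
    newlab <- sprintf("(%s:%s,%s:%s)", lab[i], fmt_bl(li),
                      lab[j], fmt_bl(lj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    lab <- c(lab[keep], newlab)
    k <- k - 1L
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", lab[1L], fmt_bl(la),
                 lab[2L], fmt_bl(lb), lab[3L], fmt_bl(lc))
  ape::read.tree(text = txt)
}

# non-trivial bipartitions of an (unrooted) tree as canonical strings
tree_biparts <- function(phy) {
  nt <- length(phy$tip.label)
  if (nt < 4L) return(character())
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  all_sorted <- sort(labs)
  out <- character()
  for (s in pp) {
    tips <- sort(labs[s])
    if (length(tips) <= 1L || length(tips) >= nt - 1L) next
    comp <- setdiff(all_sorted, tips)
    side <- if (all_sorted[1L] %in% tips) comp else tips
    out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

# pairwise p-distances from an alignment matrix (rows = taxa)
msa_pdist <- function(m, cols = seq_len(ncol(m))) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  sub <- m[, cols, drop = FALSE]
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- sub[i, ] != "-" & sub[j, ] != "-"
    d[i, j] <- d[j, i] <- if (any(ok))
      1 - mean(sub[i, ok] == sub[j, ok]) else 0
  }
  d
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree from
#' p-distances for each replicate, and reports, for every non-trivial
#' bipartition of the original tree, the fraction of replicates containing
#' it. Deterministic given `seed`. Alignments with fewer than four taxa (or
#' degenerate all-identical alignments whose tree is a star) have no
#' internal edges and yield an empty support vector.
#'
#' @param msa character matrix (rows = taxa, columns = alignment columns),
#'   or the list returned by [progressive_msa()].
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @return list: `tree` (the original NJ `phylo`) and `support` (named
#'   numeric vector keyed by bipartition).
#' @export
bootstrap_support <- function(msa, n_reps = 200L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  m <- if (is.list(msa) && !is.null(msa$matrix)) msa$matrix else msa
  stopifnot(is.matrix(m))
  d0 <- msa_pdist(m)
  tree <- nj_tree(d0)
  bp <- tree_biparts(tree)
  if (nrow(m) < 4L || !length(bp))
    return(list(tree = tree, support = stats::setNames(numeric(), character())))
  counts <- stats::setNames(numeric(length(bp)), bp)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    tr <- nj_tree(msa_pdist(m, cols))
    rb <- tree_biparts(tr)
    counts[bp %in% rb] <- counts[bp %in% rb] + 1
  }
  list(tree = tree, support = counts / n_reps)
}

## ---- progressive multiple alignment --------------------------------------

PROFILE_GAP_SCORE <- -4   # residue-vs-gap column score
PROFILE_GAP_PENALTY <- 8  # per-gap-column penalty in the profile NW

# 21-symbol scoring matrix: BLOSUM62 over the 20 residues, gap row/col -4,
# gap-gap 0
.b21 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      b <- blosum62()[AA_ALPHABET, AA_ALPHABET]
      m2 <- rbind(cbind(b, `-` = PROFILE_GAP_SCORE), `-` = PROFILE_GAP_SCORE)
      m2["-", "-"] <- 0
      m <<- m2
    }
    m
  }
})

profile_freq <- function(prof) {
  syms <- c(AA_ALPHABET, "-")
  f <- matrix(0, length(syms), ncol(prof), dimnames = list(syms, NULL))
  for (s in syms) f[s, ] <- colMeans(prof == s)
  f
}

# global (Needleman-Wunsch) alignment of two profiles, linear gap penalty
align_profiles <- function(pa, pb) {
  fa <- profile_freq(pa); fb <- profile_freq(pb)
  S <- t(fa) %*% .b21() %*% fb
  na <- ncol(pa); nb <- ncol(pb)
  gp <- PROFILE_GAP_PENALTY
  M <- matrix(0, na + 1L, nb + 1L)
  M[, 1L] <- -gp * (0:na)
  M[1L, ] <- -gp * (0:nb)
  TB <- matrix(0L, na + 1L, nb + 1L)  # 1 diag, 2 up (gap in b), 3 left
  TB[, 1L] <- 2L; TB[1L, ] <- 3L; TB[1L, 1L] <- 0L
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      sc <- c(M[i, j] + S[i, j], M[i, j + 1L] - gp, M[i + 1L, j] - gp)
      k <- which.max(sc)
      M[i + 1L, j + 1L] <- sc[k]
      TB[i + 1L, j + 1L] <- k
    }
  }
  ai <- integer(); bi <- integer()   # column indices, 0 = gap column
  i <- na + 1L; j <- nb + 1L
  while (i > 1L || j > 1L) {
    k <- TB[i, j]
    if (k == 1L) { ai <- c(i - 1L, ai); bi <- c(j - 1L, bi); i <- i - 1L; j <- j - 1L }
    else if (k == 2L) { ai <- c(i - 1L, ai); bi <- c(0L, bi); i <- i - 1L }
    else { ai <- c(0L, ai); bi <- c(j - 1L, bi); j <- j - 1L }
  }
  take <- function(prof, idx) {
    out <- matrix("-", nrow(prof), length(idx))
    nz <- idx > 0L
    out[, nz] <- prof[, idx[nz], drop = FALSE]
    rownames(out) <- rownames(prof)
    out
  }
  rbind(take(pa, ai), take(pb, bi))
}

#' Progressive multiple sequence alignment
#'
#' Guide tree from neighbor joining on pairwise p-distances (1 - identity
#' of the pairwise local alignments), then postorder profile-profile
#' alignment with BLOSUM62 column scores and a linear gap penalty. Removing
#' gap characters from any row recovers the input sequence exactly.
#'
#' @param sequences named character vector of amino-acid sequences (>= 1).
#' @return list: `matrix` (character matrix, rows = sequences) and
#'   `aligned` (named character vector of gapped rows).
#' @export
progressive_msa <- function(sequences) {
  stopifnot(length(sequences) >= 1L)
  aa_check(sequences)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("s", seq_along(sequences))
  prof_of <- function(id) {
    m <- matrix(strsplit(sequences[[id]], "")[[1L]], nrow = 1L)
    rownames(m) <- id
    m
  }
  n <- length(sequences)
  if (n == 1L) {
    m <- prof_of(names(sequences))
    return(list(matrix = m,
                aligned = stats::setNames(sequences, names(sequences))))
  }
  if (n == 2L) {
    m <- align_profiles(prof_of(names(sequences)[1L]),
                        prof_of(names(sequences)[2L]))
  } else {
    ids <- names(sequences)
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    th <- rm_thresholds()
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      h <- align_pair(sequences[[i]], sequences[[j]], ids[i], ids[j], th)
      d[i, j] <- d[j, i] <- if (nrow(h)) 1 - h$identity else 1
    }
    guide <- nj_tree(d)
    guide <- ape::root(guide, outgroup = guide$tip.label[1L],
                       resolve.root = TRUE)
    merge_node <- function(node) {
      if (node <= length(guide$tip.label))
        return(prof_of(guide$tip.label[node]))
      kids <- guide$edge[guide$edge[, 1L] == node, 2L]
      prof <- merge_node(kids[1L])
      for (kk in kids[-1L]) prof <- align_profiles(prof, merge_node(kk))
      prof
    }
    m <- merge_node(length(guide$tip.label) + 1L)
    m <- m[names(sequences), , drop = FALSE]
  }
  # drop all-gap columns (can arise from profile merges)
  m <- m[, colSums(m != "-") > 0L, drop = FALSE]
  list(matrix = m,
       aligned = stats::setNames(apply(m, 1L, paste0, collapse = ""),
                                 rownames(m)))
}
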