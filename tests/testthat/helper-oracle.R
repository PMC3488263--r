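# Independent test oracles, deliberately naive implementations kept apart
# from the package code paths they verify.

.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.blosum62_test <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

rand_protein <- function(n) paste0(
  c("M", sample(.aa20, n - 1, replace = TRUE)), collapse = "")

# Quadratic-space affine-gap local alignment DP (gap of length L costs
# open + L * ext). Returns the optimal score and the SET of identity values
# achievable by co-optimal alignments (identity is not unique when several
# tracebacks share the optimal score, so the oracle enumerates them all via
# memoized recursion over the optimal subgraph; all scores are integral, so
# comparisons are exact).
sw_oracle <- function(a, b, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a (consumes b)
  for (i in 1:n) {
    si <- .blosum62_test[av[i], bv]
    for (j in 1:m) {
      M[i + 1, j + 1] <- max(0, max(M[i, j], X[i, j], Y[i, j]) + si[j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext), X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext), Y[i + 1, j] - ext)
    }
  }
  score <- max(M)
  # enumerate (npair, nmatch) over all co-optimal tracebacks
  memo <- new.env(parent = emptyenv())
  uniq <- function(mat) mat[!duplicated(mat), , drop = FALSE]
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- NULL
    if (state == "M") {
      if (M[i, j] == 0) out <- cbind(npair = 0, nmatch = 0)
      else {
        s <- .blosum62_test[av[i - 1], bv[j - 1]]
        tgt <- M[i, j] - s
        add <- c(1, as.integer(av[i - 1] == bv[j - 1]))
        for (st in c("M", "X", "Y")) {
          val <- switch(st, M = M[i - 1, j - 1], X = X[i - 1, j - 1],
                        Y = Y[i - 1, j - 1])
          if (val == tgt && (st != "M" || val >= 0)) {
            sub <- rec(i - 1, j - 1, st)
            out <- rbind(out, sweep(sub, 2, add, `+`))
          }
        }
      }
    } else if (state == "X") {
      if (M[i - 1, j] - (open + ext) == X[i, j])
        out <- rbind(out, rec(i - 1, j, "M"))
      if (X[i - 1, j] - ext == X[i, j])
        out <- rbind(out, rec(i - 1, j, "X"))
    } else {
      if (M[i, j - 1] - (open + ext) == Y[i, j])
        out <- rbind(out, rec(i, j - 1, "M"))
      if (Y[i, j - 1] - ext == Y[i, j])
        out <- rbind(out, rec(i, j - 1, "Y"))
    }
    out <- uniq(out)
    memo[[key]] <- out
    out
  }
  ends <- which(M == score, arr.ind = TRUE)
  pairs <- NULL
  for (r in seq_len(nrow(ends)))
    pairs <- rbind(pairs, rec(ends[r, 1], ends[r, 2], "M"))
  pairs <- uniq(pairs)
  ids <- ifelse(pairs[, "npair"] > 0, pairs[, "nmatch"] / pairs[, "npair"], 0)
  list(score = score, identities = sort(unique(ids)))
}

# Independent audit of a reported alignment: rescore the gapped strings
# column by column (gap of length L costs open + L * ext) and recount
# matches / aligned residue-pair columns.
audit_alignment <- function(aligned_query, aligned_subject,
                            open = 11, ext = 1) {
  p <- strsplit(aligned_query, "")[[1]]
  s <- strsplit(aligned_subject, "")[[1]]
  stopifnot(length(p) == length(s))
  sc <- 0; gap_p <- FALSE; gap_s <- FALSE; nmatch <- 0; npair <- 0
  for (i in seq_along(p)) {
    if (p[i] == "-") {
      sc <- sc - ext - if (gap_p) 0 else open
      gap_p <- TRUE; gap_s <- FALSE
    } else if (s[i] == "-") {
      sc <- sc - ext - if (gap_s) 0 else open
      gap_s <- TRUE; gap_p <- FALSE
    } else {
      sc <- sc + .blosum62_test[p[i], s[i]]
      gap_p <- FALSE; gap_s <- FALSE
      npair <- npair + 1
      if (p[i] == s[i]) nmatch <- nmatch + 1
    }
  }
  list(score = sc, identity = if (npair) nmatch / npair else 0,
       npair = npair)
}

# Brute-force best-bidirectional-hit oracle over two named protein vectors:
# all pairwise hits via align_pair, role thresholds on the longer-sequence
# coverage, argmax by (score, identity, id), reciprocal pairs.
bbh_oracle <- function(a, b, role, th = rm_thresholds()) {
  rth <- if (role == "RE")
    list(id = th$re_ortho_identity, cov = th$re_ortho_coverage)
  else list(id = th$mtase_ortho_identity, cov = th$mtase_ortho_coverage)
  hit_tab <- list()
  for (x in names(a)) for (y in names(b)) {
    h <- align_pair(a[[x]], b[[y]], x, y, th)
    if (nrow(h) && h$identity > rth$id && h$coverage_longer > rth$cov)
      hit_tab[[paste(x, y)]] <- h
  }
  if (!length(hit_tab)) return(character())
  hits <- do.call(rbind, hit_tab)
  pick <- function(h) h[order(-h$score, -h$identity, h$subject_id), ][1, ]
  best_ab <- vapply(split(hits, hits$query_id),
                    function(h) pick(h)$subject_id, "")
  rev <- hits; rev$query_id <- hits$subject_id; rev$subject_id <- hits$query_id
  best_ba <- vapply(split(rev, rev$query_id),
                    function(h) pick(h)$subject_id, "")
  out <- character()
  for (x in names(best_ab)) {
    y <- best_ab[[x]]
    if (identical(best_ba[[y]], x)) out <- c(out, paste(x, y, sep = "~"))
  }
  sort(out)
}

# mutate a protein: per-site substitutions at rate d (uniform alternatives)
mutate_protein <- function(seq, d) {
  v <- strsplit(seq, "")[[1]]
  mut <- which(runif(length(v)) < d); mut <- mut[mut > 1]
  for (p in mut) v[p] <- sample(setdiff(.aa20, v[p]), 1)
  paste0(v, collapse = "")
}

# distances implied by an ape tree (path lengths between tips)
tree_dist <- function(phy) {
  d <- ape::cophenetic.phylo(phy)
  d[sort(rownames(d)), sort(colnames(d))]
}

rf_zero <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
}

# small two-genome annotation for distance / classification unit tests
toy_replicons <- function(L = 1e6L, topology = "linear") {
  replicon_records(c("chrA", "chrB"), c("gA", "gA"), L, topology)
}
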