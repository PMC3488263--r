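# Completeness classification and the 4 kb vicinity scan for MTase-like ORFs.

#' Group annotated genes into R-M systems
#'
#' Genes sharing a `system_id` within one genome form one system; genes with
#' `system_id = NA` become singleton systems keyed by their gene id. The
#' input's grouping is preserved as-is (how multi-MTase systems are counted
#' is taken from the annotation, not re-derived).
#'
#' @param genes gene-record data.frame.
#' @return data.frame with one row per system: `system_id`, `genome_id`,
#'   `completeness`, `n_re`, `n_mtase`, `n_s`, and a `gene_ids` list-column.
#' @export
build_systems <- function(genes) {
  rm_genes <- genes[genes$role %in% RM_ROLES, , drop = FALSE]
  if (!nrow(rm_genes))
    return(data.frame(system_id = character(), genome_id = character(),
                      completeness = character(), n_re = integer(),
                      n_mtase = integer(), n_s = integer()))
  sid <- ifelse(is.na(rm_genes$system_id),
                paste0("solo:", rm_genes$gene_id), rm_genes$system_id)
  key <- paste(rm_genes$genome_id, sid, sep = "\r")
  idx <- split(seq_len(nrow(rm_genes)), key)
  rows <- lapply(idx, function(i) {
    g <- rm_genes[i, , drop = FALSE]
    data.frame(system_id = sid[i[1L]], genome_id = g$genome_id[1L],
               completeness = classify_completeness(g),
               n_re = sum(g$role == "RE"), n_mtase = sum(g$role == "MTase"),
               n_s = sum(g$role == "S_subunit"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$gene_ids <- lapply(idx, function(i) unique(rm_genes$gene_id[i]))
  rownames(out) <- NULL
  out[order(out$genome_id, out$system_id), , drop = FALSE]
}

#' Completeness of one R-M system
#'
#' A system is `complete` iff it contains at least one non-corrupted RE gene
#' and at least one non-corrupted MTase gene; everything else is
#' `incomplete`.
#'
#' @param system_genes gene rows of one system.
#' @return `"complete"` or `"incomplete"`.
#' @export
classify_completeness <- function(system_genes) {
  stopifnot(nrow(system_genes) >= 1L)
  ok <- !system_genes$corrupted
  if (any(ok & system_genes$role == "RE") &&
      any(ok & system_genes$role == "MTase")) "complete" else "incomplete"
}

#' Six-frame open reading frames
#'
#' Stop-to-stop segments (start-codon-agnostic, as the getorf default) in
#' all six frames of a nucleotide sequence, translated with the standard
#' code. Segments shorter than `min_bp` are dropped. Coordinates are
#' 0-based half-open on the forward strand of the input sequence.
#'
#' @param dna nucleotide string.
#' @param min_bp minimum ORF length in bp (aa length * 3).
#' @return data.frame: `start`, `end`, `strand`, `frame`, `protein`.
#' @export
find_orfs <- function(dna, min_bp = 150L) {
  n <- nchar(dna)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
    for (f in 0:2) {
      ncod <- (n - f) %/% 3L
      if (ncod < 1L) next
      sub <- substr(s, f + 1L, f + ncod * 3L)
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "solve"))
      # segments between stop codons
      pieces <- strsplit(aa, "*", fixed = TRUE)[[1L]]
      pos <- 0L
      for (p in pieces) {
        w <- nchar(p)
        if (w * 3L >= min_bp && !grepl("X", p, fixed = TRUE)) {
          cs <- f + pos * 3L          # 0-based on current strand
          ce <- cs + w * 3L
          if (strand == "+") {
            out[[length(out) + 1L]] <- data.frame(
              start = cs, end = ce, strand = strand, frame = f,
              protein = p, stringsAsFactors = FALSE)
          } else {
            out[[length(out) + 1L]] <- data.frame(
              start = n - ce, end = n - cs, strand = strand, frame = f,
              protein = p, stringsAsFactors = FALSE)
          }
        }
        pos <- pos + w + 1L
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Scan the vicinity of an RE gene for MTase-like ORFs
#'
#' Implements the vicinity rule: a window of `thresholds$vicinity_bp`
#' (default 4 kb) upstream and downstream of the RE gene is scanned. Two
#' sources of evidence are combined: (i) annotated MTase genes overlapping
#' the window by at least 1 bp, and (ii) when the replicon nucleotide
#' sequence is available, all six-frame ORFs in the window searched against
#' the MTase reference protein set at `evalue < orf_evalue`. An unannotated
#' ORF counts as a full-length (non-corrupted) MTase when its best hit
#' covers more than `orf_ref_coverage` of the reference protein; frameshift
#' fragments fail that test. Without a replicon sequence the scan degrades
#' to annotation-only and the result is flagged accordingly.
#'
#' @param re_gene one-row gene-record for a non-corrupted RE.
#' @param genes full gene table (annotated MTases are consulted).
#' @param replicons replicon table.
#' @param replicon_seq nucleotide string of the RE's replicon, or `NULL`.
#' @param mtase_ref named character vector of reference MTase proteins.
#' @param thresholds an [rm_thresholds()] list.
#' @return list of class `rm_vicinity_scan`: `re_gene_id`, `intervals`,
#'   `candidate_orfs`, `has_noncorrupted_mtase`, `has_corrupted_mtase`,
#'   `annotation_only`.
#' @export
scan_vicinity_for_mtases <- function(re_gene, genes, replicons,
                                     replicon_seq = NULL, mtase_ref = NULL,
                                     thresholds = rm_thresholds()) {
  rep <- replicons[replicons$replicon_id == re_gene$replicon_id[1L], ,
                   drop = FALSE]
  if (!nrow(rep)) stop("unknown replicon for gene ", re_gene$gene_id[1L])
  arcs <- vicinity_interval(re_gene, thresholds$vicinity_bp, rep)
  nearby <- genes[genes$replicon_id == re_gene$replicon_id[1L] &
                    genes$role == "MTase" &
                    genes$gene_id != re_gene$gene_id[1L], , drop = FALSE]
  if (nrow(nearby)) {
    inwin <- vapply(seq_len(nrow(nearby)), function(i)
      overlaps_intervals(nearby$start[i], nearby$end[i], arcs), TRUE)
    nearby <- nearby[inwin, , drop = FALSE]
  }
  has_ok <- any(!nearby$corrupted)
  has_bad <- any(nearby$corrupted)
  cand <- data.frame(start = integer(), end = integer(), strand = character(),
                     frame = integer(), ref_id = character(),
                     identity = numeric(), coverage_ref = numeric(),
                     evalue = numeric(), full_length = logical(),
                     stringsAsFactors = FALSE)
  annotation_only <- is.null(replicon_seq)
  if (!annotation_only && length(mtase_ref)) {
    vic_seq <- extract_arcs(replicon_seq, arcs)
    orfs <- find_orfs(vic_seq, thresholds$min_orf_bp)
    if (nrow(orfs)) {
      prot <- stats::setNames(orfs$protein, paste0("orf", seq_len(nrow(orfs))))
      hits <- search_hits(prot, mtase_ref, evalue_max = Inf,
                          thresholds = thresholds)
      hits <- hits[hits$evalue < thresholds$orf_evalue, , drop = FALSE]
      if (nrow(hits)) {
        best <- do.call(rbind, lapply(split(hits, hits$query_id),
                                      function(h) order_hits(h)[1L, ]))
        i <- match(best$query_id, names(prot))
        # map window-relative ORF coordinates back onto the replicon
        off <- arcs[1L, "start"]
        L <- rep$length
        cand <- data.frame(
          start = (orfs$start[i] + off) %% L,
          end = ((orfs$end[i] - 1L + off) %% L) + 1L,
          strand = orfs$strand[i], frame = orfs$frame[i],
          ref_id = best$subject_id, identity = best$identity,
          coverage_ref = best$coverage_subject, evalue = best$evalue,
          full_length = best$coverage_subject > thresholds$orf_ref_coverage,
          stringsAsFactors = FALSE)
        has_ok <- has_ok || any(cand$full_length)
      }
    }
  }
  structure(list(re_gene_id = re_gene$gene_id[1L], intervals = arcs,
                 candidate_orfs = cand,
                 has_noncorrupted_mtase = has_ok,
                 has_corrupted_mtase = has_bad,
                 annotation_only = annotation_only),
            class = "rm_vicinity_scan")
}

#' Solitary call for one RE gene
#'
#' An RE is solitary iff its 4 kb vicinity contains no non-corrupted MTase —
#' neither annotated nor recovered as a full-length MTase-like ORF.
#' Corrupted RE genes are rejected: only intact RE genes are considered.
#'
#' @param re_gene one-row gene-record.
#' @param scan an `rm_vicinity_scan` from [scan_vicinity_for_mtases()].
#' @return logical.
#' @export
call_solitary <- function(re_gene, scan) {
  if (isTRUE(re_gene$corrupted[1L]))
    stop("call_solitary: corrupted RE genes are not considered")
  stopifnot(inherits(scan, "rm_vicinity_scan"))
  !scan$has_noncorrupted_mtase
}
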