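#' @importFrom utils read.delim write.table head tail
NULL

GENE_ROLES <- c("RE", "MTase", "S_subunit", "fused_RM", "other")
RM_TYPES   <- c("I", "II", "III", "IIG", "IIM", "IV", "unknown")
RM_ROLES   <- c("RE", "MTase", "S_subunit", "fused_RM")
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a gene-record table
#'
#' Genes use 0-based half-open coordinates (`start < end`) on the forward
#' strand of their replicon. A gene spanning the origin of a circular replicon
#' is stored as two rows (arcs) sharing one `gene_id`; `start > end` rows are
#' rejected. Roles outside the known vocabulary are mapped to `"other"`.
#'
#' @param genome_id,replicon_id,gene_id character vectors.
#' @param start,end integer bp, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param role one of `RE`, `MTase`, `S_subunit`, `fused_RM`, `other`.
#' @param rm_type one of `I`, `II`, `III`, `IIG`, `IIM`, `IV`, `unknown`.
#' @param corrupted logical: annotated pseudo / frameshift / premature stop.
#' @param system_id R-M system grouping key (`NA` = no system; treated as a
#'   singleton system keyed by the gene id).
#' @param product free-text product description (used by the MGE scan).
#' @param protein_seq amino-acid sequence; required for non-corrupted R-M
#'   role genes, empty string allowed otherwise.
#' @return data.frame with one row per gene (arc).
#' @export
gene_records <- function(genome_id, replicon_id, gene_id, start, end,
                         strand = "+", role = "other", rm_type = "unknown",
                         corrupted = FALSE, system_id = NA_character_,
                         product = "", protein_seq = "") {
  n <- length(gene_id)
  df <- data.frame(
    genome_id = rep_len(as.character(genome_id), n),
    replicon_id = rep_len(as.character(replicon_id), n),
    gene_id = as.character(gene_id),
    start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(end, n)),
    strand = rep_len(as.character(strand), n),
    role = rep_len(as.character(role), n),
    rm_type = rep_len(as.character(rm_type), n),
    corrupted = rep_len(as.logical(corrupted), n),
    system_id = rep_len(as.character(system_id), n),
    product = rep_len(as.character(product), n),
    protein_seq = rep_len(as.character(protein_seq), n),
    stringsAsFactors = FALSE
  )
  df$role[!df$role %in% GENE_ROLES] <- "other"
  df$rm_type[!df$rm_type %in% RM_TYPES] <- "unknown"
  df
}

#' Construct a replicon table
#'
#' @param replicon_id,genome_id character vectors.
#' @param length replicon length in bp (>= 1).
#' @param topology `"circular"` or `"linear"`.
#' @return data.frame with one row per replicon.
#' @export
replicon_records <- function(replicon_id, genome_id, length,
                             topology = "linear") {
  n <- length(replicon_id)
  data.frame(
    replicon_id = as.character(replicon_id),
    genome_id = rep_len(as.character(genome_id), n),
    length = as.integer(rep_len(length, n)),
    topology = rep_len(as.character(topology), n),
    stringsAsFactors = FALSE
  )
}

#' Validate a cohort annotation against the data-model invariants
#'
#' Checks coordinate sanity (0 <= start < end <= replicon length), referential
#' integrity between genes and replicons, strand/role/type vocabularies, and
#' the presence of protein sequences for non-corrupted R-M role genes.
#'
#' @param genes gene-record data.frame (see [gene_records()]).
#' @param replicons replicon table (see [replicon_records()]).
#' @param require_proteins enforce protein sequences on non-corrupted R-M
#'   role genes (off by default: annotations legitimately arrive without
#'   sequences and then restrict what the pipeline can do).
#' @return invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_cohort <- function(genes, replicons, require_proteins = FALSE) {
  if (nrow(replicons)) {
    if (any(replicons$length < 1L)) stop("replicon length must be >= 1")
    if (!all(replicons$topology %in% c("circular", "linear")))
      stop("replicon topology must be 'circular' or 'linear'")
    if (anyDuplicated(replicons$replicon_id))
      stop("duplicated replicon_id in replicon table")
  }
  if (!nrow(genes)) return(invisible(TRUE))
  miss <- setdiff(genes$replicon_id, replicons$replicon_id)
  if (length(miss))
    stop("referential error: gene(s) reference unknown replicon(s): ",
         paste(head(miss, 5L), collapse = ", "))
  if (any(!is.finite(genes$start)) || any(!is.finite(genes$end)))
    stop("malformed coordinates: non-finite start/end")
  if (any(genes$start < 0L) || any(genes$start >= genes$end))
    stop("malformed coordinates: need 0 <= start < end")
  rl <- replicons$length[match(genes$replicon_id, replicons$replicon_id)]
  if (any(genes$end > rl))
    stop("malformed coordinates: gene end exceeds replicon length (gene ",
         genes$gene_id[which(genes$end > rl)[1L]], ")")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(genes$role %in% GENE_ROLES)) stop("unknown gene role")
  if (!all(genes$rm_type %in% RM_TYPES)) stop("unknown rm_type")
  if (require_proteins) {
    need <- !genes$corrupted & genes$role %in% RM_ROLES
    # arcs of one origin-spanning gene may carry the protein on one row only
    prot_by_gene <- tapply(nchar(genes$protein_seq), genes$gene_id, max)
    bad <- need & prot_by_gene[genes$gene_id] == 0L
    if (any(bad))
      stop("non-corrupted R-M gene without protein sequence: ",
           genes$gene_id[which(bad)[1L]])
  }
  invisible(TRUE)
}

gene_length_aa <- function(genes) nchar(genes$protein_seq)

#' Read an annotation file
#'
#' Two dialects are supported. `rebase_tsv` is the package's documented
#' tab-separated dialect: `#replicon` pragma lines
#' (`#replicon<TAB>replicon_id<TAB>genome_id<TAB>length<TAB>topology`)
#' followed by a header line and one row per gene with columns
#' `genome_id replicon_id gene_id start end strand role rm_type corrupted
#' system_id product protein_seq`; coordinates are already 0-based half-open.
#' `gff3` reads GFF3 (1-based inclusive, converted on input) via
#' \pkg{rtracklayer}; replicon lengths come from `##sequence-region` pragmas
#' and protein sequences from the optional `proteins` FASTA keyed by gene id.
#'
#' @param path file to read.
#' @param dialect `"rebase_tsv"` or `"gff3"`.
#' @param proteins optional named character vector of protein sequences
#'   (gff3 dialect only).
#' @return list with elements `genes` and `replicons`.
#' @export
read_annotation <- function(path, dialect = c("rebase_tsv", "gff3"),
                            proteins = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "rebase_tsv") read_rebase_tsv(path)
  else read_gff3_annotation(path, proteins)
}

read_rebase_tsv <- function(path) {
  lines <- readLines(path)
  rep_lines <- grep("^#replicon\t", lines, value = TRUE)
  replicons <- if (length(rep_lines)) {
    parts <- strsplit(rep_lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 5L))
      stop("parse error in #replicon pragma of ", path)
    replicon_records(
      replicon_id = vapply(parts, `[[`, "", 2L),
      genome_id   = vapply(parts, `[[`, "", 3L),
      length      = as.integer(vapply(parts, `[[`, "", 4L)),
      topology    = vapply(parts, `[[`, "", 5L)
    )
  } else replicon_records(character(), character(), integer())
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body))
    return(list(genes = gene_records(character(), character(), character(),
                                     integer(), integer()),
                replicons = replicons))
  con <- textConnection(body)
  on.exit(close(con))
  df <- read.delim(con, stringsAsFactors = FALSE,
                   colClasses = "character")
  needed <- c("genome_id", "replicon_id", "gene_id", "start", "end", "strand",
              "role", "rm_type", "corrupted", "system_id")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("rebase_tsv missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(df$product)) df$product <- ""
  if (is.null(df$protein_seq)) df$protein_seq <- ""
  st <- suppressWarnings(as.integer(df$start))
  en <- suppressWarnings(as.integer(df$end))
  bad <- which(is.na(st) | is.na(en))
  if (length(bad))
    stop("parse error: malformed coordinates at data line ", bad[1L],
         " of ", path)
  genes <- gene_records(df$genome_id, df$replicon_id, df$gene_id, st, en,
                        df$strand, df$role, df$rm_type,
                        toupper(df$corrupted) %in% c("TRUE", "T", "1"),
                        ifelse(df$system_id == "NA", NA_character_,
                               df$system_id),
                        df$product, df$protein_seq)
  validate_cohort(genes, replicons)
  list(genes = genes, replicons = replicons)
}

#' Write an annotation file
#'
#' Inverse of [read_annotation()]; round-trips losslessly for both dialects
#' (for `gff3`, protein sequences travel separately).
#'
#' @param genes,replicons as returned by [read_annotation()].
#' @param path output file.
#' @param dialect `"rebase_tsv"` or `"gff3"`.
#' @return invisibly `path`.
#' @export
write_annotation <- function(genes, replicons, path,
                             dialect = c("rebase_tsv", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "rebase_tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    if (nrow(replicons))
      writeLines(sprintf("#replicon\t%s\t%s\t%d\t%s", replicons$replicon_id,
                         replicons$genome_id, replicons$length,
                         replicons$topology), con)
    df <- genes
    df$corrupted <- ifelse(df$corrupted, "TRUE", "FALSE")
    df$system_id[is.na(df$system_id)] <- "NA"
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write_gff3_annotation(genes, replicons, path)
  }
  invisible(path)
}

read_gff3_annotation <- function(path, proteins = NULL) {
  # replicon lengths come from ##sequence-region pragmas, topology from the
  # package's #!topology pragma (GFF3 has no standard for it)
  raw <- readLines(path)
  sr <- raw[startsWith(raw, "##sequence-region")]
  sr_parts <- strsplit(trimws(sr), "\\s+")
  lens <- stats::setNames(
    vapply(sr_parts, function(p) as.integer(p[4L]), 0L),
    vapply(sr_parts, function(p) p[2L], ""))
  topo <- raw[startsWith(raw, "#!topology")]
  topo_parts <- strsplit(trimws(topo), "\\s+")
  circ_ids <- vapply(topo_parts, function(p) p[2L], "")[
    vapply(topo_parts, function(p) identical(p[3L], "circular"), TRUE)]
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  getc <- function(field, default) {
    if (!is.null(md[[field]])) as.character(md[[field]]) else
      rep(default, length(gr))
  }
  gid <- getc("ID", paste0("gene", seq_along(gr)))
  genes <- gene_records(
    genome_id = getc("genome_id", "genome"),
    replicon_id = as.character(GenomeInfoDb::seqnames(gr)),
    gene_id = gid,
    start = BiocGenerics::start(gr) - 1L,   # 1-based inclusive -> 0-based half-open
    end = BiocGenerics::end(gr),
    strand = ifelse(as.character(BiocGenerics::strand(gr)) == "-", "-", "+"),
    role = getc("role", "other"),
    rm_type = getc("rm_type", "unknown"),
    corrupted = toupper(getc("corrupted", "FALSE")) %in% c("TRUE", "T", "1"),
    system_id = {
      s <- getc("system_id", NA_character_); s[s == "NA"] <- NA; s
    },
    product = getc("product", ""),
    protein_seq = if (!is.null(proteins))
      ifelse(gid %in% names(proteins), unname(proteins[gid]), "") else ""
  )
  miss <- setdiff(unique(genes$replicon_id), names(lens))
  if (length(miss))
    stop("gff3 lacks ##sequence-region for replicon(s): ",
         paste(miss, collapse = ", "))
  replicons <- replicon_records(
    replicon_id = names(lens),
    genome_id = vapply(names(lens), function(r) {
      g <- genes$genome_id[genes$replicon_id == r]
      if (length(g)) g[1L] else "genome"
    }, ""),
    length = unname(lens),
    topology = ifelse(names(lens) %in% circ_ids, "circular", "linear")
  )
  validate_cohort(genes, replicons)
  list(genes = genes, replicons = replicons)
}

write_gff3_annotation <- function(genes, replicons, path) {
  si <- GenomeInfoDb::Seqinfo(
    seqnames = replicons$replicon_id,
    seqlengths = replicons$length,
    isCircular = replicons$topology == "circular"
  )
  gr <- GenomicRanges::GRanges(
    seqnames = factor(genes$replicon_id, levels = replicons$replicon_id),
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand,
    seqinfo = si
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "rmsep", type = "gene",
    ID = genes$gene_id, genome_id = genes$genome_id, role = genes$role,
    rm_type = genes$rm_type,
    corrupted = ifelse(genes$corrupted, "TRUE", "FALSE"),
    system_id = ifelse(is.na(genes$system_id), "NA", genes$system_id),
    product = genes$product
  )
  rtracklayer::export(gr, path, format = "gff3")
  # rtracklayer omits the pragmas; write them explicitly
  body <- readLines(path)
  body <- body[!startsWith(body, "##sequence-region")]
  pragmas <- c(sprintf("##sequence-region %s 1 %d", replicons$replicon_id,
                       replicons$length),
               sprintf("#!topology %s %s", replicons$replicon_id,
                       replicons$topology))
  writeLines(c(body[1L], pragmas, body[-1L]), path)
  invisible(path)
}

#' Read / write protein FASTA
#'
#' Thin wrappers over \pkg{Biostrings} returning plain named character
#' vectors, the currency used throughout the pipeline.
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_protein_fasta
#' @param seqs named character vector.
#' @export
write_protein_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' @rdname read_protein_fasta
#' @export
read_dna_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_protein_fasta
#' @export
write_dna_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

SOLITARY_CLASSES <- c("probably_truncated", "separated_system_member",
                      "corrupted_mtase_nearby", "no_paired_mtase",
                      "no_orthologs")

#' Summarize solitary-RE classifications and write report files
#'
#' Builds a per-type summary table (one row per R-M type plus a total row,
#' one column per classification class plus a row total) and writes it as
#' TSV and/or JSON. The two renderings contain identical numbers; the JSON
#' carries a `schema_version` field.
#'
#' @param classifications data.frame with columns `gene_id`, `genome_id`,
#'   `rm_type`, `class` (one of the five solitary classes).
#' @param path output path without extension; `.tsv` / `.json` are appended.
#'   `NULL` skips writing.
#' @param format character vector, subset of `c("tsv", "json")`.
#' @return the summary data.frame, invisibly when writing.
#' @export
write_report <- function(classifications, path = NULL,
                         format = c("tsv", "json")) {
  cls <- classifications
  if (nrow(cls) && !all(cls$class %in% SOLITARY_CLASSES))
    stop("unknown classification class")
  types <- c("I", "II", "III")
  tab <- matrix(0L, nrow = length(types) + 1L,
                ncol = length(SOLITARY_CLASSES) + 1L,
                dimnames = list(c(types, "total"),
                                c(SOLITARY_CLASSES, "total")))
  for (ty in types) {
    sub <- cls[cls$rm_type == ty, , drop = FALSE]
    for (cl in SOLITARY_CLASSES)
      tab[ty, cl] <- sum(sub$class == cl)
    tab[ty, "total"] <- nrow(sub)
  }
  tab["total", ] <- colSums(tab[types, , drop = FALSE])
  stopifnot(tab["total", "total"] == nrow(cls[cls$rm_type %in% types, ]))
  out <- data.frame(rm_type = rownames(tab), tab, row.names = NULL,
                    check.names = FALSE)
  if (!is.null(path)) {
    if ("tsv" %in% format)
      write.table(out, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    if ("json" %in% format)
      jsonlite::write_json(
        list(schema_version = "1.0", summary = out,
             classifications = cls[, c("gene_id", "genome_id", "rm_type",
                                       "class")]),
        paste0(path, ".json"), dataframe = "rows", auto_unbox = TRUE)
    return(invisible(out))
  }
  out
}
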