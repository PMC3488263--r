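# Deterministic synthetic genome cohorts with planted R-M scenarios and
# full ground-truth labels. The generator states a world, it is not tuned:
# amino-acid substitutions are uniform over the 19 alternatives (no rate
# matrix), intergenic sequence is i.i.d. uniform with stop-codon cassettes
# inserted so spurious ORFs stay below the scan's minimum length, and
# proteins are reverse-translated with a fixed codon table so the
# six-frame scan can re-find them.

DNA_BASES <- c("A", "C", "G", "T")

# one fixed codon per amino acid
CODON_TABLE <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
  P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT")

# 16 bp cassette with stop codons in all six frames
STOP_CASSETTE <- "TAGCTAGCTAGCTAGC"

reverse_translate <- function(protein) {
  paste0(paste0(CODON_TABLE[strsplit(protein, "")[[1L]]], collapse = ""),
         "TAA")
}

# random DNA with stop cassettes every ~106 bp (all six frames terminated)
random_dna_with_stops <- function(n) {
  v <- sample(DNA_BASES, n, replace = TRUE)
  cass <- strsplit(STOP_CASSETTE, "")[[1L]]
  if (n >= 17L)
    for (at in seq(1L, n - 16L, by = 106L)) v[at:(at + 15L)] <- cass
  paste0(v, collapse = "")
}

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Generate a protein family from a common root
#'
#' Each member is derived from the root by i.i.d. substitutions at the
#' given per-site fraction, uniform over the 19 alternative residues
#' (position 1 is kept as methionine so reverse-translated genes start with
#' ATG). With substitution-only evolution the expected pairwise identity of
#' two members is `(1 - d)^2 + d^2 / 19`. Optional indels delete or insert
#' short (1-3 aa) runs at rate `indel_rate` per site.
#'
#' @param root_length root protein length in aa (>= 50), ignored when
#'   `root` is supplied.
#' @param n_members number of members (>= 1).
#' @param divergence per-site substitution fraction `d` in `[0, 0.6]`.
#' @param seed optional integer; when given the caller's RNG state is
#'   preserved.
#' @param indel_rate per-site indel rate (default 0).
#' @param root optional root sequence to reuse.
#' @return list: `root` and `members` (named character vector).
#' @export
generate_family <- function(root_length, n_members, divergence, seed = NULL,
                            indel_rate = 0, root = NULL) {
  stopifnot(n_members >= 1L, divergence >= 0, divergence <= 0.6)
  if (is.null(root)) stopifnot(root_length >= 50L)
  with_local_seed(seed, {
    if (is.null(root))
      root <- paste0(c("M", sample(AA_ALPHABET, root_length - 1L,
                                   replace = TRUE)), collapse = "")
    rootv <- strsplit(root, "")[[1L]]
    members <- vapply(seq_len(n_members), function(i) {
      v <- rootv
      mut <- which(stats::runif(length(v)) < divergence)
      mut <- mut[mut > 1L]   # keep the start methionine
      for (p in mut)
        v[p] <- sample(setdiff(AA_ALPHABET, v[p]), 1L)
      if (indel_rate > 0) {
        n_ind <- stats::rpois(1L, indel_rate * length(v))
        for (k in seq_len(n_ind)) {
          w <- sample(1:3, 1L)
          if (stats::runif(1L) < 0.5 && length(v) > 60L + w) {
            at <- sample(2:(length(v) - w), 1L)
            v <- v[-(at:(at + w - 1L))]
          } else {
            at <- sample(2:length(v), 1L)
            v <- append(v, sample(AA_ALPHABET, w, replace = TRUE), after = at)
          }
        }
      }
      paste0(v, collapse = "")
    }, "")
    list(root = root,
         members = stats::setNames(members, paste0("m", seq_len(n_members))))
  })
}

#' Cohort specification for the synthetic generator
#'
#' Defaults state the standard test world: 20 genomes with one 150 kb
#' linear replicon each, 10\% family divergence, separated gene pairs 30 kb
#' apart, and the scenario mix used by the planted-truth acceptance check
#' (5 separated systems each backed by an ordinary orthologous system, 3
#' truncated REs, 3 corrupted-MTase cases, 2 lone REs, plus ordinary
#' complete systems and Type IV decoys).
#'
#' @param n_genomes number of genomes.
#' @param replicon_length bp length of each genome's single replicon.
#' @param topology `"linear"` or `"circular"`.
#' @param scenarios named integer vector of scenario counts.
#' @param divergence per-family substitution fraction.
#' @param indel_rate per-site indel rate inside families.
#' @param mge_fraction fraction of separated systems given a planted mobile
#'   element neighbor.
#' @param separation_bp RE-MTase gap planted for separated systems (> 4 kb).
#' @param re_length,mtase_length,s_length protein lengths in aa.
#' @param emit_sequences generate replicon nucleotide sequences (disable
#'   for fast annotation-only cohorts).
#' @param seed integer seed; generation is a pure function of (spec, seed).
#' @return list of class `rm_cohort_spec`.
#' @export
rm_cohort_spec <- function(n_genomes = 20L, replicon_length = 150000L,
                           topology = "linear",
                           scenarios = c(ordinary_complete = 6L,
                                         separated_with_ordinary_ortholog = 5L,
                                         separated_without_ortholog = 0L,
                                         truncated_re = 3L,
                                         corrupted_mtase_nearby = 3L,
                                         lone_re_no_mtase = 2L,
                                         methyl_directed_decoy = 2L),
                           divergence = 0.10, indel_rate = 0,
                           mge_fraction = 0.5, separation_bp = 30000L,
                           re_length = 300L, mtase_length = 350L,
                           s_length = 250L, emit_sequences = TRUE,
                           seed = 1L) {
  all_scen <- c("ordinary_complete", "separated_with_ordinary_ortholog",
                "separated_without_ortholog", "truncated_re",
                "corrupted_mtase_nearby", "lone_re_no_mtase",
                "methyl_directed_decoy")
  full <- stats::setNames(integer(length(all_scen)), all_scen)
  full[names(scenarios)] <- as.integer(scenarios)
  bad <- setdiff(names(scenarios), all_scen)
  if (length(bad)) stop("unknown scenario(s): ", paste(bad, collapse = ", "))
  if (any(full < 0L)) stop("scenario counts must be >= 0")
  stopifnot(divergence >= 0, divergence <= 0.6, n_genomes >= 1L,
            separation_bp > 0L)
  structure(list(n_genomes = as.integer(n_genomes),
                 replicon_length = as.integer(replicon_length),
                 topology = topology, scenarios = full,
                 divergence = divergence, indel_rate = indel_rate,
                 mge_fraction = mge_fraction,
                 separation_bp = as.integer(separation_bp),
                 re_length = as.integer(re_length),
                 mtase_length = as.integer(mtase_length),
                 s_length = as.integer(s_length),
                 emit_sequences = isTRUE(emit_sequences),
                 seed = as.integer(seed)),
            class = "rm_cohort_spec")
}

#' Generate a synthetic genome cohort with planted ground truth
#'
#' Returns annotations, replicon sequences, the MTase reference protein set
#' and truth labels naming each planted RE's correct classification and
#' each separated system's partner MTase. Deterministic: two calls with the
#' same spec produce identical cohorts.
#'
#' @param spec an [rm_cohort_spec()].
#' @return list of class `rm_cohort`: `genes`, `replicons`, `sequences`
#'   (named character vector, `NULL` when not emitted), `mtase_ref`,
#'   `truth` (list: `classes`, `partners`, `mge`), `spec`.
#' @export
generate_cohort <- function(spec = rm_cohort_spec()) {
  stopifnot(inherits(spec, "rm_cohort_spec"))
  with_local_seed(spec$seed, .generate_cohort_impl(spec))
}

.generate_cohort_impl <- function(spec) {
  n_g <- spec$n_genomes
  L <- spec$replicon_length
  genomes <- sprintf("g%02d", seq_len(n_g))
  replicon_of <- stats::setNames(paste0(genomes, "_chr"), genomes)
  cursor <- stats::setNames(rep(3000L, n_g), genomes)
  GAP <- 9000L

  genes <- list(); truth_cls <- list(); truth_part <- list()
  truth_mge <- list(); mtase_ref <- character()
  placed <- list()  # per replicon: list of (start, dna)
  counters <- new.env()
  counters$gene <- 0L; counters$sys <- 0L; counters$fam <- 0L
  counters$genome_rr <- 0L

  next_genome <- function() {
    counters$genome_rr <- counters$genome_rr %% n_g + 1L
    genomes[counters$genome_rr]
  }
  new_id <- function(prefix, counter) {
    v <- get(counter, counters) + 1L
    assign(counter, v, counters)
    sprintf("%s%03d", prefix, v)
  }
  allocate <- function(g, span) {
    pos <- cursor[[g]]
    if (pos + span > L - 2000L)
      stop("sizing error: scenarios do not fit on replicon of length ", L,
           " (genome ", g, ")")
    cursor[[g]] <<- pos + span + GAP
    pos
  }
  add_gene <- function(g, start, protein, role, rm_type, system_id,
                       corrupted = FALSE, dna = NULL, product = "",
                       gene_id = new_id("gene", "gene")) {
    if (is.null(dna)) dna <- reverse_translate(protein)
    end <- start + nchar(dna)
    genes[[length(genes) + 1L]] <<- gene_records(
      g, replicon_of[[g]], gene_id, start, end, "+", role, rm_type,
      corrupted, system_id, product,
      if (corrupted) "" else protein)
    placed[[replicon_of[[g]]]] <<-
      c(placed[[replicon_of[[g]]]], list(list(start = start, dna = dna)))
    gene_id
  }
  frameshift_dna <- function(protein) {
    # premature stop at ~45% of the coding sequence
    dna <- reverse_translate(protein)
    at <- (floor(nchar(protein) * 0.45)) * 3L + 1L
    paste0(substr(dna, 1L, at - 1L), "TAA",
           substr(dna, at + 3L, nchar(dna)))
  }
  fam <- function(role_len, n) generate_family(role_len, n, spec$divergence,
                                               indel_rate = spec$indel_rate)
  label <- function(gene_id, genome, rm_type, class) {
    truth_cls[[length(truth_cls) + 1L]] <<- data.frame(
      gene_id = gene_id, genome_id = genome, rm_type = rm_type,
      class = class, stringsAsFactors = FALSE)
  }
  add_mtase_ref <- function(root) {
    id <- new_id("MTref", "fam")
    mtase_ref[[id]] <<- root
    id
  }

  sc <- spec$scenarios
  mge_products <- c("IS481 family transposase", "phage integrase",
                    "insertion sequence IS3 element protein")
  n_sep <- sc[["separated_with_ordinary_ortholog"]]
  n_mge <- ceiling(spec$mge_fraction * n_sep)

  # --- ordinary complete systems (negative controls) ---
  for (i in seq_len(sc[["ordinary_complete"]])) {
    g <- next_genome()
    fre <- fam(spec$re_length, 1L); fmt <- fam(spec$mtase_length, 1L)
    add_mtase_ref(fmt$root)
    ty <- c("II", "I", "III")[(i - 1L) %% 3L + 1L]
    re_span <- nchar(fre$members[[1L]]) * 3L + 3L
    mt_span <- nchar(fmt$members[[1L]]) * 3L + 3L
    s_span <- if (ty == "I") spec$s_length * 3L + 3L else 0L
    pos <- allocate(g, re_span + 200L + mt_span +
                      if (ty == "I") 150L + s_span else 0L)
    sys <- new_id("sys", "sys")
    rid <- add_gene(g, pos, fre$members[[1L]], "RE", ty, sys)
    add_gene(g, pos + re_span + 200L, fmt$members[[1L]], "MTase", ty, sys)
    if (ty == "I") {
      fs <- fam(spec$s_length, 1L)
      add_gene(g, pos + re_span + 200L + mt_span + 150L, fs$members[[1L]],
               "S_subunit", ty, sys)
    }
    label(rid, g, ty, "not_solitary")
  }

  # --- separated systems with an ordinary orthologous system ---
  for (i in seq_len(n_sep)) {
    g1 <- next_genome(); g2 <- next_genome()
    if (g2 == g1) g2 <- next_genome()
    ty <- if (i <= 3L) "II" else "I"
    fre <- fam(spec$re_length, 2L); fmt <- fam(spec$mtase_length, 2L)
    add_mtase_ref(fmt$root)
    fs <- if (ty == "I") fam(spec$s_length, 2L) else NULL
    re_span <- nchar(fre$members[[1L]]) * 3L + 3L
    mt_span <- nchar(fmt$members[[1L]]) * 3L + 3L
    s_extra <- if (ty == "I") 150L + spec$s_length * 3L + 3L else 0L
    # genome 1: RE ... (separation_bp) ... MTase [+ S]
    pos <- allocate(g1, re_span + spec$separation_bp + mt_span + s_extra)
    re_id <- add_gene(g1, pos, fre$members[[1L]], "RE", ty,
                      new_id("sys", "sys"))
    mt_start <- pos + re_span + spec$separation_bp
    mt_sys <- new_id("sys", "sys")
    mt_id <- add_gene(g1, mt_start, fmt$members[[1L]], "MTase", ty, mt_sys)
    if (ty == "I")
      add_gene(g1, mt_start + mt_span + 150L, fs$members[[1L]],
               "S_subunit", ty, mt_sys)
    if (i <= n_mge) {
      mge_id <- add_gene(g1, pos + re_span + 3000L,
                         paste0(c("M", rep("A", 99L)), collapse = ""),
                         "other", "unknown", NA_character_,
                         dna = random_dna_with_stops(900L),
                         product = mge_products[(i - 1L) %% 3L + 1L])
      truth_mge[[length(truth_mge) + 1L]] <- data.frame(
        mge_gene_id = mge_id, anchor_re = re_id, stringsAsFactors = FALSE)
    }
    # genome 2: ordinary orthologous complete system
    pos2 <- allocate(g2, re_span + 200L + mt_span + s_extra)
    sys2 <- new_id("sys", "sys")
    rid2 <- add_gene(g2, pos2, fre$members[[2L]], "RE", ty, sys2)
    add_gene(g2, pos2 + re_span + 200L, fmt$members[[2L]], "MTase", ty, sys2)
    if (ty == "I")
      add_gene(g2, pos2 + re_span + 200L + mt_span + 150L, fs$members[[2L]],
               "S_subunit", ty, sys2)
    label(re_id, g1, ty, "separated_system_member")
    label(rid2, g2, ty, "not_solitary")
    truth_part[[length(truth_part) + 1L]] <- data.frame(
      re_gene_id = re_id, mtase_gene_id = mt_id, stringsAsFactors = FALSE)
  }

  # --- separated pair with no orthologous system in the cohort ---
  for (i in seq_len(sc[["separated_without_ortholog"]])) {
    g1 <- next_genome()
    fre <- fam(spec$re_length, 1L); fmt <- fam(spec$mtase_length, 1L)
    add_mtase_ref(fmt$root)
    re_span <- nchar(fre$members[[1L]]) * 3L + 3L
    mt_span <- nchar(fmt$members[[1L]]) * 3L + 3L
    pos <- allocate(g1, re_span + spec$separation_bp + mt_span)
    re_id <- add_gene(g1, pos, fre$members[[1L]], "RE", "II",
                      new_id("sys", "sys"))
    add_gene(g1, pos + re_span + spec$separation_bp, fmt$members[[1L]],
             "MTase", "II", new_id("sys", "sys"))
    # without a supporting orthologous system the method cannot pair these
    label(re_id, g1, "II", "no_orthologs")
  }

  # --- truncated RE fragments ---
  for (i in seq_len(sc[["truncated_re"]])) {
    g1 <- next_genome(); g2 <- next_genome()
    if (g2 == g1) g2 <- next_genome()
    ty <- c("II", "III")[(i - 1L) %% 2L + 1L]
    fre <- fam(spec$re_length, 2L); fmt <- fam(spec$mtase_length, 1L)
    add_mtase_ref(fmt$root)
    frag <- substr(fre$members[[1L]], 1L, floor(spec$re_length * 0.6))
    pos <- allocate(g1, nchar(frag) * 3L + 3L)
    frag_id <- add_gene(g1, pos, frag, "RE", ty, new_id("sys", "sys"))
    re_span <- nchar(fre$members[[2L]]) * 3L + 3L
    mt_span <- nchar(fmt$members[[1L]]) * 3L + 3L
    pos2 <- allocate(g2, re_span + 200L + mt_span)
    sys2 <- new_id("sys", "sys")
    rid2 <- add_gene(g2, pos2, fre$members[[2L]], "RE", ty, sys2)
    add_gene(g2, pos2 + re_span + 200L, fmt$members[[1L]], "MTase", ty, sys2)
    label(frag_id, g1, ty, "probably_truncated")
    label(rid2, g2, ty, "not_solitary")
  }

  # --- RE with a corrupted (pseudo) MTase nearby ---
  for (i in seq_len(sc[["corrupted_mtase_nearby"]])) {
    g1 <- next_genome(); g2 <- next_genome()
    if (g2 == g1) g2 <- next_genome()
    ty <- c("II", "I")[(i - 1L) %% 2L + 1L]
    fre <- fam(spec$re_length, 2L); fmt <- fam(spec$mtase_length, 2L)
    add_mtase_ref(fmt$root)
    re_span <- nchar(fre$members[[1L]]) * 3L + 3L
    mt_span <- nchar(fmt$members[[1L]]) * 3L + 3L
    pos <- allocate(g1, re_span + 200L + mt_span)
    sys1 <- new_id("sys", "sys")
    re_id <- add_gene(g1, pos, fre$members[[1L]], "RE", ty, sys1)
    add_gene(g1, pos + re_span + 200L, fmt$members[[1L]], "MTase", ty, sys1,
             corrupted = TRUE, dna = frameshift_dna(fmt$members[[1L]]))
    pos2 <- allocate(g2, re_span + 200L + mt_span)
    sys2 <- new_id("sys", "sys")
    rid2 <- add_gene(g2, pos2, fre$members[[2L]], "RE", ty, sys2)
    add_gene(g2, pos2 + re_span + 200L, fmt$members[[2L]], "MTase", ty, sys2)
    label(re_id, g1, ty, "corrupted_mtase_nearby")
    label(rid2, g2, ty, "not_solitary")
  }

  # --- lone REs: ortholog system exists, but no partner MTase transfers ---
  for (i in seq_len(sc[["lone_re_no_mtase"]])) {
    g1 <- next_genome(); g2 <- next_genome()
    if (g2 == g1) g2 <- next_genome()
    fre <- fam(spec$re_length, 2L); fmt <- fam(spec$mtase_length, 1L)
    add_mtase_ref(fmt$root)
    re_span <- nchar(fre$members[[1L]]) * 3L + 3L
    mt_span <- nchar(fmt$members[[1L]]) * 3L + 3L
    pos <- allocate(g1, re_span)
    re_id <- add_gene(g1, pos, fre$members[[1L]], "RE", "II",
                      new_id("sys", "sys"))
    pos2 <- allocate(g2, re_span + 200L + mt_span)
    sys2 <- new_id("sys", "sys")
    rid2 <- add_gene(g2, pos2, fre$members[[2L]], "RE", "II", sys2)
    add_gene(g2, pos2 + re_span + 200L, fmt$members[[1L]], "MTase", "II",
             sys2)
    label(re_id, g1, "II", "no_paired_mtase")
    label(rid2, g2, "II", "not_solitary")
  }

  # --- methyl-directed (Type IV) decoys ---
  for (i in seq_len(sc[["methyl_directed_decoy"]])) {
    g <- next_genome()
    fre <- fam(spec$re_length, 1L)
    pos <- allocate(g, nchar(fre$members[[1L]]) * 3L + 3L)
    did <- add_gene(g, pos, fre$members[[1L]], "RE", "IV",
                    new_id("sys", "sys"))
    label(did, g, "IV", "not_solitary")
  }

  genes_df <- if (length(genes)) do.call(rbind, genes) else
    gene_records(character(), character(), character(), integer(), integer())
  replicons <- replicon_records(unname(replicon_of), genomes, L,
                                spec$topology)
  sequences <- NULL
  if (spec$emit_sequences) {
    sequences <- stats::setNames(vector("character", n_g),
                                 unname(replicon_of))
    for (r in names(sequences)) {
      v <- sample(DNA_BASES, L, replace = TRUE)
      cass <- strsplit(STOP_CASSETTE, "")[[1L]]
      for (at in seq(1L, L - 16L, by = 106L))
        v[at:(at + 15L)] <- cass
      for (p in placed[[r]]) {
        d <- strsplit(p$dna, "")[[1L]]
        v[(p$start + 1L):(p$start + length(d))] <- d
      }
      sequences[[r]] <- paste0(v, collapse = "")
    }
  }
  validate_cohort(genes_df, replicons, require_proteins = TRUE)
  structure(list(
    genes = genes_df, replicons = replicons, sequences = sequences,
    mtase_ref = mtase_ref,
    truth = list(
      classes = if (length(truth_cls)) do.call(rbind, truth_cls) else
        data.frame(gene_id = character(), genome_id = character(),
                   rm_type = character(), class = character()),
      partners = if (length(truth_part)) do.call(rbind, truth_part) else
        data.frame(re_gene_id = character(), mtase_gene_id = character()),
      mge = if (length(truth_mge)) do.call(rbind, truth_mge) else
        data.frame(mge_gene_id = character(), anchor_re = character())),
    spec = spec), class = "rm_cohort")
}

#' Write / read a cohort as plain-text files
#'
#' Emits the same dialects the pipeline reads: `genes.tsv` (documented TSV
#' dialect with replicon pragmas), `replicons.fna`, `mtase_ref.faa` and
#' `truth.json`.
#'
#' @param cohort an `rm_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_annotation(cohort$genes, cohort$replicons,
                   file.path(dir, "genes.tsv"), "rebase_tsv")
  if (!is.null(cohort$sequences))
    write_dna_fasta(cohort$sequences, file.path(dir, "replicons.fna"))
  if (length(cohort$mtase_ref))
    write_protein_fasta(cohort$mtase_ref, file.path(dir, "mtase_ref.faa"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  ann <- read_annotation(file.path(dir, "genes.tsv"), "rebase_tsv")
  seq_path <- file.path(dir, "replicons.fna")
  ref_path <- file.path(dir, "mtase_ref.faa")
  truth_path <- file.path(dir, "truth.json")
  structure(list(
    genes = ann$genes, replicons = ann$replicons,
    sequences = if (file.exists(seq_path)) read_dna_fasta(seq_path),
    mtase_ref = if (file.exists(ref_path)) read_protein_fasta(ref_path)
      else character(),
    truth = if (file.exists(truth_path))
      jsonlite::read_json(truth_path, simplifyVector = TRUE),
    spec = NULL), class = "rm_cohort")
}
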