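test_that("gene_distance: linear, long-range, circular and cross-replicon", {
  reps <- toy_replicons(1000000L)
  g <- function(rep, s, e) gene_records("gA", rep, paste0("x", s), s, e)
  expect_equal(gene_distance(g("chrA", 10000L, 11000L),
                             g("chrA", 11500L, 12500L), reps), 500)
  expect_equal(gene_distance(g("chrA", 11500L, 12500L),
                             g("chrA", 10000L, 11000L), reps), 500)
  # overlap -> 0
  expect_equal(gene_distance(g("chrA", 10000L, 11000L),
                             g("chrA", 10500L, 12500L), reps), 0)
  # ~160 kb apart: separated under the 4 kb rule
  d160 <- gene_distance(g("chrA", 10000L, 11000L),
                        g("chrA", 171000L, 172000L), reps)
  expect_equal(d160, 160000)
  expect_gt(d160, rm_thresholds()$separated_bp)
  # different replicons of one genome -> Inf
  expect_identical(gene_distance(g("chrA", 1L, 10L),
                                 g("chrB", 1L, 10L), reps), Inf)
  # circular: adjacency across the origin
  repc <- replicon_records("chrC", "gA", 1000000L, topology = "circular")
  gc1 <- gene_records("gA", "chrC", "c1", 0L, 1000L)
  gc2 <- gene_records("gA", "chrC", "c2", 999500L, 1000000L)
  expect_equal(gene_distance(gc1, gc2, repc), 0)
  gc3 <- gene_records("gA", "chrC", "c3", 995000L, 996000L)
  expect_equal(gene_distance(gc1, gc3, repc), 4000)
  expect_error(gene_distance(
    gene_records("gA", "chrA", "a", 1L, 10L),
    gene_records("gB", "chrB", "b", 1L, 10L), reps), "different genomes")
})

sep_cohort <- function(seed = 71L, n_sep = 2L, n_ord = 1L) {
  generate_cohort(rm_cohort_spec(
    n_genomes = 8L, emit_sequences = FALSE,
    scenarios = c(ordinary_complete = n_ord,
                  separated_with_ordinary_ortholog = n_sep),
    seed = seed))
}

test_that("partner MTase transfer recovers the planted separated systems", {
  co <- sep_cohort()
  genes <- co$genes; reps <- co$replicons
  systems <- build_systems(genes)
  re_pairs <- bbh_all(genes, "RE")
  mt_pairs <- bbh_all(genes, "MTase")
  for (i in seq_len(nrow(co$truth$partners))) {
    re_id <- co$truth$partners$re_gene_id[i]
    re <- genes[genes$gene_id == re_id, , drop = FALSE]
    part <- find_partner_mtase(re, genes, reps, systems, re_pairs, mt_pairs)
    expect_equal(nrow(part), 1L)
    expect_equal(part$mtase_gene, co$truth$partners$mtase_gene_id[i])
    expect_equal(part$status, "separated")
    expect_gt(part$separation_bp, rm_thresholds()$separated_bp)
    expect_gte(part$n_support, 1L)   # provenance records the ordinary system
  }
})

test_that("removing the supporting ordinary system removes the call", {
  co <- sep_cohort(seed = 72L, n_sep = 1L, n_ord = 0L)
  genes <- co$genes
  re_id <- co$truth$partners$re_gene_id[1]
  support_genome <- genes$genome_id[
    genes$gene_id != re_id & genes$role == "RE"][1]
  pruned <- genes[genes$genome_id != support_genome, , drop = FALSE]
  systems <- build_systems(pruned)
  re_pairs <- bbh_all(pruned, "RE")
  mt_pairs <- bbh_all(pruned, "MTase")
  re <- pruned[pruned$gene_id == re_id, , drop = FALSE]
  part <- find_partner_mtase(re, pruned, co$replicons, systems,
                             re_pairs, mt_pairs)
  expect_equal(nrow(part), 0L)
})

test_that("two supporting genomes merge into one putative system", {
  # build a second supporting genome by cloning the ordinary one
  co <- sep_cohort(seed = 73L, n_sep = 1L, n_ord = 0L)
  genes <- co$genes
  systems <- build_systems(genes)
  ord_genome <- systems$genome_id[systems$completeness == "complete"][1]
  clone <- genes[genes$genome_id == ord_genome, , drop = FALSE]
  clone$genome_id <- "gZZ"
  clone$replicon_id <- "gZZ_chr"
  clone$gene_id <- paste0(clone$gene_id, "_z")
  clone$system_id <- paste0(clone$system_id, "_z")
  # perturb the clone slightly so BBH tie-breaking cannot collapse routes
  set.seed(731)
  clone$protein_seq <- vapply(clone$protein_seq, function(p)
    if (nzchar(p)) mutate_protein(p, 0.03) else p, "")
  reps <- rbind(co$replicons,
                replicon_records("gZZ_chr", "gZZ",
                                 co$replicons$length[1]))
  genes2 <- rbind(genes, clone)
  systems2 <- build_systems(genes2)
  re_pairs <- bbh_all(genes2, "RE")
  mt_pairs <- bbh_all(genes2, "MTase")
  re_id <- co$truth$partners$re_gene_id[1]
  re <- genes2[genes2$gene_id == re_id, , drop = FALSE]
  part <- find_partner_mtase(re, genes2, reps, systems2, re_pairs, mt_pairs)
  expect_equal(nrow(part), 1L)        # merged by partner MTase
  expect_equal(part$n_support, 2L)    # both supporting systems recorded
})

test_that("classification precedence is fixed and exclusive", {
  re <- gene_records("gA", "chr", "re1", 0L, 300L, role = "RE",
                     rm_type = "II", protein_seq = "MACDEFGHIK")
  scan0 <- structure(list(has_corrupted_mtase = FALSE,
                          has_noncorrupted_mtase = FALSE),
                     class = "rm_vicinity_scan")
  scan_cor <- structure(list(has_corrupted_mtase = TRUE,
                             has_noncorrupted_mtase = FALSE),
                        class = "rm_vicinity_scan")
  partners <- data.frame(mtase_gene = "mt9", status = "separated")
  no_partners <- partners[0, ]
  # truncated wins even with a separated partner
  expect_equal(classify_solitary(re, TRUE, TRUE, partners, scan0)$class,
               "probably_truncated")
  # no orthologs anywhere blocks the partner search
  expect_equal(classify_solitary(re, FALSE, FALSE, no_partners, scan0)$class,
               "no_orthologs")
  expect_equal(classify_solitary(re, FALSE, TRUE, partners, scan_cor)$class,
               "separated_system_member")
  expect_equal(classify_solitary(re, FALSE, TRUE, no_partners,
                                 scan_cor)$class, "corrupted_mtase_nearby")
  expect_equal(classify_solitary(re, FALSE, TRUE, no_partners, scan0)$class,
               "no_paired_mtase")
})

test_that("classification partitions the solitary set on random cohorts", {
  set.seed(74)
  for (k in 1:3) {
    co <- generate_cohort(rm_cohort_spec(
      n_genomes = 6L, emit_sequences = FALSE,
      scenarios = c(ordinary_complete = sample(0:2, 1),
                    separated_with_ordinary_ortholog = sample(1:2, 1),
                    truncated_re = sample(0:2, 1),
                    corrupted_mtase_nearby = sample(0:1, 1),
                    lone_re_no_mtase = sample(0:1, 1)),
      seed = 100L + k))
    res <- run_pipeline(co, seed = k, screen = FALSE)
    expect_equal(nrow(res$classifications), nrow(res$solitary))
    expect_false(any(duplicated(res$classifications$gene_id)))
    tab <- res$table1
    expect_equal(tab[tab$rm_type == "total", "total"],
                 sum(tab[tab$rm_type != "total",
                         setdiff(colnames(tab), c("rm_type", "total"))]))
  }
})

test_that("group summaries count systems, separated members and REs", {
  co <- sep_cohort(seed = 75L, n_sep = 2L)
  res <- run_pipeline(co, seed = 75L, screen = FALSE)
  t2 <- res$table2
  expect_equal(nrow(t2), 2L)          # one row per planted separated group
  expect_true(all(t2$n_separated == 1L))
  expect_true(all(t2$n_annotated == 1L))
  expect_true(all(t2$n_systems == 2L))
  expect_true(all(t2$n_solitary_re == 1L))

  # one RE paired with two MTase cassettes: separated count exceeds RE count.
  # A second cassette is planted in the solitary genome and a matching
  # second MTase inside the supporting complete system; both carry the same
  # mild divergence so the BBH routes stay distinct.
  set.seed(751)
  genes <- co$genes
  re_id <- co$truth$partners$re_gene_id[1]
  mt_id <- co$truth$partners$mtase_gene_id[1]
  mt <- genes[genes$gene_id == mt_id, , drop = FALSE]
  # cassette2 family sits at ~75% identity to cassette1 so each cassette's
  # BBH route is unambiguous
  variant_d <- mutate_protein(mt$protein_seq, 0.25)
  dup <- mt
  dup$gene_id <- paste0(mt_id, "_cassette2")
  dup$system_id <- paste0(mt$system_id, "_c2")
  dup$start <- mt$start + 60000L; dup$end <- mt$end + 60000L
  dup$protein_seq <- variant_d
  # the support MTase = the family member orthologous to cassette1
  others <- genes[genes$role == "MTase" & genes$genome_id != mt$genome_id, ,
                  drop = FALSE]
  ident <- vapply(others$protein_seq, function(p)
    align_pair(mt$protein_seq, p)$identity, 0)
  sup_mt <- others[which.max(ident), , drop = FALSE]
  sup2 <- sup_mt
  sup2$gene_id <- paste0(sup_mt$gene_id, "_b")
  sup2$system_id <- sup_mt$system_id   # same complete system
  sup2$start <- sup_mt$start + 50000L; sup2$end <- sup_mt$end + 50000L
  sup2$protein_seq <- mutate_protein(variant_d, 0.03)
  co2 <- co; co2$genes <- rbind(genes, dup, sup2)
  res2 <- run_pipeline(co2, seed = 75L, screen = FALSE)
  sep2 <- res2$putative_systems[res2$putative_systems$re_gene == re_id &
                                  res2$putative_systems$status ==
                                    "separated", ]
  expect_gte(nrow(sep2), 2L)
  t2b <- res2$table2
  row <- t2b[t2b$n_separated >= 2L, , drop = FALSE]
  expect_true(nrow(row) >= 1L)
  expect_gt(row$n_separated[1], row$n_solitary_re[1])
})
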