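# helpers to build tiny annotated worlds ------------------------------------

mini_world <- function(mt_offset = 200L, mt_corrupted = FALSE,
                       with_mtase = TRUE, L = 1e6L) {
  reps <- replicon_records("chr", "gA", L)
  re_prot <- generate_family(100, 1, 0, seed = 5)$members[[1]]
  mt_prot <- generate_family(120, 1, 0, seed = 6)$members[[1]]
  genes <- gene_records("gA", "chr", "re1", 10000L, 10303L, role = "RE",
                        rm_type = "II", system_id = "s1",
                        protein_seq = re_prot)
  if (with_mtase) {
    mstart <- 10303L + mt_offset
    genes <- rbind(genes, gene_records(
      "gA", "chr", "mt1", mstart, mstart + 363L, role = "MTase",
      rm_type = "II", system_id = "s1", corrupted = mt_corrupted,
      protein_seq = if (mt_corrupted) "" else mt_prot))
  }
  list(genes = genes, replicons = reps)
}

test_that("completeness follows the non-corrupted RE + MTase rule", {
  w <- mini_world()
  expect_equal(classify_completeness(w$genes), "complete")
  w2 <- mini_world(mt_corrupted = TRUE)
  expect_equal(classify_completeness(w2$genes), "incomplete")
  w3 <- mini_world(with_mtase = FALSE)
  expect_equal(classify_completeness(w3$genes), "incomplete")
  sys <- build_systems(w2$genes)
  expect_equal(sys$completeness, "incomplete")
  expect_equal(sys$n_re, 1L)
})

test_that("vicinity_interval handles clipping and circular wrap", {
  repL <- replicon_records("chr", "g", 1000000L)
  g <- gene_records("g", "chr", "x", 10000L, 11000L)
  expect_equal(unname(vicinity_interval(g, 4000L, repL)[1, ]),
               c(6000L, 15000L))
  g2 <- gene_records("g", "chr", "x", 1000L, 2000L)
  expect_equal(unname(vicinity_interval(g2, 4000L, repL)[1, ]),
               c(0L, 6000L))
  repC <- replicon_records("chr", "g", 100000L, topology = "circular")
  g3 <- gene_records("g", "chr", "x", 500L, 1500L)
  arcs <- vicinity_interval(g3, 4000L, repC)
  # modular arithmetic oracle: [96500,100000) + [0,5500)
  expect_equal(nrow(arcs), 2L)
  expect_equal(unname(arcs[1, ]), c(96500L, 100000L))
  expect_equal(unname(arcs[2, ]), c(0L, 5500L))
  g4 <- gene_records("g", "chr", "x", 1100000L - 99000L, 1002000L)
  expect_error(vicinity_interval(g4, 4000L, repC), "outside replicon")
})

test_that("six-frame ORF scan finds a planted gene and respects min length", {
  set.seed(31)
  prot <- generate_family(80, 1, 0, seed = 8)$members[[1]]
  dna <- rmsep:::reverse_translate(prot)
  junk1 <- rmsep:::random_dna_with_stops(500L)
  junk2 <- rmsep:::random_dna_with_stops(400L)
  orfs <- find_orfs(paste0(junk1, dna, junk2), min_bp = 150L)
  expect_true(any(vapply(orfs$protein, function(p)
    grepl(prot, p, fixed = TRUE), TRUE)))
  # reverse strand plant
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  orfs_rc <- find_orfs(paste0(junk1, rc, junk2), min_bp = 150L)
  hit <- vapply(orfs_rc$protein, function(p) grepl(prot, p, fixed = TRUE), TRUE)
  expect_true(any(hit))
  expect_true(all(orfs_rc$strand[hit] == "-"))
  # cassette-punctuated junk alone has no ORFs above the minimum
  expect_identical(nrow(find_orfs(rmsep:::random_dna_with_stops(6000L),
                                  min_bp = 150L)), 0L)
})

test_that("vicinity scan detects planted, corrupted and absent MTases", {
  co <- generate_cohort(rm_cohort_spec(
    n_genomes = 6L,
    scenarios = c(ordinary_complete = 1L,
                  separated_with_ordinary_ortholog = 1L,
                  corrupted_mtase_nearby = 1L, lone_re_no_mtase = 1L),
    seed = 17L))
  th <- rm_thresholds()
  truth <- co$truth$classes
  get_re <- function(cl) {
    id <- truth$gene_id[truth$class == cl][1]
    co$genes[co$genes$gene_id == id, , drop = FALSE]
  }
  scan_of <- function(g) scan_vicinity_for_mtases(
    g, co$genes, co$replicons, co$sequences[[g$replicon_id]],
    co$mtase_ref, th)

  # ordinary complete system: annotated + ORF-level MTase present
  ok_re <- get_re("not_solitary")
  sc_ok <- scan_of(ok_re)
  expect_true(sc_ok$has_noncorrupted_mtase)
  expect_true(any(sc_ok$candidate_orfs$full_length))
  expect_true(all(sc_ok$candidate_orfs$evalue < th$orf_evalue))
  expect_false(call_solitary(ok_re, sc_ok))

  # separated system: vicinity is clean at this stage -> solitary
  sep_re <- get_re("separated_system_member")
  sc_sep <- scan_of(sep_re)
  expect_false(sc_sep$has_noncorrupted_mtase)
  expect_true(call_solitary(sep_re, sc_sep))

  # frameshifted pseudo MTase nearby: corrupted yes, non-corrupted no
  cor_re <- get_re("corrupted_mtase_nearby")
  sc_cor <- scan_of(cor_re)
  expect_true(sc_cor$has_corrupted_mtase)
  expect_false(sc_cor$has_noncorrupted_mtase)
  expect_false(any(sc_cor$candidate_orfs$full_length))

  # annotation-only degradation
  sc_ann <- scan_vicinity_for_mtases(ok_re, co$genes, co$replicons, NULL,
                                     co$mtase_ref, th)
  expect_true(sc_ann$annotation_only)
  expect_true(sc_ann$has_noncorrupted_mtase)

  # corrupted RE genes are rejected
  fake <- ok_re; fake$corrupted <- TRUE
  expect_error(call_solitary(fake, sc_ok), "corrupted")
})

test_that("MTase at exactly the window distance is outside the vicinity", {
  th <- rm_thresholds()
  w <- mini_world(mt_offset = th$vicinity_bp)   # starts exactly 4000 bp past
  sc <- scan_vicinity_for_mtases(w$genes[1, ], w$genes, w$replicons,
                                 NULL, character(), th)
  expect_false(sc$has_noncorrupted_mtase)
  expect_true(call_solitary(w$genes[1, ], sc))
  # one bp closer -> overlap by 1 bp -> inside
  w2 <- mini_world(mt_offset = th$vicinity_bp - 1L)
  sc2 <- scan_vicinity_for_mtases(w2$genes[1, ], w2$genes, w2$replicons,
                                  NULL, character(), th)
  expect_true(sc2$has_noncorrupted_mtase)
})

test_that("solitary call is monotone in the window size", {
  # enlarging the window can only flip solitary -> not solitary
  for (off in c(1000L, 3999L, 4000L, 8000L, 20000L)) {
    w <- mini_world(mt_offset = off)
    res <- vapply(c(2000L, 4000L, 10000L, 30000L), function(win) {
      th <- rm_thresholds(vicinity_bp = win)
      call_solitary(w$genes[1, ],
                    scan_vicinity_for_mtases(w$genes[1, ], w$genes,
                                             w$replicons, NULL,
                                             character(), th))
    }, TRUE)
    expect_true(all(diff(as.integer(res)) <= 0))
  }
})
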