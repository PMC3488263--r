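---
title: "Detecting solitary REs and separated R-M systems with rmsep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting solitary REs and separated R-M systems with rmsep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Restriction-modification (R-M) systems pair a restriction endonuclease (RE),
which cleaves unmethylated recognition sites, with a DNA methyltransferase
(MTase) that methylates the same sites and thereby protects the host
chromosome. In almost all annotated cases the two genes are adjacent. A
*solitary* RE — an intact RE gene with no intact MTase gene nearby — is
therefore a puzzle: a Type II RE expressed without its MTase should be toxic.

`rmsep` implements a comparative-genomics pipeline that takes per-genome
annotations of R-M-related genes (plus, optionally, replicon nucleotide
sequences and protein sequences) and classifies every solitary RE into one
of five mutually exclusive classes:

1. **probably_truncated** — likely a fragment of a full-length RE gene;
2. **separated_system_member** — a partner MTase exists in the same genome
   more than 4 kb away (or on another replicon), supported by an orthologous
   complete system elsewhere;
3. **corrupted_mtase_nearby** — a pseudo (frameshifted / prematurely
   stopped) MTase sits within the 4 kb vicinity;
4. **no_paired_mtase** — orthologs exist but no partner MTase could be
   transferred;
5. **no_orthologs** — the RE has no sufficiently similar relative in any
   other genome, so the method cannot run.

Because the classes are assigned in that fixed precedence order, per-class
counts always sum to the number of solitary REs — the same additive
structure as the summary tables the procedure is designed to produce.

## The procedure, stage by stage

**Completeness.** Genes sharing a `system_id` form one R-M system. A system
is *complete* iff it contains at least one non-corrupted RE and one
non-corrupted MTase gene. How multi-MTase systems are grouped is taken from
the input annotation; the pipeline does not re-derive system membership.

**Vicinity scan (4 kb).** For every intact RE of Types I-III in an
incomplete system, the window 4 kb upstream and downstream of the gene is
scanned. Annotated MTase genes overlapping the window by at least one base
pair count; a gene starting exactly 4000 bp beyond the RE is outside. When
the replicon sequence is available, all six-frame stop-to-stop ORFs of at
least 150 bp (50 aa; the shortest MTase domains exceed this) are translated
and searched against a user-supplied MTase reference set at `E < 0.01`. An
unannotated ORF is accepted as a *full-length* MTase only when its best hit
covers more than 80% of the reference protein — an operational stand-in for
"full-length" that frameshift fragments (which split into two sub-50%
pieces) cannot pass. Without a sequence the scan degrades to
annotation-only and says so. An RE is *solitary* iff the scan finds no
non-corrupted MTase.

**Truncation filter.** The solitary RE is compared with REs of complete
systems. Candidates must be significant hits (`E < 0.01`) with more than
20% alignment identity; the RE is flagged *probably truncated* when it is
shorter by 20% or more than at least one such homolog
(`len <= 0.8 * len(homolog)`, boundary inclusive — "20% or more" read
literally). The significance gate is not spelled out in the published rule
but is implicit in calling a hit a homolog: with local alignment, unrelated
proteins almost always exceed 20% identity over some short span, so the
identity condition alone would flag everything.

**Orthology.** Best bidirectional hits between genomes, computed per role
and per R-M type (cross-type comparisons are disallowed; published ortholog
groups are type-homogeneous). An RE pair qualifies at more than 40%
identity over more than 80% of the length of the longer sequence; MTases at
more than 50% over 80%. The published MTase rule says "over 80% of length"
without naming the denominator; the longer sequence is used for both roles
for symmetry. All comparisons are strict inequalities (the rules are
written as ">"). Ortholog groups are single-linkage connected components of
the pair graph; proteins with no pair are excluded.

**Partner-MTase transfer.** For each ortholog RE′ of a solitary RE that
belongs to a *complete* system with MTase M′, the BBH ortholog M of M′ in
the solitary RE's genome is looked up. Every non-corrupted, same-type M
yields a putative R-M system (RE, M); duplicate partners found through
several supporting genomes are merged with pooled provenance. The putative
system is *separated* when the edge-to-edge RE-M distance exceeds 4 kb or
the genes lie on different replicons of the genome (a plasmid-borne partner
is maximally separated). Distances are edge-to-edge so that "within the
4 kb vicinity" and "more than 4 kb separated" are exact complements; on
circular replicons the shorter arc counts. For Type I partners, S-subunit
genes within 4 kb of M are reported as cassette members, and one RE may
legitimately pair with several MTase cassettes, in which case a group's
separated-system count exceeds its solitary-RE count.

**Methyl-directed screen.** Solitary REs are compared with Type IIM/IV
(methyl-directed) REs at `E < 0.001`, clustered by single linkage at more
than 40% identity over 60% of the length of *each* sequence, and mixed
clusters are aligned (progressive profile-profile alignment over an NJ
guide tree), given an NJ tree from p-distances, and bootstrapped by column
resampling. The screen *reports* mixed clusters and tree placements; it
never reclassifies a solitary RE as methyl-directed — sequence similarity
alone cannot establish that.

**Neighborhood scan (20 kb).** Around both genes of every separated system,
annotated products matching editable keyword classes (insertion sequences,
transposases, integrases, phage-related proteins) are collected, and the
fraction of systems with at least one hit is reported. Mobile elements near
separated genes support rearrangement-based origin scenarios.

## Parameters

All numeric parameters live in one `rm_thresholds()` object:

| field | default | meaning |
|---|---|---|
| `vicinity_bp` | 4000 | MTase scan window around an RE gene (bp) |
| `separated_bp` | 4000 | separation rule: distance must exceed this (bp) |
| `neighborhood_bp` | 20000 | mobile-element scan window (bp) |
| `orf_evalue` | 0.01 | vicinity ORF vs MTase reference cutoff |
| `typeiv_evalue` | 0.001 | methyl-directed screen cutoff |
| `re_ortho_identity` / `_coverage` | 0.40 / 0.80 | RE BBH thresholds |
| `mtase_ortho_identity` / `_coverage` | 0.50 / 0.80 | MTase BBH thresholds |
| `trunc_homolog_identity` | 0.20 | homolog identity floor (strict) |
| `trunc_length_fraction` | 0.80 | flagged when `len <= 0.8 * len(homolog)` |
| `trunc_evalue` | 0.01 | homolog significance gate |
| `cluster_identity` / `_coverage` | 0.40 / 0.60 | screen clustering (each sequence) |
| `bootstrap_reps` | 200 | bootstrap replicates |
| `min_orf_bp` | 150 | six-frame scan minimum ORF length |
| `orf_ref_coverage` | 0.80 | ORF counts as full-length MTase above this |

## Numerical and algorithmic choices

*Alignment.* Pairwise comparison is local alignment with BLOSUM62 and
affine gaps (open 11, extend 1), approximating the BLASTp defaults the
published procedure relied on; the engine is `Biostrings::pairwiseAlignment`
behind the module's own interface. Identity is identical residue pairs over
aligned residue-pair columns (gap columns excluded); the alternative
convention — identical pairs over the full length of the longer sequence —
is stored alongside (`identity_over_longer`) so the choice is auditable.
E-values use the Karlin-Altschul form `E = K·m·n·exp(-λS)` with the
standard gapped BLOSUM62 11/1 parameters (λ = 0.267, K = 0.041); this is an
approximation to BLAST, not a bit-exact clone, and the hit tables accept
external tabular search results in the same shape. Identity of an optimal
local alignment is not unique when several tracebacks share the optimal
score; the test suite therefore certifies the score against an independent
DP oracle and recomputes identity from the reported aligned strings.

*Ties.* Best hits order by score, then identity, then lexicographic subject
id; NJ Q-matrix ties break at the smallest index pair. Runs are fully
deterministic given inputs and seed, and two identically-seeded runs
produce byte-identical result bundles.

*NJ degeneracies.* Taxa at pairwise distance zero are merged before
agglomeration and re-attached as zero-length pendants; with fewer than
three distinct taxa the tree degenerates to a star of zero-length branches
with no internal edges (bootstrap supports are then vacuous). Negative NJ
branch lengths are clamped to zero.

*Coordinates.* Intervals are 0-based half-open internally; GFF3 I/O
converts from 1-based inclusive. Origin-spanning genes on circular
replicons are stored as two arcs under one gene id, and all distance
operations use circular arc arithmetic. Strand never affects distances.

## The synthetic cohort generator

Real inputs for this analysis are a versioned external database snapshot
plus a thousand genome assemblies — not reproducible at desk scale. The
generator (`rm_cohort_spec()` / `generate_cohort()`) instead *states* a
world with planted ground truth: by default 20 genomes with one 150 kb
linear replicon each, families diverged at 10% per-site amino-acid
substitution (uniform over the 19 alternatives — deliberately not a
biological rate matrix; it is sufficient to exercise the identity
thresholds), separated gene pairs 30 kb apart, ordinary pairs 200 bp apart,
corrupted MTases with a premature stop at 45% of the coding sequence, and a
scenario mix of 5 separated systems (each backed by an ordinary orthologous
system in another genome), 3 truncated REs (60% of parent length), 3
corrupted-MTase cases, 2 lone REs, 6 ordinary complete systems and 2
Type IV decoys. Proteins are reverse-translated with a fixed codon table so
the six-frame scan can re-find them; intergenic sequence is i.i.d. uniform
punctuated every ~106 bp by a 16 bp cassette containing stop codons in all
six frames, which caps spurious ORFs below the scan's minimum length.
Generation is a pure function of (spec, seed).

What a green planted-truth test establishes: the plumbing — scanning,
thresholds, orthology transfer, precedence — reproduces known labels under
clean geometry and moderate divergence. What it does not establish:
performance on real genomes with mis-annotated boundaries, mosaic proteins,
horizontal transfer at awkward divergences, or families straddling the
identity thresholds; the generator plants none of these.

The truth label for a separated pair *without* any orthologous supporting
system is `no_orthologs`: the method is provenance-dependent by
construction, and removing the supporting ordinary system removes the
separated call (this is tested).

## Known limitations

- E-values are approximate; absolute cutoffs near the 0.01/0.001 boundaries
  can differ from NCBI BLAST on the same pair.
- The ORF scan is start-codon-agnostic and cannot model frameshift-aware
  alignment; a frameshifted but unannotated MTase appears as two fragments
  and is only recognized via the annotation's `corrupted` flag.
- Orthology is similarity-only (no synteny, no tree reconciliation); very
  recent paralogs can swap BBH partners.
- The screen makes no functional claims: mixed clusters are reported, not
  interpreted.
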