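# rmsep

Comparative-genomics detection of **solitary restriction endonucleases**
and **separated restriction–modification (R-M) systems** in annotated
prokaryotic genomes.

## The problem

An R-M system pairs a restriction endonuclease (RE), which cleaves
unmethylated recognition sites, with a DNA methyltransferase (MTase) that
protects the host chromosome by methylating the same sites. The two genes
are almost always adjacent — yet genome annotations contain hundreds of
intact RE genes with no intact MTase nearby. A Type II RE expressed without
its MTase should kill the cell, so each such *solitary* RE demands an
explanation: is it a gene fragment, is its MTase a mis-annotated
pseudogene, or does a functional partner sit elsewhere in the genome as a
**separated R-M system**?

`rmsep` answers this per RE with a fixed-precedence, mutually exclusive
classification:

| class | meaning |
|---|---|
| `probably_truncated` | shorter by ≥20% than a significant >20%-identity homolog from a complete system |
| `separated_system_member` | a partner MTase >4 kb away (or on another replicon), transferred through an orthologous complete system |
| `corrupted_mtase_nearby` | a pseudo MTase within the 4 kb vicinity |
| `no_paired_mtase` | orthologs exist, but no partner MTase transfers |
| `no_orthologs` | no sufficiently similar RE in any other genome |

## Method core

* **Vicinity rule** — an RE is solitary iff no non-corrupted MTase gene or
  full-length MTase-like ORF (six-frame scan, `E < 0.01` vs a reference
  set) lies within 4 kb of the gene.
* **Orthology** — best bidirectional hits, per role and R-M type, at
  identity > 40% over > 80% of the longer sequence for REs and > 50% / 80%
  for MTases (strict inequalities throughout); single-linkage ortholog
  groups.
* **Partner transfer** — for each ortholog RE′ in a *complete* system with
  MTase M′, the BBH ortholog M of M′ in the solitary genome becomes a
  putative partner; the pair is *separated* when the edge-to-edge distance
  exceeds 4 kb (different replicons ⇒ separated).
* **Methyl-directed screen** — solitary REs vs Type IIM/IV REs at
  `E < 0.001`, single-linkage clusters at > 40% identity over 60% of each
  sequence, NJ trees with column-resampling bootstrap for mixed clusters.
* **Neighborhood scan** — mobile-genetic-element annotations within 20 kb
  of both genes of every separated system.

Alignment is local Smith–Waterman-style (BLOSUM62, affine gaps 11/1) with
Karlin–Altschul E-values — a documented approximation of BLASTp defaults.

Everything is exercised on synthetic genome cohorts with planted ground
truth (`generate_cohort()`), so no external databases are needed.

## Worked example

```r
library(rmsep)

co  <- generate_cohort(rm_cohort_spec(seed = 7))   # 20 genomes, planted truth
res <- run_pipeline(co, seed = 7)
res$table1
#>   rm_type probably_truncated separated_system_member corrupted_mtase_nearby
#> 1       I                  0                       2                      1
#> 2      II                  2                       3                      2
#> 3     III                  1                       0                      0
#> 4   total                  3                       5                      3
#>   no_paired_mtase no_orthologs total
#> 1               0            0     3
#> 2               2            0     9
#> 3               0            0     1
#> 4               2            0    13
```

The cohort plants 13 solitary REs (5 separated, 3 truncated, 3 with a
corrupted MTase nearby, 2 lone); every class count above matches the
planted labels, and the per-type rows sum to the totals — the
classification is a partition. Recovery is exact:

```r
evaluate_against_truth(res$classifications, co$truth)
#>                     class n_truth n_pred tp precision recall
#> 1      probably_truncated       3      3  3         1      1
#> 2 separated_system_member       5      5  5         1      1
#> 3  corrupted_mtase_nearby       3      3  3         1      1
#> 4         no_paired_mtase       2      2  2         1      1
#> 5            no_orthologs       0      0  0         1      1

head(res$putative_systems[, c("re_gene", "mtase_gene", "separation_bp", "status")], 2)
#>   re_gene mtase_gene separation_bp    status
#> 1 gene015    gene016         30000 separated
#> 2 gene020    gene021         30000 separated

res$mge$enrichment   # 3 of 5 separated systems have a mobile element within 20 kb
#> $n_systems [1] 5   $n_with_mge [1] 3   $fraction [1] 0.6
```

`res$table2` summarizes each ortholog group containing separated systems
(systems, annotated systems, separated members, solitary REs per group).

## Command line

```sh
inst/cli/rmsep simulate --out cohort/ --seed 3 --genomes 20
inst/cli/rmsep run --cohort cohort/ --out results/ --seed 3
inst/cli/rmsep report --bundle results/
```

Exit codes: 0 ok, 1 validation error, 2 runtime error.

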