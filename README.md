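# neovax

Neoepitope prioritization and multi-epitope DNA vaccine insert design.

`neovax` is an R package for the in-silico stage of personalized cancer
vaccine design. Starting from protein-level somatic variant calls (with
per-caller support), transcript expression and a tumor purity estimate,
it:

1. **extracts neoepitope windows** — tumor-specific protein sequences are
   built by applying germline then somatic substitutions; a window of 14
   flanking residues on each side of the mutation is cut (a 29mer when
   complete, mutant at position 15), clipped windows shorter than 15
   residues are discarded, and full windows are trimmed to the final
   27mer with the mutant at position 14;
2. **scores candidates on four probability factors** and ranks by their
   product:
   - *somatic*: weighted caller-consensus fraction,
   - *clonal*: purity-corrected cancer cell fraction,
     CCF = min(2·VAF/purity, 1) under a diploid copy-neutral model,
     times the somatic probability,
   - *MHC ligand*: best predictor %rank over all 8–11mers (class I) and
     15mers (class II) across alleles, logistic-calibrated
     (1/(1+e^{k(r−r₀)}), r₀ = 2, k = 2) and weighted by a saturating
     expression factor e/(e+E₅₀), E₅₀ = 10 RPKM,
   - *immunogenicity*: I = 1 − e^{−d/τ} from the summed Euclidean
     distance d between mutant and wild-type residues in a 5-D
     physicochemical (Atchley) space;
3. **selects the vaccine panel** (default 13) from the top of the ranked
   list under four exclusion criteria: not expressed; no predicted
   ligand of either MHC class; same source mutation as a previous pick;
   both best ligands identical to a previous pick. An alternative mode
   ranks by best class II 15mer %rank with a strict >20 RPKM filter
   (default panel 5);
4. **designs the DNA insert**: epitopes are reverse-translated by
   weighted codon sampling, concatenated with diverse synonymous "GGS"
   linkers, framed by Kozak/start/stop and restriction sites; a cohort
   of 10,000 such constructs is screened for repeats, TATA boxes,
   premature poly-A signals and internal sites, thresholded dynamically
   on CAI and GC content (top 1% survives), and the survivor with the
   highest RNA minimum free energy (least secondary structure) becomes
   the final insert.

A synthetic-data module simulates proteomes, variant tables with caller
support, VAF distributions under a set purity, and expression spanning
the 20-RPKM cutoff, so the whole chain runs and is tested without any
sequencing data. Tumor-study utilities (caliper volume
V = (π/6)(d₁·d₂)^{3/2} and growth-curve AUC) round out the toolkit.

## Worked example

```r
library(neovax)

ds     <- simulate_dataset(sim_config(seed = 42))
cand   <- extract_candidates(ds$proteome, ds$variants, ds$expression)
scored <- score_candidates(cand, ds$purity,
                           alleles = list(mhc1 = c("H2-Kb", "H2-Db"),
                                          mhc2 = "H2-IAb"),
                           predictor = mock_predictor())
sel    <- select_panel(rank_b16f10(scored), selection_config("b16f10"))
head(sel$panel[, c("id", "expression_rpkm", "clonal_p", "mhc_p",
                   "immunogenicity_p", "composite")], 5)
#>                 id expression_rpkm clonal_p mhc_p immunogenicity_p composite
#> 57 SYNP0005_261_WN           372.7    1.000 0.943            0.768     0.724
#> 28 SYNP0038_112_AT            40.7    0.975 0.769            0.848     0.636
#> 3  SYNP0020_266_EM            30.3    1.000 0.719            0.796     0.572
#> 42 SYNP0010_319_FN            33.4    1.000 0.748            0.720     0.539
#> 5  SYNP0008_134_DG            31.4    0.688 0.735            0.978     0.495
```

Each row is a retained neoepitope: `clonal_p` near 1 marks variants whose
purity-corrected VAF implies presence in essentially all tumor cells,
`mhc_p` combines predicted presentation with expression, and `composite`
(the product of the four factors) drives the ranking. The audit in
`sel$audit` records, for every examined candidate, either "selected" or
the first exclusion criterion it failed.

Designing the insert for the selected panel (scaled-down cohort for the
example; the default is 10,000):

```r
d <- design_insert(sel$panel$sequence, design_config(cohort_size = 2000),
                   seed = 1)
d$report[c("n_generated", "n_survivors", "eliminated_percent",
           "final_cai", "final_gc", "final_mfe")]
#> $n_generated        2000
#> $n_survivors        20
#> $eliminated_percent 99
#> $final_cai          0.818
#> $final_gc           0.499
#> $final_mfe          -1117
```

99% of the cohort is eliminated by the dynamic CAI/GC thresholds; among
the 20 folded survivors the selected ~1.2-kb insert has a high codon
adaptation index, balanced GC, and the least stable predicted secondary
structure. `write_construct()` emits the insert FASTA plus a feature
table (Kozak, start, each epitope, each linker, sites, stop) with
1-based inclusive coordinates.

```r
tumor_volume(6.5, 5.0)
#> [1] 97.0116   # mm^3 from two orthogonal caliper diameters
```

A thin command-line surface over the same functions lives at
`inst/cli/neovax.R` (subcommands `simulate`, `score`, `select`, `design`,
`volume`).

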