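---
title: "Methods: neoepitope prioritization and DNA insert design in neovax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neoepitope prioritization and DNA insert design in neovax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neovax)
```

# Scope

`neovax` implements the computational chain of a personalized DNA cancer
vaccine design: protein-level somatic variants are turned into candidate
neoepitope peptides, scored on four probability factors, filtered into a
vaccine panel under redundancy rules, and finally encoded as a
codon-optimized multi-epitope DNA insert. Raw sequencing analysis (read
alignment, variant calling, purity estimation, expression quantification)
is upstream of this package: its outputs — protein-level variant tables
with per-caller support, RPKM expression values, and a tumor purity — are
the package's inputs. A synthetic-data module generates inputs with the
same statistical structure so that every stage is testable end to end.

# Neoepitope window extraction

For each somatic missense variant, germline missense substitutions are
first applied to the reference protein, then the somatic substitution,
giving the tumor-specific sequence the window is cut from. Proteins
carrying germline frameshift or splice variants are rejected outright,
since their downstream protein sequence is not representable as a
substitution; somatic frameshift/splice variants are likewise recorded as
discarded rather than forced into a substitution model. A variant whose
annotated reference residue disagrees with the protein is discarded as an
annotation mismatch, never silently corrected.

The extraction window spans 14 residues of flank on each side of the
mutated position — a 29mer when both flanks are complete, with the mutant
residue at position 15. Windows clipped by a protein end are kept if at
least 15 residues long and discarded otherwise. Full 29mers are then
trimmed by one terminal residue on each side, yielding the final 27mer
with the mutant at position 14. Clipped windows (shorter than 29) pass
through the truncation step unchanged: the terminal trimming is defined
for full windows only, and trimming already-short windows would only lose
flank information. The matched wild-type peptide is cut from the
germline-applied (pre-somatic) protein at identical coordinates, so the
mutant/wild-type pair differs at exactly the mutant index.

# The four-factor score

Candidates are ranked by the product of four probabilities; each factor
has a documented, configurable functional form because the corresponding
production scores are not publicly specified. The package's forms are
deliberately simple, monotone stand-ins:

* **Somatic probability** — the weighted consensus fraction of the
  configured somatic callers supporting the variant (default: equal
  weights over `lofreq`, `mutect2`, `strelka`, `snvsniffer`; 2 of 4
  callers gives 0.5).
* **Clonal probability** — the purity-corrected cancer cell fraction
  times the somatic probability. Under a diploid, copy-neutral model, a
  heterozygous variant carried by all cancer cells of a sample with
  purity $p$ has expected VAF $p/2$, so
  $\mathrm{CCF} = \min(2 \cdot \mathrm{VAF} / p,\, 1)$. Copy-number
  variation is out of scope: no copy-number model is part of the input
  contract, and the diploid form is exact for the synthetic data.
* **MHC ligand probability** — every overlapping oligomer (sizes 8–11
  for class I, 15 for class II) is scored against every allele of the
  class by the configured predictor (lower %rank = stronger). The best
  rank $r^*$ per class is calibrated with a logistic map
  $p_\mathrm{raw} = 1/(1 + e^{k (r^* - r_0)})$ with midpoint $r_0 = 2$
  %rank and slope $k = 2$, then multiplied by a saturating expression
  factor $e/(e + E_{50})$ with $E_{50} = 10$ RPKM. The midpoint sits at
  the conventional class II binder cutoff, and $E_{50}$ places
  half-weight at a moderate expression level; all three are `scoring_params()`
  arguments. The combined ligand probability is the maximum of the two
  class probabilities — a candidate presentable on either class is a
  target, matching the selection rule that accepts either ligand class.
* **Immunogenicity probability** — from the physicochemical property
  distance $d$ between the mutant and wild-type peptide: the summed
  Euclidean distance of aligned residue pairs in a five-dimensional
  property space (the Atchley factor representation by default; any
  20×5 table can be supplied). The distance maps to a probability with
  $I = 1 - e^{-d/\tau}$, $\tau = 2$: conservative substitutions score
  near zero, drastic ones approach one, and $I$ is strictly increasing
  in $d$ with $I(0) = 0$.

All rank ties break leftmost (lowest offset), then by lexicographic
allele name; ranked lists tie-break by candidate id, so every ordering
is deterministic.

An alternative ranking mode reproduces the simpler class II workflow:
candidates with expression **strictly** above 20 RPKM are ranked
ascending by the best %rank among their overlapping 15mers against a
single class II allele, the representative 15mer being the minimizer.

# Panel selection

Selection walks the prioritized list from the top, skipping candidates
that violate any of four exclusion criteria, until the panel (default 13;
5 in the class II rank mode) is full:

1. not expressed — RPKM ≤ 0. This is deliberately distinct from the
   20-RPKM ranking filter of the class II mode, which the composite-score
   mode does not repeat;
2. no predicted ligand of either class — best class I %rank above 0.5
   and best class II %rank above 2.0 (the conventional strong/weak binder
   cutoffs; both configurable, as no ligand-call threshold is part of the
   published procedure);
3. same source mutation as an already-selected candidate;
4. best class I **and** best class II ligand both sequence-identical to
   those of an already-selected candidate (the criterion joins the two
   classes with "and", so a single-class match is allowed).

Every examined candidate is either selected or annotated with its first
failing criterion, so the audit trail is exhaustive and the panel is
always a subsequence of the ranked order.

# DNA insert optimization

The panel peptides are encoded as one insert:
`5' site – Kozak (GCCACC) – ATG – epitope – linker – … – epitope – stop – 3' site`,
with NheI/XhoI flanks by default. Epitopes are reverse-translated by
weighted sampling from an organism-specific codon-usage table; linkers
encode a glycine/serine spacer ("GGS" by default) and are drawn per
junction from a small set of synonymous DNA variants chosen by greedy
max–min Hamming distance (seeded at the most-frequent-codon encoding), so
repeated junctions do not create DNA repeats.

A cohort of constructs (default 10,000) is generated this way and scored:

* **CAI** — geometric mean of each codon's relative adaptiveness
  $w = f/f_{\max}$ within its synonymous family, excluding
  single-codon amino acids (Met, Trp) and stops, which carry no signal;
* **GC content** — G+C fraction of the whole insert;
* **hazard screens** — exact direct repeats ≥ 12 nt occurring twice,
  TATA-box-like motifs (`TATAWAW`), premature polyadenylation signals
  (`AATAAA`/`ATTAAA`, coding strand), and internal occurrences of the
  flanking restriction sites. Hazard-flagged constructs are excluded
  before thresholding; with a ~1.2-kb insert a substantial fraction of
  random encodings is flagged (mostly poly-A signals and chance internal
  sites), which is exactly the risk the screen removes.

"Dynamic" thresholding is realized relative to the cohort's own score
distribution rather than fixed cutoffs: hazard-free members are ranked by
CAI penalized by the distance of their GC content from a 40–60% target
window (penalty 5 per unit GC outside the window, scaled so a 2% GC
excursion costs 0.1 CAI), and exactly
$\lceil \text{survivor fraction} \times N \rceil$ survive — 1% at
defaults, i.e. 99% of the cohort is eliminated. Only the survivors are
folded, and the construct with the **highest** (least negative) minimum
free energy is selected: less stable transcript structure favors
translation. Ties break by higher CAI, then id.

## RNA folding engine

The built-in engine is a Nussinov-style minimum-energy dynamic program on
the transcribed sequence with pair energies GC = −3, AU = −2, GU = −1
(arbitrary units) and a minimum hairpin loop of three unpaired bases. It
is exact for that energy model (the test-suite checks it against
brute-force enumeration of all nested structures on short sequences) and
fast enough to fold hundreds of kilobase-scale survivors in seconds. It
is not a thermodynamic folder: loop entropies, stacking and dangles are
outside its model, so its energies are comparable only within a cohort —
which is the only use the selection makes of them. A full thermodynamic
engine (ViennaRNA's `RNAfold`) can be selected via
`design_config(engine = "rnafold")` when the binary is on the PATH; both
engines sit behind the same lower-is-more-structured contract.

# Synthetic data: what it does and does not emulate

The generator produces proteomes (i.i.d. uniform residues), somatic and
germline variant tables, caller support, expression, and purity with the
statistical structure the pipeline assumes:

* somatic variants are clonal (CCF 1, probability 0.6 by default) or
  subclonal (CCF uniform on (0,1)); observed VAF is
  $\mathrm{CCF} \times p / 2$ plus binomial noise at the configured
  depth (default 200×; `depth = Inf` gives the noise-free limit);
* per-caller support is Bernoulli at per-caller sensitivities
  (0.8–0.9 by default);
* expression is log-normal with median at the 20-RPKM cutoff
  (log-mean $\log 20$, log-sd 1.2) so both sides of the eligibility
  filter are populated, with a 10% unexpressed fraction;
* tumor purity defaults to 0.8, a realistic value for an engrafted
  murine tumor line.

All generators derive independent substreams from one seed and are
bit-reproducible. A planted-recovery scenario augments this with $k$
variants constructed to dominate every score factor (clonal, all-caller
support, maximal property distance, high expression, and a lookup
predictor that makes exactly their mutation-spanning oligomers strong
ligands); recovery of exactly the planted set is a pipeline-level
correctness check.

What the generator does **not** emulate: real proteome composition and
homology, mutational signatures, copy-number and LOH structure, correlated
caller errors, mapping artifacts, or any real MHC binding landscape (the
mock predictor is a deterministic hash). Passing tests therefore
demonstrate that the pipeline's rules and arithmetic are implemented
correctly under its stated model — not that the scores are biologically
calibrated on real tumors.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere (proteins, windows,
  construct features).
* CCF and all probabilities are clamped to [0, 1]; purity 0 is an error,
  not a NaN.
* Empty allele lists per class yield a zero class probability rather
  than an error, so class-restricted designs run unchanged.
* Oligomer sizes longer than the candidate produce empty enumerations,
  not errors.
* The survivor count is $\lceil \cdot \rceil$ of the fraction, computed
  on the full cohort size; if hazards leave fewer eligible members than
  that, the run stops with an instruction to enlarge the cohort rather
  than silently shrinking the survivor pool.
* Variant-table parsing is total: each row yields a validated record or
  a row-level error citing the file line; nothing is dropped silently.

# Problem sizes

The unit tier exercises cohorts of a few hundred constructs and folding
oracles on sequences up to 12 nt (where exhaustive enumeration is
feasible); the full-scale tier runs the complete default design — a
13 × 27mer panel, a 10,000-construct cohort, 100 folded survivors of
~1.2 kb — in about a minute on one core, plus 20 seeded replicates of the
planted-recovery scenario at 100 somatic variants each.

# Known limitations

The four probability factors are principled stand-ins, not reproductions
of proprietary models; their functional forms and constants are exposed
in `scoring_params()` precisely so they can be refit. The clonality model
ignores copy number. The built-in folding energies are not thermodynamic.
Fusion peptides, indel-derived neo-ORFs and splice isoform enumeration
are out of scope, as are allele-coverage optimization across a panel and
any downstream statistics on in-vivo outcomes beyond caliper volume and
growth-curve AUC utilities.
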