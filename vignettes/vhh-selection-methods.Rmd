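---
title: "Selecting and characterising modulatory VHHs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and characterising modulatory VHHs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhhscreen)
```

## The problem

Raising antibodies that *modulate* a G-protein-coupled receptor — rather
than merely bind it — has a notoriously high attrition rate. One
productive strategy is to pan a camelid single-domain antibody (VHH)
phage-display library against many different presentations of the same
receptor in parallel ("multiplexed" panning: whole cells, membrane
preparations, proteoliposomes, the soluble ectodomain, fusion
constructs, peptides), sequence every round of every panning condition,
and keep only the sequence clusters that are enriched in at least one
receptor-positive condition while being absent from every negative
control. The selected candidates are then screened functionally and the
best binders characterised by binding kinetics and dose–response
pharmacology.

`vhhscreen` implements that computational workflow end to end:

1. **Repertoire processing** — paired-end amplicon merging, reading
   frame detection from a conserved framework-1 label, CDR annotation,
   and collapsing into non-redundant *signature* clusters (a signature
   is the concatenation of the three CDRs).
2. **Enrichment selection** — counts-per-million (CPM) normalisation
   and the positive/control selection rule.
3. **Repertoire embedding** — kmer encoding and UMAP projection, with a
   candidate-cohesion summary.
4. **Virtual epitope binning** — overlap, competition,
   similarity-probability and incoherence matrices from externally
   supplied epitope predictions.
5. **Pharmacology** — BLI double referencing and global 1:1 Langmuir
   fitting; BRET trace normalisation, AUC summaries and
   four-parameter logistic (4PL) dose–response fits; reporter-gene
   classification; split-luciferase competition readout.
6. **Synthetic data** — a generator for every input above, with a
   ground-truth manifest, used throughout the test suite.

## The enrichment model behind the synthetic generator

Real panning data for this kind of campaign are rarely deposited, so
validation rests on simulation with known truth. The generator uses the
minimal model consistent with round-over-round enrichment: a geometric
per-round amplification. Clone $i$ carries a per-modality factor
$a_{i,m} \ge 0$; starting from a uniform library, its expected
frequency after $t$ rounds in modality $m$ is

$$p_i^{(t)} = \frac{a_{i,m}^t}{\sum_j a_{j,m}^t},$$

and observed counts are one multinomial draw of the condition's total
reads from $p^{(t)}$. The closed form makes oracle tests possible: with
factors $(2, 1)$ and a uniform start the enriched clone's expected
frequency after three rounds is exactly $8/9$, and the simulated
frequency must land within three binomial standard deviations of it.

Ground truth designates *target binders* ($a = 4$ in one
target-positive modality, 1 elsewhere) and *background binders*
($a = 4$ in all negative-control modalities, emulating matrix or
plastic binders). Defaults for the study-scale simulation are 300
clones, 20 target binders, 20 background binders, $10^5$ reads per
condition, across the default 12-condition design (six modality
families with four negative controls, rounds 2 or 3). Sequencing error
is off by default (an optional uniform substitution rate exists); base
qualities are constant. The generator therefore does **not** emulate
PCR bias, chimeras, quality-score structure, or phage growth kinetics —
passing recovery tests demonstrates the selection logic, not robustness
to those artefacts.

Synthetic clones follow the FR1–CDR1–FR2–CDR2–FR3–CDR3–FR4
architecture with fixed framework segments and random CDRs (lengths
5–8, 6–10 and 8–18 aa). The conserved nine-residue FR1 prefix
(`QVQLVESGG`) doubles as the "protein label" used for reading-frame
detection; it is configurable, since any real pipeline will have its
own conserved label.

## Repertoire processing choices

* **Merging.** Pairs are merged on their best suffix/prefix overlap
  (largest overlap of at least 10 nt with mismatch fraction ≤ 0.1);
  mismatches are resolved toward the higher-quality base. There is no
  other quality filtering.
* **Frame detection.** All six frames are translated; the frame
  containing the FR1 label wins. Label in zero frames, label in more
  than one frame, or an internal stop codon are distinct rejection
  codes. Rejections are logged with reasons at every stage — read
  counts reconcile exactly (input = accepted + rejected).
* **CDR annotation** is motif-anchored: the four framework motifs must
  occur in order, FR1 at the start and FR4 flush with the end, and the
  CDRs are the residues between them. This approximates Chothia-style
  delimitation for the default scaffold and is configurable.
* **Collapsing** groups on the exact protein-level signature (the
  concatenated CDRs). Two clones differing only in their frameworks
  merge into one cluster — intentional, since the signature is the
  identity key. Collapsing is idempotent and count-conserving.
* Sequence coordinates are 0-based half-open internally and 1-based in
  reports.

## The selection rule

Counts are normalised per million per condition
($\mathrm{cpm} = 10^6 \cdot \mathrm{raw} / \mathrm{total}$). A cluster
is selected iff

* cpm **strictly exceeds** `positive_min_cpm` in ≥ 1 positive
  condition, and
* cpm is **at or below** `control_max_cpm` in *every* control
  condition.

`control_max_cpm = 0` is the strict "absent from all controls" reading
and is the default. In simulations every library clone drifts through
every condition at a low background frequency, as it would in a real
unwashed library, so the study-scale recovery protocol uses
`control_max_cpm = 1000` and `positive_min_cpm = 5000` (cpm of the
uniform background for 300 clones is ≈ 3300; enriched clones sit one to
two orders of magnitude above it). "Enriched" is operationalised as
presence above threshold in the final round available — the source
workflow states no fold-change rule, so none is applied by default.
Ranking is by total raw count, ties broken lexicographically.

The packaged fixture `table1.tsv` is a per-million-normalised
cluster-by-condition table of 34 candidate clusters from a 12-condition
campaign; its control columns are all zero, so the strict rule keeps
all 34 rows, with the PRC1 cluster (45,099 reads) ranked first. Note
that for most rows of that table the printed per-cluster total does not
equal the sum of the printed per-condition values — the totals
plausibly report un-normalised raw counts. The package exposes both
and does not attempt to reconcile them; only the PRC1 row's
per-condition values sum to its printed total.

## Embedding and candidate cohesion

Signatures are encoded as overlapping amino-acid kmer counts
(default `k = 5`; only observed kmers are materialised, as the full
$20^5$ space is prohibitively wide) and projected with UMAP
(`n_neighbors = 15`, `n_components = 2`, Euclidean metric), the
parameterisation standard for repertoire embeddings. The embedding
seed defaults to 42 and the optimiser runs single-threaded so results
are reproducible.

Whether candidates "cluster together" in the embedding needs a
quantitative rule; ours is: a candidate is an outlier if its nearest
*selected* neighbour is farther than the 0.99 quantile of the
background spacing, where the background spacing is every point's
distance to its $k$-th nearest neighbour with
$k = \lceil n_\text{points}/n_\text{selected} \rceil$ — the spacing
the candidates would exhibit if they were a random subset of the
repertoire. This density matching keeps the rule stable when the
candidates sample their family sparsely. On three-family synthetic
repertoires (50 point-mutants per family), same-family candidate sets
produce zero outliers and two strays from other families are exactly
the two flagged points.

## Virtual binning matrices

Epitope predictions arrive as data (antibody, residue index,
confidence tier among very-high/high/medium; all three tiers counted
equally). For two antibodies the overlap is
$|A \cap B| / \max(|A|, |B|)$; competition is called strictly above
0.3. Similarity scores map to shared-epitope probabilities: > 50 →
0.95, 30–50 → 0.75, below 30 unassessed. The incoherence between the
two analyses is the min–max-normalised similarity minus the overlap,
with normalisation over off-diagonal entries only (self-similarity
would otherwise saturate the maximum); +1 means identical sequences
predicted to bind disjoint epitopes. No threshold for *counting* "an
incoherence" is inherited from the source analysis, so the flagging
threshold defaults to 0.5 and is configurable and always reported
alongside the full matrix.

## Pharmacology models

**BLI.** Sensorgrams are double-referenced (sample − NR control −
blank, re-zeroed at association start) and fitted globally with the
1:1 Langmuir model, sharing $k_{on}$, $k_{off}$ and $R_{max}$ across
concentrations (rates estimated on the log scale):

$$R_\text{assoc}(t) = R_{eq}(C)\,(1 - e^{-(k_{on}C + k_{off})t}),
\qquad R_{eq}(C) = \frac{R_{max} C}{C + K_D},$$
$$R_\text{dissoc}(t) = R_0\, e^{-k_{off}(t - t_a)}, \qquad
K_D = k_{off}/k_{on}.$$

A global fit is the standard, better-conditioned choice for 1:1 BLI;
initial values are data-driven (dissociation log-slope for $k_{off}$,
double-reciprocal plateau fit for $R_{max}$ and $K_D$). Noiseless
simulated sensorgrams are recovered to ≤ 10⁻⁶ relative error, and the
$K_D \equiv k_{off}/k_{on}$ identity holds to machine precision. Rate
units are 1/(M·s) and 1/s as dimensional analysis of the model
requires.

**BRET.** Kinetic traces are normalised to percent of the maximal
agonist response (the reference maximum maps exactly to 100), and
summarised by the trapezoidal AUC over the post-stimulation window
after subtracting the pre-stimulation baseline.

**Dose–response.** AUCs versus dose are fitted with the 4PL
$y = b + (E_{max} - b)/(1 + (EC_{50}/x)^h)$, $EC_{50}$ on the log
scale, initialised from the data quartiles; `bottom` and `hill` can be
fixed. All four parameters are free by default.

For the Monte-Carlo potency-recovery experiments the protocol fixes
`bottom = 0` (the responses are baseline-subtracted AUCs, which are
zero at zero dose by construction) and `hill = 1` (standard slope).
This is an identifiability decision, not a convenience: the
experimental concentration grid ($10^{-9.5}$–$10^{-6.5}$ M, half-log
steps) starts about twofold *above* the cAMP-pathway EC50 of 0.15 nM,
so with realistic noise a four-free-parameter fit cannot pin the lower
asymptote and the median recovered EC50 inflates several-fold. With
the two assay-level constraints the median over 200 simulated
experiments (4 replicates per dose, Gaussian noise at the reported
response dispersions) recovers the generating EC50s well within their
reported uncertainties. The mGs-recruitment scenario has no printed
response-scale dispersion, so it is simulated on the normalised scale
(Emax 100%, noise SD 10, i.e. 10% of Emax — the same order as the
~19% relative dispersion of the cAMP assay).

**Reporter screen.** Candidate luminescence is expressed as percent of
the NR-control mean; candidates are called positive/negative
modulators when the departure from 100% exceeds twice the replicate
spread, neutral otherwise. **Competition readout**: plateau ratio
(trailing 20% of each trace) with a delta-method 95% CI; "no
competition" when the CI contains 1. Formal two-way ANOVA machinery is
intentionally out of scope; CI-overlap reporting covers the package's
comparative needs.

## Orchestration and problem sizes

`run_pipeline()` chains synth → repertoire → select → embed from one
(YAML-serialisable) config, writes every artefact as TSV, and ends
with a content-hashed JSON run manifest; reruns with the same seed
hash identically. The FASTQ emission/re-processing route and the
direct tabulation route produce identical cluster tables and can be
toggled (`emit_fastq`), since re-deriving counts through actual reads
is only informative at small scale. Default problem sizes throughout
the test suite — 300-clone repertoires at $10^5$ reads per condition
for recovery, a few thousand read pairs for the FASTQ route, 150-point
embeddings, 200 Monte-Carlo dose-response repeats — were chosen as the
smallest sizes at which the statistical claims under test are stable.

## Known limitations

* The merge step assumes the amplicon is fully covered by the pair;
  non-overlapping (staggered) designs are rejected, not assembled.
* CDR annotation requires exact framework motif matches; a single
  substitution inside a motif makes the read `unannotatable` rather
  than fuzzily matched.
* The outlier rule for embedding cohesion and the incoherence flagging
  threshold are this package's own quantitative renderings of
  qualitative claims; both are parameters, and conclusions should be
  checked for sensitivity to them.
* Selection offers no differential-enrichment statistics (no
  fold-change tests, no p-values); it is a deterministic rule on
  normalised counts, which is exactly what it validates against.
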