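---
title: "Network dissection of dietary restriction genetics with netGBA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network dissection of dietary restriction genetics with netGBA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netGBA)
```

## The problem

Dietary restriction (DR) — reduced nutrient intake without malnutrition —
extends lifespan in organisms from yeast to mammals. A small number of
*DR-essential* genes are known: genes whose manipulation blocks or disrupts
the lifespan extension. Treating these genes as a *seed list*, netGBA asks
three questions of them that together dissect the genetics of DR:

1. **Network position.** Do seed genes sit centrally in the molecular
   interaction network (high degree), and do they interact with each other
   more than chance predicts (high *specificity of interconnectivity*)?
2. **Prediction.** Which other genes are so over-connected to the seeds that
   they are themselves candidates (*guilt by association*, GbA)?
3. **Conservation and regulation.** Are seed genes evolutionarily conserved
   (ortholog presence, dN/dS), which transcription factors and promoter
   motifs drive the DR expression signature, and which interactions are
   induced or suppressed when the interactome is weighted by expression
   changes?

The package implements the full pipeline — interaction-evidence integration,
identifier mapping, merging and scoring; degree and specificity statistics;
GbA ranking with exhaustive leave-one-out validation; conservation
statistics and a degree/orthology/dN-dS regression; fold-change and
differential-expression (DE) calling; motif and TF-specificity enrichment;
expression-weighted network condensation; and two p-value combination
methods — together with a synthetic-data generator that reproduces the
statistical structure of every input, so the whole chain is testable without
external downloads.

## The guilt-by-association statistic

For a network with $n$ nodes and a seed set $S$, a gene $g$ with total
degree $d$ and $s$ edges to seeds is scored by the exact binomial upper
tail

$$ p(g) \;=\; P\!\left[\mathrm{Bin}(d, q) \ge s\right], \qquad
   q \;=\; \frac{|S \setminus \{g\}|}{n - 1}. $$

The null model says each of $g$'s interaction partners is a uniform draw
from the other nodes, so $q$ is the seed fraction among them. Genes with
$p < \alpha$ (default $\alpha = 0.05$, uncorrected — BH q-values are
reported alongside) are significant interactors; non-seed significant genes
are the candidates. Seeds are scored too, with $s$ counting edges to *other*
seeds, which is what makes the leave-one-out test coherent: each seed is
withheld in turn, the ranking is recomputed from the remainder, and the
*recovery rate* is the fraction of withheld seeds that score significant.
That rate is the method's sensitivity estimate on a given network/seed pair.

Two design points were genuinely open and are resolved as follows:

* **Background null.** An alternative null sets $q$ to the seeds' share of
  all edge *endpoints*, which weights seeds by their connectivity. Both are
  available (`null = "node"` is the default; `null = "endpoint"` the
  option). The node-fraction null is the default because it is the simplest
  model consistent with a "number of interactions with seeds" statistic and
  does not double-count the very hub effect the pipeline measures.
* **Tie-breaking.** Ranked output orders by ascending p, then descending
  specificity, descending degree, lexical id — fully deterministic, so runs
  are reproducible to the byte.

*Specificity of interconnectivity* is the companion descriptive measure:
$100 \times (\text{edges to seed members}) / (\text{all edges})$ per gene,
averaged over the seed set. Zero-degree members are excluded from the mean
and reported. The set-vs-background degree comparison excludes set members
from the background by default (a `background = "all"` switch gives the
literal interactome-wide mean); exclusion avoids contaminating the
background with the very genes being tested.

## Interaction evidence: integration, mapping, merging, scoring

Evidence arrives as PSI-MITAB 2.5/2.6 or a generic source/target TSV.
Cross-species records are dropped (and counted): only same-taxon
interactions are analyzed. Identifier mapping is two-pass: exact primary-id
lookup first, then synonym resolution choosing the candidate canonical id
with the highest support count across source databases; ties are treated as
unmappable and reported rather than guessed, because mapping errors poison
degree statistics. Merging fuses $(A,B)$ and $(B,A)$ in undirected mode
(directed mode keeps them distinct), removes self-loops with a count, and
de-duplicates evidence on (source, publication, method, type).

Each merged edge gets an integer score: one point per distinct interaction
type, per distinct detection method, and per distinct publication, plus one
if any evidence involves a post-translational modification. The features are
fixed; the unit weights are the minimal faithful choice where no weighting
is prescribed, so a single-evidence edge scores 3 and scores only grow as
evidence accumulates. Missing annotations count as one "(unspecified)" level
of their feature rather than zero, keeping the score monotone in evidence.

## Conservation statistics

*Ortholog presence.* For each target species the fraction of set genes with
at least one protein-coding ortholog is compared with the genome-wide
fraction; fractions are averaged over all pairwise comparisons and the
enrichment is a Poisson upper tail with $\lambda$ = averaged genome fraction
× set size, evaluated at the averaged set count (rounded to the nearest
integer, since the average of integer counts need not be integral). The
upper tail is the default because the claim under test is *enrichment* of
conservation; a lower-tail option exists. The per-pair versus
averaged-comparison convention was open; the averaged convention is used
because it matches how the percentages themselves are summarized.

*dN/dS.* Rate comparisons are Mann-Whitney tests plus group means, run
separately for dN, dS and dN/dS. The caller first applies the ancient-gene
filter (`ancientGenes()`): both groups are restricted to genes with
orthologs in distant species, so a conserved set is compared against equally
old background genes. Stored dN/dS values win over recomputed dn/ds when
both are present, mirroring the consumption of precomputed ortholog tables.

*Regression.* On a per-gene table of degree, number of species with
orthologs, and dN/dS, rows with zero degree or missing/non-positive dN/dS
are removed so degree and dN/dS can be log-transformed (species counts stay
linear). The package reports pairwise Pearson correlations, a least-squares
fit of each variable on the other two, and — for a gene set of interest —
observed versus model-predicted means, back-transformed by plain
exponentiation. No smearing correction is applied to the back-transform: the
predictions are meant as simple expected values on the natural scale, and a
bias correction would change the quantity being reported.

## Expression, enrichment, condensation

Replicates are averaged per condition (arithmetic mean by default, geometric
by option) and fold changes are linear-scale ratios. DE calling uses a
threshold $\tau$ (default 2) with *inclusive* boundaries: up if ratio
$\ge \tau$, down if ratio $\le 1/\tau$. Inclusive versus strict is
config-switchable; inclusive is the default so that "two-fold" data points
sitting exactly at the threshold are counted.

Set-overlap enrichment is the exact hypergeometric upper tail. The universe
is an explicit required argument everywhere — there is no silent default —
because overlap p-values move by orders of magnitude across plausible
universes (all annotated genes? genes on the array?). The acceptance script
reports this sensitivity explicitly by sweeping the universe from 5000 to
8000 genes for fixed printed overlap counts.

Motif enrichment scans fixed-length upstream regions (default 500 bases,
extracted 1-based, strand-aware and TSS-exclusive: $[TSS-500,\,TSS-1]$ on
the coding strand) for degenerate IUPAC motifs; every start position is
tested and overlapping matches count. Scanning is forward-strand by default
— annotated upstream sequences are scanned as given — with a both-strands
flag. The universe for the hypergeometric test is the promoter set itself.
TF target specificity is the analogous binomial statistic: $s$ DE targets
out of $t$ at the DE background rate.

Condensation weights each edge by
$\log_2(\mathrm{ratio}_u) + \log_2(\mathrm{ratio}_v)$ — the log-ratio of the
endpoints' joint expression after versus before, which factors exactly into
this sum. Positive scores are *startup* (induced) interactions, negative
*shutdown* (suppressed); zero-score edges belong to neither side. Reduction
to "approximately $N$ genes" is a single monotone threshold search over the
sorted absolute scores of the chosen side, keeping whole threshold classes:
this is order-free and reproducible, unlike iterated ad-hoc passes, and
satisfies the same contract. The returned subgraph never exceeds the target
and adding the next score class would (or no edges remain).

## p-value combination

Two combiners for independent p-values:

* **Analytic (product) method:** with $k = \prod p_i$,
  $P = k \sum_{i=0}^{n-1} (-\ln k)^i / i!$, accumulated in log space. This
  equals the $\chi^2_{2n}$ survival value at $-2\ln k$ (Fisher's method);
  the identity is verified to $10^{-10}$ over 1000 random vectors in the
  test suite.
* **z-method (unweighted Stouffer):**
  $z = \sum \Phi^{-1}(1-p_i)/\sqrt{n}$, returning $1-\Phi(z)$.

Both are identities at $n = 1$ and permutation-invariant. A p-value of
exactly 0 is rejected rather than silently collapsed to 0 (a `zeroOk` flag
overrides), because zeros usually signal upstream underflow.

## The synthetic-data generators

The generators define the conditions under which the pipeline is validated;
they are first-class, tested code, not fixtures.

* **Interactome:** preferential attachment starting from $m$ isolated
  nodes, each newcomer attaching $m$ distinct degree-proportional edges, so
  the edge count is exactly $m(n-m)$ and the degree distribution is
  approximately power-law (log-log slope within $[-3.5, -1.5]$ at
  $n = 2000$). A planted module of `moduleSize` nodes receives each absent
  intra-module edge independently with `intraModuleEdgeProb`.
* **Expression:** baseline log2 intensities $\mathcal{N}(9, 1)$; DE genes
  (fraction `deFraction`, labeled up/down in equal numbers) shifted by
  $\pm\log_2(\texttt{effectFold})$ in the DR condition; replicate noise
  $\mathcal{N}(0, \texttt{noiseSd})$ on the log2 scale. Effects are
  symmetric up/down so truth accounting is exact; real DR data are
  asymmetric, which the generator deliberately does not model.
* **Orthology:** per-species ortholog presence Bernoulli(0.9) for module
  genes versus Bernoulli(0.5) genome-wide; dN/dS log-normal with median
  0.08 (module) versus 0.15 (background), spread 0.6 on the log scale —
  magnitudes typical of conserved versus average genes in mammalian
  pairwise comparisons.
* **Promoters:** i.i.d. uniform ACGT sequences of 500 bases; one concrete
  expansion of the degenerate motif (default the 10-mer `YGNCACAAAW`, a
  middle-sporulation-element-like pattern) overwrites a uniform window in
  80% of the target set and 5% of the background.

Defaults are the validated operating point: $n = 500$, $m = 3$, module 25,
intra-module probability 0.4, DE fraction 0.1 at 4-fold with noise 0.2 and
2 replicates. At that point, across generator seeds 1–5, mean leave-one-out
recovery at $\alpha = 0.05$ exceeds 60% while 25-gene random pseudo-seed
sets recover at most 10%; two-fold DE calling reaches sensitivity ≥ 0.9 at
false-positive rate ≤ 0.05; and the planted motif reaches $q < 0.05$. These
sizes keep the full validation suite fast while leaving all the statistics
far from small-sample degeneracy.

Every generator is a pure function of its `simConfig()`: the same seed gives
byte-identical output, and the caller's RNG stream is left untouched. What
passing these tests shows is that the *statistics* behave as designed on
data with the assumed structure; it does not show that real interactomes
satisfy the assumptions (notably: uniform-endpoint null, independent edges,
symmetric DE effects, i.i.d. promoter background). Literature-curation bias
— seeds being studied *because* they are conserved and well-connected — is a
property of real seed lists that no generator setting reproduces.

## Numerical and degenerate-input choices

* Discrete tails are exact summations (via R's exact distribution
  functions); no normal approximations anywhere in the tails.
* Mann-Whitney: exact closed-form null for untied samples up to combined
  $n = 20$; exact midrank enumeration for tied samples up to combined
  $n = 14$; tie- and continuity-corrected normal approximation beyond.
  The default is two-sided; every directional claim in the pipeline
  ("higher degree", "higher expression") passes `alternative = "greater"`
  explicitly.
* Degree-slope fitting is simple least squares on log-log binned counts —
  a descriptive diagnostic matching the log-log presentation, not a
  maximum-likelihood power-law fit — and errors on fewer than three
  distinct nonzero degrees.
* Empty intersections, empty universes, all-seed networks, fewer than two
  seeds for leave-one-out, and negative thresholds are domain errors with
  informative messages; unmappable identifiers and clipped set members are
  reported, never silently dropped.

## Orchestration

`runPipeline()` runs any subset of stages in dependency order from one
configuration (YAML file or list; YAML is used because a mature parser is a
standard R dependency and the format is human-diffable), validates stage
names and input paths before executing anything, supports dry runs, logs to
file and console, and writes a machine-readable `run_report.json` whose
content is deterministic given config and seed. A thin command-line wrapper
ships in `inst/scripts/run-pipeline.R`; the package functions are the
primary interface.

## Known limitations

* The GbA statistic is strictly a first-neighbor count; no network
  propagation or diffusion.
* No probe-level microarray modeling or normalization: normalized
  expression matrices are consumed as-is.
* Hypergeometric overlap p-values are only as meaningful as the supplied
  universe; the package forces that choice on the caller.
* The interactome evidence score is ordinal, not calibrated; it is carried
  through outputs but no stage currently thresholds on it.
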