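---
title: "Benchmarking short-read functional annotation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking short-read functional annotation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(komapr)
library(dplyr)
library(purrr)
```

# The measurement problem

Homology-based functional annotation maps each shotgun read independently
to a database of orthologous gene groups (KOs) through a translated
search, and takes the abundance of reads per KO as the functional profile
of the community. komapr quantifies how faithful that process is, by
simulating reads whose true origin is known exactly and comparing the
annotation each read receives with the annotation of the genomic region
it came from.

The package separates four concerns, each with its own module surface:
generating reads with recorded provenance; turning an alignment table
into per-read fractional KO assignments under a chosen protocol;
simulating incomplete reference databases; and scoring assignments
against ground truth at the read and at the profile level.

# Read simulation

Reads are windows of fixed length $L$ slid across a genome at a stride
$s$: starts $1, 1+s, 2s+1, \dots$, giving exactly
$\lfloor (G-L)/s \rfloor + 1$ reads on a linear genome of length $G$. A
stride of 1 produces *every* possible read (each interior base is then
covered by exactly $L$ reads); a stride of 10 the common down-sampled
variant. Circular genomes optionally wrap windows across the origin so
every start position is used once. Each read records its origin
category — fully inside a KO-annotated gene, fully inside a gene with no
KO, intergenic, or spanning more than one category (`MULTI`) — along with
the genes it overlaps and per-category overlap fractions that always sum
to 1.

Where gene annotations overlap, a position covered by at least one KO
gene counts as KO-gene territory, any other gene-covered position as
non-KO-gene. Annotation sources rarely say how they resolved overlapping
CDS when labelling positions; letting KO evidence dominate is this
package's choice, made once and applied consistently (the synthetic
communities place genes without overlap, so nothing downstream depends
on it). Origin classification ignores strand, since a translated search
covers all six reading frames.

Sequencing error is modelled as substitution-only, matching the Illumina
regime the short-read protocols target; indels are not modelled. An
error profile is a vector of per-position substitution probabilities
(plus an optional 4×4 replacement matrix). `scale_profile()` multiplies
the profile by a constant so that its mean over the read length equals a
target rate — the "uniform magnification" used to turn a 0.15%
run-derived profile into 1.5% and 3% variants — and refuses to push any
position past probability 1. Injection is seeded and byte-reproducible.

# From alignments to assignments

Alignments arrive as 12-column tabular (outfmt-6) rows. Hits with
E-value $\ge$ the cutoff (default 1, strict `<`, the HMP convention) are
discarded; the rest are ordered per read by E-value, ties broken by
bitscore then subject id. Two hits *tie* when their printed E-value
strings are equal: aligners print coarse precision, and comparing parsed
floats would split ties the aligner reported as equal.

Four protocols turn a hit list into KO weights:

* **top gene** — the minimal-E hit(s), ties included. If none carries a
  KO the read gets *no result*.
* **top KO** — the minimal-E hit(s) among KO-bearing hits only;
  better-scoring KO-less alignments are ignored. Equivalent to searching
  a database that only contains annotated genes.
* **top 20 genes** — the up-to-20 smallest-E hits (boundary ties
  extend the set), KO-bearing or not.
* **top 20 KOs** — the KO-bearing hits within that top-20 set.

When several alignments are considered they are weighted by their chance
probabilities. With $P_i = 1 - e^{-E_i}$ the probability of at least one
chance match at hit $i$'s score, the default weighting uses the
complement,

$$ w_i \;=\; \frac{1 - P_i}{\sum_j (1 - P_j)} \;=\;
   \frac{e^{-E_i}}{\sum_j e^{-E_j}}, $$

so that better hits (smaller $E$) weigh more. A literal mode
$w_i \propto P_i$ is selectable; the two coincide for tied hits (the
only case the single-hit protocols ever weight), and practical reports
note the functional form matters little. The complement is the default
because it avoids the degenerate case where a perfect hit ($P \approx 0$)
receives zero weight; in the literal mode an all-zero-$P$ set falls back
to uniform weights. Weights over the considered set always sum to 1.

Two further rules matter for profile accuracy. KO-less hits inside a
top-20 set contribute no KO but keep their weight, deliberately deflating
the fractional counts of the KOs that are present. And a hit to a gene
annotated with several KOs splits its weight equally among them,
preserving unit sums (the sources are silent here; equal split is the
minimal assumption).

# Simulating incomplete databases

Removing all alignments to the read's own strain, species, or genus
from an existing search result is mathematically equivalent to replacing
those database sequences with non-matching sequences of the same
lengths: database-size-based metrics such as the E-value are untouched.
`apply_exclusion()` implements exactly this filter, plus a distance mode
that removes hits to genomes closer than a cutoff in a user-supplied
16S-distance table (strict `<`, so a cutoff of 0 removes nothing).
Exclusion never edits a surviving hit, is idempotent, and nests:
the species-excluded hit set is a subset of the strain-excluded set.
The caveat for the distance mode is inherited from the filtering
identity: it is exact only when the removed set corresponds to whole
taxa; distance-filtered tables taken from a search against the full
database keep the full database's E-value scale.

# Scoring

Classification is per considered alignment: each hit's weight goes to
one label according to whether the subject is the read's gene of origin
and whether the subject's KOs intersect the source gene's KOs
(correct gene/correct KO, incorrect gene/correct KO, incorrect
gene/incorrect KO, incorrect gene/no KO, correct gene/no KO). Reads
whose considered set exists are judged this way even when the protocol
reports *no result* (a KO-less considered set) — the alignment-level
labels are what the gene-level metrics need. Reads with no alignments
at all are *no hit*. Labels for each read sum to weight 1.

`MULTI` reads are excluded by default, since their "correct" annotation
is not well defined; a coverage-weighted policy retains them with their
per-category overlap fractions as weights, and `overlap_mappability()`
uses that mode to resolve mappability as a function of how many bases a
read shares with a KO gene.

The sources never write the precision/recall formulas; the
operationalization here takes reads as the unit with fractional weights
propagating:

* **KO recall** = (summed correct-KO weight over reads originating in KO
  genes) / (number of such reads). *No result* and *no hit* reads count
  in the denominator — failing to annotate a KO-gene read is a recall
  failure — but never against precision.
* **KO precision** = (summed correct-KO weight) / (summed weight
  assigned to any KO, over all reads). Only assignments actually made
  can be imprecise.
* **gene recall** is the correct-gene analogue, over reads originating
  in any gene (KO or not), with correct-gene labels
  {correct gene/correct KO, correct gene/no KO}.

With an empty assignment set precision is reported as `NaN` with its
zero denominator flagged, never silently as 0 or 1.

# Profile-level analyses

Counts per KO are the summed fractional weights. To correct the length
bias of read counts, each gene's contribution is divided by a gene
length: by default the length of the gene the read actually aligned to
(simulating the realistic case where the true source is unknown), with a
weight-average of reciprocal lengths for multi-hit reads; alternatively
by the KO's mean member-gene length, a scheme kept for comparison since
it measures worse whenever within-KO lengths vary. Copy numbers divide
each KO's normalized count by the mean normalized count of a set of
universal single-copy marker KOs. The canonical marker set (15 ribosomal
single-copy genes) is a property of real catalogs and is cited rather
than enumerated in the sources, so markers are a configurable list here
and synthetic communities declare their own; with equal gene lengths and
perfect annotation the estimator is exact by construction
(window-count arithmetic: $(l - L + 1)$ reads per copy, lengths cancel).

Profiles are compared with the Jensen-Shannon *distance*, the square
root of the Jensen-Shannon divergence with base-2 logarithms — a metric
bounded in $[0,1]$ (symmetry, identity, and the triangle inequality are
property-tested). Vectors are zero-filled over the union of KOs and
normalized to sum 1 before comparison; copy-number vectors are treated
the same way, the package's convention since divergence requires
distributions.

Per-KO recall is computed per dataset and averaged, with a 95% normal-
approximation CI across datasets, alongside a gene-property vector
(length mean/SD/CV, gene and genome counts, genes per genome) for
correlating mappability with its determinants. The cross-KO similarity
fraction is defined only where a similarity structure exists; synthetic
catalogs set it by construction (zero: families share no sequence), real
catalogs would need an external similarity database, and it is `NA`
otherwise. The bottom-5% recall set (boundary ties included) feeds a
one-sided hypergeometric enrichment over pathways with Benjamini-
Hochberg correction at 0.05 — BH being the default reading of an
unspecified "FDR". Pathway abundance vectors sum KO abundances into
every pathway a KO belongs to and normalize per sample; protocol effects
are assessed by comparing inter-protocol to inter-sample Jensen-Shannon
distances and by paired Wilcoxon signed-rank tests per pathway against a
reference protocol, testing only pathways with nonzero paired
differences in at least 10 samples (the default carried over from the
HMP-scale analysis; configurable for smaller designs).

# The synthetic community and its oracle

The generator builds a panel of genomes on a nested taxonomy (strains
within species within genera). Gene family $f$ is instantiated once per
genome, so orthologs exist at every taxonomic level; a configurable
fraction of families carries a KO, the first families are reserved as
single-copy markers, and selected KOs can be duplicated to known copy
numbers. Sequence content is random nucleotide: the pipeline under test
consumes alignment tables, so homology lives in the *oracle aligner's*
hit structure rather than in sequence similarity — this keeps the tests
fast and the ground truth exact, at the deliberate cost of not
exercising a real aligner (an optional hook for running a real
translated search on the synthetic sequences exists but no test requires
it).

The oracle grants every fully-in-gene read a self hit, hits to its
family's homologs at E-values fixed per taxonomic relationship
(defaults $10^{-40}$ self, $10^{-35}$ same-strain paralog, $10^{-20}$
sibling strain, $10^{-10}$ same genus), an optional cross-family
"remote" hit in a different genus ($E = 10^{-3}$, different KO), and
random decoy hits at $E \in [0.01, 0.9]$. With probability $c$
(corruption) a gene read's self hit is dropped, modelling mappability
failure. Boundary-spanning and intergenic reads receive only decoys.

Two points in this design were genuinely open. First, a single "remote"
homolog level cannot be both same-KO (needed for the perfect-annotation
limit, where every protocol must score 1 even with homolog hits inside
the top 20) and different-KO (needed for the exclusion sweep to end in
a wrong annotation); the generator therefore keeps same-family homologs
within the genus and makes the cross-family remote hit a separate,
optional feature. Second, the corruption-recovery identity
(recall $= 1 - c$) only holds when a corrupted read has no surviving
homolog hits, so those experiments disable cross-genome homology — the
community that identity implicitly assumes.

Two hand-worked fixtures anchor the arithmetic. **F1** (three reads: a
KO-gene read annotated correctly, a non-KO-gene read whose best hit is
its own KO-less gene with a worse KO-bearing hit below, an intergenic
read with a KO hit) gives, by hand, KO precision $1/2$ and recall $1$
under *top gene* and precision $1/3$ under *top KO*. **F2** (equal-length
genes, three markers, one KO in two copies, perfect annotation) recovers
copy number exactly 2.

# Numerical and scale choices

Deterministic seeding covers every stochastic step (community assembly,
error injection, oracle decoys and corruption); reruns are
byte-identical, and the orchestration layer writes a manifest from which
any output directory can be regenerated. E-value ties are resolved on
printed strings; remaining order is fixed by bitscore and lexicographic
ids so truncation is reproducible. $0 \log 0$ is treated as 0 in
entropies; Jensen-Shannon values are clamped to $[0,1]$ against rounding.
All-zero profiles, missing markers, empty hit lists and unknown subject
genes raise errors or flags rather than propagating silently.

The bundled experiments run at desk scale, chosen so the full test suite
and the acceptance script each finish in minutes on one core: the
default community is 2 genera × 2 species × 2 strains × 30 gene families
of 300 bp with 150 bp intergenic gaps and 15 markers, read length 101,
strides 1–10, $\ge 10^4$ reads per end-to-end experiment and $10^6$
bases for error-rate checks. These sizes give binomial standard errors
small enough for the two-standard-error acceptance bands while keeping
ground truth exhaustively checkable.

# What passing does and does not show

The synthetic benchmark validates the *pipeline arithmetic*: window
counting, weighting, tie handling, exclusion logic, metric definitions,
normalization and copy-number recovery, at exactly known truth. It does
not validate biological realism: oracle E-values are fixed per level
rather than drawn from alignment score distributions, homology is
all-or-nothing across families, error injection does not interact with
the oracle (real mismatches degrade alignments continuously), and no
real aligner is run. Conclusions about a particular organism, database
or aligner require feeding the same interfaces real outfmt-6 tables —
which is precisely what the interfaces are shaped for.
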