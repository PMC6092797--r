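---
title: "Differential CLIP binding and the splicing map: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential CLIP binding and the splicing map: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipmap)
```

This vignette is the package's account of its statistical models, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the places where the design was genuinely open and a choice had
to be made.

## The problem

A cell type-specific CLIP library (here labelled MN, for motoneuron) is
compared against a whole-tissue reference (WSC, whole spinal cord). The two
libraries differ in everything that is *not* biology: replicate counts (8 vs
4), depth (the MN library is roughly one eighth of the WSC library), and
power. Every statistic in the package is therefore built to cancel library
size: the site test conditions on within-gene totals, the gene test
conditions on the library-size proportion, and normalised peak heights are
reads-per-million.

## Read preprocessing

**Deduplication** collapses reads to one per (chromosome, start, end,
strand) within each replicate. The degenerate-barcode collapse used in
library preparation operates upstream of the package's input boundary
(aligned intervals), so exact-position collapse is the conservative stand-in;
identical intervals in *different* replicates are deliberately kept, because
biological complexity counts replicate provenance.

**RT-artifact filtering.** Reverse transcription can be mis-primed by
GUGUC-like pentamers in the captured RNA, so reads whose 3′ ends abut such
pentamers are amplification artifacts. For every read the 5-mer starting
immediately after its 3′ end (strand-aware) is extracted, all observed
pentamers are ranked by frequency, and reads are removed when their
downstream pentamer is both in the top 20 and within Hamming distance 1 of
GTGTC. Two readings of that rule are possible: "GTGTC-like members of the
overall top 20" (implemented default) or "the top 20 of the GTGTC-like
pentamers" (`rule = "top_of_like"`). The default is the stricter reading: a
GTGTC-like pentamer that is not globally frequent is not evidence of a
systematic artifact. Ranking pools both conditions, since the artifact is a
property of the RT chemistry, not of a condition. Reads with under 5 nt of
3′ flank cannot be evaluated and are kept — dropping them would bias genes
at chromosome edges.

## Peak calling

The null for a gene with $R$ reads of mean length $\bar L$ over a
transcription unit of length $G$ (gene span plus 10 kb downstream,
strand-aware, clipped at chromosome bounds) is that reads fall uniformly, so
per-base coverage is approximately Poisson with rate $\lambda = R\bar L/G$.
The significance height $k^\ast$ is the smallest $k$ with
$G \cdot P(\mathrm{Pois}(\lambda) \ge k) \le \alpha$ (default
$\alpha = 0.01$), peaks are maximal runs of coverage $\ge k^\ast$, and the
per-peak p-value is the adjusted tail at the run's summit.

The multiplicity factor was a genuinely open choice. A clump-count heuristic
($\lceil G/\bar L\rceil$ effective windows, reasoning that coverage
decorrelates over one read length) is tempting but anti-conservative: the
maximum *within* a correlated clump exceeds a single Poisson draw, and in
calibration runs on uniform reads about 6% of null genes acquired a peak at
$\alpha = 0.01$. The per-base factor $G$ is conservative in the opposite
direction, and empirically costs nothing here: on 20 seeds of uniform-read
data 0.17% of genes acquire a peak, while planted sites with tens of reads
are recovered essentially always (their summits exceed $k^\ast$ by a wide
margin). Multiplicity is controlled per gene, not per transcriptome — the
$p \le 0.01$ rule is a per-gene statement.

Peak boundaries are the maximal run at $k^\ast$ rather than a half-maximum
rule: deterministic and parameter-free. `region_class` is assigned by peak
midpoint with priority exon > intron > downstream; UTR subclasses are folded
into "exon" because the differential test treats intronic and exonic sites
as the only two families.

## Joint peaks and the site-wise test

Joint peaks (JPs) are called on reads pooled from both conditions and kept
when either group contributes reads from at least half of its replicates
(MN ≥ 4 of 8, WSC ≥ 2 of 4) — an OR rule, so a site present only in MN
survives. For each JP the test statistic is the two-sided Fisher exact
p-value of

$$\begin{pmatrix} m & M-m \\ n & N-n \end{pmatrix}$$

with $m, n$ the MN/WSC reads in the JP and $M, N$ the same-class totals over
the gene's JPs. Coverage is the smallest cell; JPs under 10 are untested and
excluded from the BH family (intronic and exonic families corrected
separately). The fold change is the ratio of relative peak heights
$\mathrm{RPH} = 100\,m/M$ (MN over WSC) — the quantity plotted on the
package's scatter — rather than a ratio of raw normalised counts; both were
defensible and the RPH ratio is the one consistent with how the results are
visualised and thresholded (FDR ≤ 0.1, fold ≥ 2). JPs whose gene has reads
in only one condition have a zero denominator and are reported untested, not
infinite-fold; the coverage rule would exclude them anyway. JPs in the
downstream extension belong to neither testing family and are dropped from
the site table.

**Compositionality.** The site test measures *disproportionate
representation*: a genuine gain of binding at one site necessarily lowers
the relative share of the gene's other sites. This is a property of the
statistic, not an artifact — and it is how ground truth is defined in the
recovery tests: a call counts as a false discovery only when the site's true
relative shares are equal between conditions. At realistic depths the
displaced sites' true fold (about 0.67 for a gene with one 4× site among
six) sits above the 0.5 call threshold, so they rarely produce calls; when
they do, the calls are real in the measured quantity.

## Gene-wise enrichment

The gene-level comparison of summed in-peak reads uses a conditional exact
binomial test: given $T = \mathrm{mn} + \mathrm{wsc}$, under no enrichment
$\mathrm{mn} \sim \mathrm{Binomial}(T, \ell)$ with $\ell$ the MN
library-size fraction. This is a deliberate, documented replacement of a
negative-binomial tagwise-dispersion model: it is deterministic, free of
fitting machinery, exactly calibrated under its null (verified on simulated
null counts), and sufficient for the package's purpose of ranking and
thresholding genes at FDR ≤ 0.01. What it does not model is
biological gene-level overdispersion across replicates; with few replicates
and the shallow MN library this costs specificity on bursty genes, which is
a known limitation rather than a target of the package.

## Motif and conservation profiles

Profiles anchor at the floor midpoint of each peak and scan the
transcript-strand sequence; T stands for U throughout. The observed value at
offset $x$ is the fraction of peaks with a class-matching 4-mer *starting*
at $x$; the expectation is composition-based under an i.i.d. model:
$E_\mathrm{YCAY} = p_Y p_C p_A p_Y$ with $p_Y = p_C + p_T$,
$E_\mathrm{YYYY} = p_Y^4$, and for U-rich (≥ 2 T among 4)
$E = 1-(1-p_T)^4-4p_T(1-p_T)^3$. The composition defaults to the scanned
windows themselves (a supplied composition can override). "Fraction of
peaks" rather than "occurrences per position" was the open normalisation
choice; the per-peak reading keeps the statistic in [0, 1] per offset and is
invariant to peak width. Windowed tetramer enrichment counts all 4-mer
occurrences within ±100 nt of peak centres, compares target against
background windows with an upper-tail hypergeometric test and BH over all
256 tetramers; overlapping windows double-count by design (each window is a
draw of positional opportunity, not a partition). Conservation profiles
average a per-base score track per offset with mean ± 1.96 SD/√n intervals;
bases missing from the track are absent, not zero, and offsets with a
single covered peak carry no interval.

## Splicing quantification

The junction quantifier fixes three conventions that the upstream tools
leave open. (1) The two cassette inclusion junctions are averaged,
$I = (\sum I_1 + \sum I_2)/2$, because one included transcript supports both
junctions; $\psi = I/(I+E)$ is then unbiased. (2) The pooled Fisher test
needs integer counts, so the averaged $I$ is rounded half-even; the dI
recovery test (bias ≤ 0.02 at coverage 100) bounds the distortion. (3)
Biological consistency ("BC 2 of 2") is read as sign consistency: every
per-replicate MN-vs-WSC ψ difference must share the pooled dI's sign. An
event is expressed when pooled junction coverage is strictly over 10 in both
conditions — coverage of exactly 10 is not expressed — and only expressed
events enter the BH family (within kind). ALE usage is junction-based
(reads into each last exon), with significance additionally requiring
|dI| ≥ 0.2; genes with three or more last exons emit one event per exon
against the rest.

## The RNA map

A differential site predicts the direction of an alternative exon's
inclusion change when its centre lies within the 400-nt hotspot around the
exon: over-represented upstream ⇒ repression in MN (dI < 0),
over-represented downstream ⇒ activation (dI > 0), under-representation
flips the sign. "Around" is read as 400 nt into each flanking intron plus
the exon body, the reading under which the canonical exemplars (a site
109 nt upstream repressing, one 121 nt downstream activating) both fall
inside. A site inside the exon body is treated like upstream binding
(repression), the dominant mode for exonic binding of this protein family;
exonic differential sites are rare in the synthetic data, so this choice is
exercised but not load-bearing. When several differential sites hit one
hotspot with conflicting predictions, the smallest FDR wins and exact ties
predict nothing — one deterministic site per exon. Sites are filtered for
significance *first* and then intersected with hotspots (the order was
ambiguous; filtering first keeps the prediction set a function of the
genome-wide site test, not of the event list). Concordance is evaluated only
against events significant at FDR ≤ 0.1, as a fraction of sign agreements.

## Category concordance and enrichment

Gene-set enrichment is an upper-tail hypergeometric test per set with BH
across sets (threshold FDR < 0.05). The category-concordance analysis
compares each category's enriched/depleted split of directional genes
(gene FDR ≤ 0.01) against the global proportion with a 1-df chi-squared
goodness-of-fit test without continuity correction. The exact cells of the
original analysis are not specified anywhere authoritative; the
goodness-of-fit form against the global direction proportion is this
package's documented choice (a 2×2 association test is the main
alternative), and the continuity correction is off by default because the
uncorrected statistic reproduces the order of magnitude of the reference
p-values; a flag enables it.

## The synthetic experiment

The generator is the package's study-design stand-in, not a tuning knob. Its
defaults are the conditions the analysis was built for:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 200 | genes, one per chromosome |
| `gene_length` | 4000–6000 nt | gene span; the unit adds 10 kb downstream |
| `n_replicates` | MN 8, WSC 4 | CLIP replicate design |
| `depth` | MN 200, WSC 1600 reads/gene | per-gene scale of the real libraries, 8× total asymmetry |
| `read_length` | 30–80 nt | cDNA insert selection |
| `background_fraction` | 0.3 | uniform reads within the unit |
| `artifact_fraction` | 0.05 | RT artifact reads at GTGTC occurrences |
| `sites_per_gene` | 6 | planted 32-nt YCAY clusters, ≥ 250 nt apart |
| `differential_fraction` | 0.3 | genes with one multiplier ≠ 1 site |
| `fold_levels` | 4, 0.25 | MN intensity multipliers of differential sites |
| `cassette_fraction`, `ale_fraction` | 0.6, 0.3 | genes with splicing events |
| `coupled_ddI` | 0.2–0.5 | inclusion shift of map-coupled events |
| `splicing_replicates`, `splicing_depth` | 2, 100 | junction-count design |

Site-anchored reads jitter ±10 nt around the cluster centre, producing
compact peaks comparable to 30–80 nt reads without modelling crosslink
chemistry. Genes carrying both a differential site and a cassette event
place that site inside the exon's hotspot and set the inclusion shift in the
direction the map dictates; the coupling rule is asserted on every emitted
truth table. The per-gene depth (200/1600 at an 8× ratio) mirrors the real
libraries' per-gene scale; at materially shallower depth the coverage ≥ 10
rule starts selecting upward-fluctuated MN counts, a small-sample selection
artifact rather than the study condition.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: sequencing errors and mapping ambiguity
(inputs are alignments by construction), PCR duplication beyond
exact-position duplicates, overlapping genes and shared exons, isoform
mixtures within a gene, non-i.i.d. sequence composition, transcript-level
expression differences between conditions (the within-gene site test
cancels these by design, but the gene-level test on real data confounds
expression with binding), and crosslink-site biochemistry (CIMS/CITS are out
of scope).

Test and validation runs use 20–150 genes per seed and 3–20 seeds per
property — sizes at which every estimated rate has comfortable margin to its
threshold while the full suite stays quick; the acceptance script uses 150
genes at the default depths.

## Numerical choices

Extreme tails are computed in log space (`phyper`/`ppois` with
`log.p = TRUE`) and only exponentiated on output, so bounds far below
1e-300 remain ordered. The two-sided Fisher p sums hypergeometric
probabilities at most `1 + 1e-7` times the observed table's probability —
the standard relative-error guard against floating-point ties. Averaged
inclusion counts round half-even. BH families exclude `NA` (untested or
unexpressed) entries from the family size. Degenerate inputs follow fixed
conventions: an all-zero 2×2 table gives p = 1; a gene with no reads yields
no peaks; a zero-denominator relative height is `NA`/untested; an event with
zero coverage in a condition is unexpressed, never an error.

## Known limitations

The peak caller's per-base Bonferroni is conservative; at very low per-gene
depth, weak but real sites are missed before the site test ever sees them.
The gene-wise binomial ignores replicate overdispersion (above). The site
test's compositional nature means calls at unchanged sites of strongly
changed genes are relative, not absolute, statements. The hotspot rule uses
a single site per exon and does not model additive effects of multiple
sites. ALE quantification is junction-only; coverage-based 3′ usage
estimation is out of scope.
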