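---
title: "Inferring oxygen-responsive Fnr regulons from ChIP-Seq and RNA-Seq"
author: "fnrscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring oxygen-responsive Fnr regulons from ChIP-Seq and RNA-Seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnrscape)
```

## The inference problem

*Herbaspirillum seropedicae* carries paralogous CRP-family oxygen sensors,
Fnr1 and Fnr3, that activate transcription when oxygen becomes limiting.
Each paralog controls its own set of promoters, and a third set appears to
be controlled by both. `fnrscape` implements the computational route to
that conclusion as a reusable, testable pipeline:

1. **Peak calling.** Per-factor IP coverage is compared with a total-DNA
   (input) library in sliding windows, and enrichment is assessed under a
   normal model of between-library differences.
2. **Differential expression.** Gene counts for three strains (wild type,
   *fnr1* deletion `D1`, *fnr3* deletion `D3`) under high-aeration control
   (`C`) and low-aeration switch (`S`) conditions are tested with a
   negative-binomial exact test across seven pairwise comparisons.
3. **Regulon classification.** Binding and deletion-dependent expression
   changes are intersected. Promoters bound exclusively by Fnr1 with the
   matching expression dependence form Group I, Fnr3-only promoters Group
   II, and promoters bound by both factors Group III; each is further
   labelled activated or repressed.
4. **Motif discovery.** 300-bp strand-oriented windows around peak
   summits are searched for a 14-bp site model per group with a ZOOPS EM
   algorithm, and the Group III motif is decomposed into 7-bp half-sites
   to test whether it is a hybrid of the Group II (upstream) and Group I
   (downstream) motifs — the signature expected for oriented Fnr3–Fnr1
   heterodimers.

A seeded synthetic-data generator emulates the whole study design so every
stage can be exercised and scored against a known truth without any
external data.

## The window enrichment model

For a window with IP count $c_{IP}$ and input count $c_{in}$ (read-bases),
with library sizes $N$ and pseudocount $a$:

$$d = \log_2\frac{c_{IP}+a}{N_{IP}} - \log_2\frac{c_{in}+a}{N_{in}},
\qquad z = \frac{d - \mathrm{median}(d)}{1.4826\,\mathrm{MAD}(d)},
\qquad p = 1 - \Phi(z).$$

The genome-wide robust location and scale make the statistic
self-calibrating against depth and composition, and $d$ is invariant under
joint rescaling of counts and library sizes. Windows are 300 bp (the
sonication fragment mode) stepped by 50 bp; runs of windows with
$p < 10^{-4}$, tolerating one non-significant window, are merged into
peaks. Group membership downstream applies the stricter $p < 10^{-5}$ to
the peak p-value, mirroring the two printed thresholds of the original
analysis.

**Summit refinement.** The centre of the maximal-$d$ window localizes a
summit no better than the 50-bp step. When coverage is available the
summit is therefore refined to the base-resolution argmax of a
fragment-length (301 bp) running mean of IP minus library-scaled input —
a matched filter that converts the flat-topped fragment pileup into a
sharp apex at the binding position. Under the default simulation this
localizes summits to a few bp.

**Validity regime and calibration.** The normal model is a large-count
approximation. Window sums over fragment-smoothed coverage are compound
Poisson; at low depth (20 reads/base) their tails are visibly heavier than
normal and extreme-tail p-values are mildly anti-conservative (of no
consequence for planted sites, whose p-values are orders of magnitude
below threshold). The calibration experiment in the test suite therefore
runs where the model's assumption holds: depth 400, and only every third
contiguous window is counted so that counted windows share no fragments
(900 bp spacing exceeds the 500 bp maximum fragment) and the binomial
reference band applies. Under those conditions the empirical exceedance
fractions match $\alpha \in \{10^{-2}, 10^{-3}, 10^{-4}\}$ within three
binomial standard deviations over $10^5$ windows.

## The exact test for counts

Counts are normalized by median-of-ratios effective library sizes
(computed on depth-normalized counts, so a pure depth change scales the
effective size proportionally), a common dispersion $\varphi$ is estimated
by a method-of-moments median across genes, and each comparison is tested
conditionally: with group sums $A$ and $B$ modelled as
$\mathrm{NB}(n_a\mu,\ n_a/\varphi)$ and $\mathrm{NB}(n_b\mu,\ n_b/\varphi)$,
the two-sided p-value sums the probabilities of all splits of $S = A+B$ no
more probable than the observed one. With $\varphi = 0$ this reduces to
the conditional binomial (Poisson) test. The decision rule is the study's
printed one: significant means $p < 0.001$ **and** $|\log_2 FC| \ge 1$
(the printed interval "1 ≤ logFC ≤ –1" is read as $|logFC|\ge 1$; as
written it is vacuous). Benjamini–Hochberg q-values are reported as an
extra column but do not enter the rule. Tagwise dispersion shrinkage and
GLM-based testing are deliberately out of scope: the aim is the stated
procedure, not feature parity with edgeR.

The test suite verifies the implementation against exhaustive
plain-probability enumeration for all totals up to 50 (agreement to
$10^{-10}$), checks conservativeness on null simulations (the conditional
test is discrete, so observed type-I error sits below nominal), and
checks $\ge 90\%$ power for 8-fold inductions at baseline mean 100,
$\varphi = 0.1$, 3 vs 3 replicates.

## Classification logic

Binding evidence per factor is the best peak p-value among peaks whose
summit falls within $[\mathrm{TSS}-400, \mathrm{TSS}+100]$ on the gene
strand (the association window is a package choice; the source analysis
does not state one). A promoter is *exclusively* bound only when the other
factor shows nothing even at the relaxed $10^{-4}$ screening threshold; a
sub-threshold other-factor peak makes the call ambiguous and the promoter
is reported unclassified rather than silently assigned. This rule also
makes assignments monotone in the membership threshold: tightening it can
only drop promoters to `none`, never move them between groups.

Expression evidence follows the strain logic: activated promoters must be
up on the oxygen switch (WTCvWTS) and significantly lower in the deletion
of each binding factor (WTSvD1S / WTSvD3S); repressed promoters the
mirror image. Because *fnr1* expression itself requires Fnr3, Group I
genes are expected to fall in *both* deletions; the Fnr3 dependence is
recorded (`fnr3_dependent`) but only Fnr1 binding defines the group.
Promoters bound without expression evidence are listed with group `none`
(`bound_no_de`) and excluded from group tallies, matching how bound but
unregulated promoters are absent from the reported group sizes.

## Motif model and the hybrid test

The ZOOPS mixture gives each 300-bp window either no site (probability
$1-\gamma$) or one site of width 14 at a uniform offset, emitted by the
motif PWM against a uniform background. EM alternates a soft E-step over
offsets with a Dirichlet-smoothed M-step (pseudocount 0.25 per base);
the recorded objective is the MAP objective (data log-likelihood plus the
smoothing term), which is non-decreasing by EM theory and asserted in the
tests. Initialization follows the MEME starting-point strategy: candidate
W-mers every 7 positions from a subsample of sequences are scored in a
single pass, the best ten are run to convergence, and the winner is
polished with ±1–3 column shift restarts.

**Phase gauge.** When flanking motif columns are weakly informative — as
the Group II and III motifs' positions 1 and 14 deliberately are — phase-
shifted EM solutions differ by fractions of a nat and the maximum-
likelihood phase is effectively arbitrary. Column-wise comparisons
therefore first fix the gauge: discovered Group II/III motifs are aligned
(`align_pwm()`, up to ±3 columns) to the discovered Group I motif, whose
strongly conserved flanks pin its phase; in synthetic scoring, discovered
motifs are aligned to the planted models. Site offsets are corrected by
the same shift.

The hybrid hypothesis is quantified with column-wise Jensen–Shannon
divergence (base 2; bounded, symmetric; Euclidean distances are emitted
alongside): the verdict holds when the Group III upstream half (columns
1–7) is closer to Group II than to Group I *and* its downstream half
(columns 8–14) closer to Group I than to Group II. Half-sites are split
7 + 7, following the motif's position vocabulary (1 and 14 are the two
flanking positions; 6–7 sit in the upstream half).

Finally, discovered sites are mapped back to gene-strand TSS offsets;
a median offset within $[-45, -39]$ flags the Class II promoter
architecture (activator centred at $-42$, overlapping the $-35$ element).

## The synthetic study design

`sim_config()` fixes every condition; all stages derive independent RNG
streams from one seed, so a run is reproducible byte-for-byte. Key
defaults, and why:

| parameter | default | rationale |
|---|---|---|
| `genome_length`, `n_genes` | 1.5 Mb, 600 | desk-scale stand-in for a ~5.5 Mb / ~4800 gene chromosome; keeps planted regulon members ~14% of genes, a regime where median-of-ratios normalization is valid |
| `group_sizes` | 40 / 24 / 18 | near the reported 39 / 23 / 18 promoter classes |
| `n_repressed` | 5 / 2 | the reported repressed counts in Groups I and II; none in Group III |
| `background_depth` | 20 | input coverage per base |
| `enrichment_fold` | 8 | expected IP/input fold at a bound summit |
| `fragment_len_mean/sd` | 300 / 80, truncated to [100, 500] | the reported sonication geometry |
| `nb_mean_baseline` | 100 | baseline counts; per-gene log-normal spread (sd 0.25 on log2) mimics expression heterogeneity |
| `nb_dispersion` | 0.02 | biological CV ~14%, typical of replicate cultures of one isogenic bacterial strain; dispersions near 0.1 describe outbred samples, not this design |
| `induction_fold` | 8 | full activation on the oxygen switch |
| `partial_fold` | 2 | single-factor activation of Group III promoters; genuinely intermediate, while keeping the 4-fold single-deletion decrease detectable under the printed DE rule — as it was, by construction, for every reported co-regulated promoter |
| `replicates` | 3 | replicate count per condition is not stated in the source; 3 is assumed and configurable |

Sites are planted with their centre at TSS−42 on the gene strand
(reverse-complemented into the genome for minus-strand genes), sampled
column-wise from the group PWMs. The default PWMs encode the qualitative
motif architecture: Group I a strong TTGAT-N4-ATCAA inverted repeat with
conserved positions 1/14; Group II with degenerate flanks and C/G, C/T
preferences at positions 6 and 7 (mirrored at 8 and 9); Group III
literally the Group II upstream half joined to the Group I downstream
half. Exact column frequencies are package choices (configurable via a
MEME-format file) constrained to average at least 1 bit/column so motif
recovery is well-posed.

What the generator does **not** emulate: read-level sequencing error, GC
bias or skewed base composition, operon structure, mapping artifacts,
overlapping or shadowed peaks, and condition-dependent library
composition beyond the planted regulation. Passing tests therefore
demonstrate correctness of the inference machinery under the stated
model, not robustness to every artifact of real libraries; the bedGraph /
counts interfaces accept real data, but no claims are made about the
deposited accessions.

## Numerical choices and degenerate inputs

* Pseudocount $a = 0.5$ stabilizes window log-ratios at low coverage; the
  all-identical-tracks case returns $z = 0$, $p = 0.5$ exactly.
* If the window MAD is zero, z-scores degenerate to $0/\pm\infty$ by sign
  rather than dividing by zero.
* Rescaled counts are rounded half-to-even before conditioning; ties in
  the split probabilities are included with a $1+10^{-10}$ relative
  tolerance, and $S = 0$ returns $p = 1$.
* EM stops at an objective gain below $10^{-6}$ or 200 iterations;
  $\gamma$ is clamped to $[10^{-6}, 1-10^{-6}]$.
* Coordinates are 0-based half-open internally; GFF3 is written 1-based
  inclusive, bedGraph and BED 0-based half-open.
* Windows whose summit is within 150 bp of a contig edge are skipped with
  a warning; planted sites that would overrun an edge are an error.

## Problem sizes in the checks

The test suite and the acceptance script size their simulations to
exercise each property sharply: $10^5$ independent windows for
calibration (three 30-Mb null chromosomes), three replicate simulations
of 60 planted sites each for recovery at the boundary condition
(enrichment fold 5, depth 20), exhaustive enumeration up to totals of 50
for the exact test, 200 planted inductions for power, the full default
design (600 genes, 82 planted promoters) for end-to-end classification,
and three replicate 30-window experiments per group for motif recovery.

## Known limitations

* The enrichment statistic is this package's concrete realization of a
  normality assumption whose original implementation is not public;
  numerical equivalence with the source analysis is not claimed, nor is
  equivalence with edgeR for the exact test — only calibration, oracle
  agreement and power are claimed, and verified.
* Common dispersion only; genes with atypical variability are tested at
  the shared $\varphi$.
* ZOOPS EM reports a motif even on noise (offset selection enriches
  chance matches, flooring apparent information content near 0.65
  bits/column at 30 × 300 bp); discovered motifs should be judged by the
  separation from that floor, not by raw information content alone.
* A single motif width (14) is assumed throughout, taken from the site's
  position numbering.
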