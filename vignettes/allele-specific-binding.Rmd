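---
title: "Allele-specific binding analysis: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific binding analysis: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelome)
```

This vignette is the package's own account of the science it implements: the
allele-assignment model and its calibration, the motif-architecture
statistics, what the synthetic data generator does and does not emulate, and
the design decisions taken where more than one defensible convention exists.

## The two-haplotype read model

The analysis assumes an F1 hybrid genome in which the two parental
haplotypes (labelled B6 and JF1 after the C57BL/6 and JF1 mouse strains)
differ **only by single-nucleotide substitutions**. The JF1 haplotype is
constructed from the B6 reference by substituting the JF1 allele at every
SNP (`apply_snps()`); the operation is an involution, and the Hamming
distance between the haplotypes equals the SNP count — both properties are
asserted in the test suite. Indels are outside the model: reads overlapping
indel intervals are removed (`filter_indel_overlap()`), which is why the
pseudogenome needs no coordinate liftover.

Reads are represented as placements: chromosome, 1-based leftmost position,
strand, and the sequence as sequenced (minus-strand reads are
reverse-complemented before any comparison). Alignment itself is out of
scope; the package replaces the remapping step of the original protocol by
placement-level Hamming comparison against each haplotype, which takes the
identical accept/reject decision on an SNV-only genome pair without an
aligner dependency.

### Stringent and control contracts

Each read is evaluated against both haplotypes:

* **Stringent** (0 mismatches): because the haplotypes differ at the
  overlapped SNPs, at most one haplotype can match perfectly, so assignment
  is unambiguous. Reads matching neither haplotype (sequencing errors) are
  excluded from the informative-read count entirely, so `IR = ASR^B6 +
  ASR^JF1` holds by construction. This convention — ambiguous reads excluded
  from the denominator as well as the numerators — is a deliberate choice;
  including them in IR would deflate every allelic percentage by the error
  rate.
* **Control** (≤ 3 mismatches per haplotype, tested independently): an
  informative read with *k* overlapped SNPs has *k* more mismatches against
  the wrong haplotype than the right one, so with the usual 0–2 SNPs per
  50 bp read it maps to **both** haplotypes and is counted once on each side
  of the control tally. The control percentage *j* therefore sits near 50
  for every peak regardless of its true allelic state, and the dispersion of
  *j* across peaks measures what remains: residual mapping bias. A read
  fails one side only when SNP count plus sequencing errors exceed the
  budget, which is what gives the *j* distribution its width on real
  alignments.

This "both-sided" control is the one point where the package interprets the
dual-genome lenient remapping literally rather than re-using the stringent
voting rule with a looser bound. The alternative (assign control reads by
their SNP alleles, merely tolerating 3 mismatches) makes *j* track the true
allelic imbalance, so the across-peak spread of *j* becomes dominated by the
mono-allelic peaks and the calibrated range covers the whole 0–100 scale —
the calibration then cannot separate anything. Only the both-sided reading
yields a control distribution that actually calibrates mapping bias.

## Calibration, score and classification

Per cell line, the mean `j̄` and **sample** standard deviation `σ`
(`n − 1` denominator — the conservative choice, giving a slightly wider
range; the convention is not otherwise forced) of the per-peak control
percentages define the bi-allelicity range `Y = j̄ ± 3σ`. Membership is
inclusive at the bounds (tie behaviour is not forced by the method; the
inclusive rule is the simplest total one). A peak inside Y in both lines is
bi-allelic, outside in both mono-allelic, mixed discordant. Calibration is
computed after the informativeness filter (`IR` and `IR_C ≥ 5` in both
lines, sex chromosomes excluded), over all surviving autosomal peaks; peaks
with a zero control denominator are dropped rather than imputed.

The combined score

$$S = \frac{|\bar\jmath^{JB1} - x^{JB1}| + |\bar\jmath^{BJ1} - x^{BJ1}|}{2}$$

measures bias strength symmetrically in the two reciprocal lines and in the
two haplotype labels. Two fixed cut-offs label peaks bi-allelic (`S ≤ 26`)
or mono-allelic (`S ≥ 27`); since S is continuous, scores strictly between
the two published cut-offs are labelled `indeterminate` rather than silently
attached to either side. `S > 42.5` flags the most strongly biased peaks.
Both classifications — Y-range and score-threshold — are always reported
side by side and never merged.

**Which rule classifies?** On real alignments the two rules are intended to
coincide. On simulated placements there is no mapping machinery and hence no
mapping bias: every control read maps both ways, *j* is essentially exactly
50 everywhere, `σ → 0`, and Y degenerates to the point {50}, so the Y-range
rule would call any peak with sampling noise mono-allelic. The score
thresholds are immune to this degeneracy (they compare against `j̄`, not
against `σ`), so the package uses the score-threshold class for the
truth-recovery confusion table and fills the mono-allelic direction
`category` for score-threshold mono-allelic peaks. The Y-range class is
carried alongside in `range_class` for every peak.

Direction calling uses `j̄` as the neutral point rather than 50, so a
mapping-bias shift cannot flip a category; `x ≥ j̄` counts as "above"
(the boundary case cannot arise from exact arithmetic on distinct counts,
but the rule must be total). JF1-favoured in JB1 with B6-favoured in BJ1 is
*maternal* because JF1 is the mother of the JB1 cross and B6 the mother of
BJ1; the mirror is paternal; the same haplotype in both lines is
strain-specific.

## Motif architecture

Motifs are hexamers scanned on both strands (`scan_motifs()`); overlapping
occurrences are all reported and opposite-strand overlapping occurrences
count as distinct motifs — required to represent architectures such as two
overlapping GGCCGC copies in inverted orientation. `N` never matches.

Two occurrences are "closely spaced" when the **intervening gap** — bases
strictly between them, `start₂ − end₁ − 1` — is below 38 bp. The gap
convention (rather than start-to-start) is the default because spacing
language like "2–3 bp apart" reads most naturally as intervening sequence;
the start-to-start convention is available via `find_clusters(method =
"start")`. Clusters are maximal single-linkage chains of hits with
consecutive gaps under the threshold, size ≥ 2; on hexamers, sorting by
start also sorts by end, so consecutive-pair chaining is exactly the
transitive closure of the pairwise relation (asserted against a brute-force
closure oracle in the tests).

Cluster **density** is expressed as bp of scanned sequence per cluster; the
region denominator is the summed peak widths and the genome-wide denominator
the total non-N length. The enrichment fold is the genome density divided by
the region density, reported both raw and rounded half-up to an integer.

SNP-driven motif disruption (`snp_disruption()`) compares the ± 5 bp allele
strings around each SNP: a call is made only when one allele's window
contains a motif occurrence **covering the SNP** that the other allele
lacks. A SNP that converts one recognised variant into another (TGCCGC ↔
GGCCGC) is a disruption under a canonical-only motif set and no call under
the variant-aware set — the behaviour that lets variant-aware scanning
explain otherwise unexplained strain-specific peaks. Windows truncated by a
contig edge are shrunk with a warning. Peak motif content is evaluated on
the B6 reference by default; passing the JF1 pseudogenome to the same
functions gives the allele-aware view.

## The synthetic data generator

`sim_dataset()` emulates the features of the hybrid ChIP design that the
analysis actually consumes:

| parameter | default | meaning |
|---|---|---|
| `snp_density` | 1/250 per bp | haplotype divergence |
| `peak_width` | 300 bp | binding-site footprint |
| `read_length` | 50 bp | single-end reads |
| `allelic_fraction_mono` | 0.95 | favoured-haplotype fraction at mono-allelic peaks |
| `error_rate` | 0.001 per base | sequencing substitution errors |
| `duplicate_fraction` | 0.05 | exact positional copies |

Read length and SNP density mirror the study design the package targets;
peak width, coverage, the 95% mono-allelic fraction, the error and duplicate
rates are free parameters of the generator chosen as typical values for a
well-behaved ChIP library — the source protocol does not pin them down.

Five truth categories (bi-allelic, maternal, paternal, B6-specific,
JF1-specific) set the per-line B6 read fraction; strain-specific peaks
additionally receive a disrupting SNP in the CpG of one planted motif on the
non-permissive haplotype, so motif-disruption calls can be validated against
ground truth. Each peak gets 1–4 motif occurrences with a mix of gaps below
and above the 38 bp threshold, on both strands and from both variants.
Every peak receives one neutral SNP placed in the centre band of the peak
(inset by one read length from the edges) so that reads starting inside the
peak can cover it — the SNP exists precisely so the peak *can* be
informative, and an edge placement would defeat that purpose. Reads are
strand-symmetric (50% minus, reverse-complemented), a neutral convention the
analysis never depends on. In the degenerate configuration `snp_density = 0`
with `ensure_peak_snp = FALSE` the generator plants no SNPs at all — the
haplotypes are identical and no read is informative, a useful null dataset.

One user seed drives everything through fixed per-stage derived seeds
(reference, architecture, reads per line), so a dataset is bit-identical
across runs and any stage can be re-run alone.

**What the generator does not emulate:** fragment-size and shift structure,
GC bias, chromatin input tracks, mappability variation, indels, and — most
importantly — alignment itself. Because placements are exact, there is no
mapping bias, which is why the control calibration degenerates on synthetic
data (see above). Passing tests on synthetic data therefore validate the
counting, scoring and classification logic, not robustness to real aligner
artefacts.

## Numerical and testing choices

Degenerate inputs are handled explicitly: zero allelic denominators mark a
peak uninformative (`NA`, never `NaN`); calibration on fewer than two peaks
is an error (σ undefined); an empty SNP set makes every read
non-informative; `find_clusters` on fewer than two hits returns an empty
table. Duplicate marking is positional — one representative per
`(chromosome, start, strand)` — matching standard single-end practice, and
peak–read overlap is any intersection of at least 1 bp on closed intervals.

The test suite checks each engine against an independent brute-force oracle
(sliding-window scanning, transitive-closure clustering, base-by-base
Hamming counting, two-pass standard deviation) and runs end-to-end recovery
on seeded simulations: 200 peaks, 40 per category, ~30+ informative reads
per peak and line at a 0.1% error rate for the realistic run, and an
error-free 100-read run for exact recovery. These sizes keep the full suite
around a minute while leaving per-peak counts large enough that binomial
sampling noise cannot cross the classification thresholds. One test block
compares cohort-level motif statistics against the original published peak
set; it requires the mm9 genome FASTA and the published peak table, which
are external downloads, and reports a plain failure when they are absent
rather than silently skipping.

## Known limitations

* The method calibrates mapping bias globally per cell line; locus-specific
  bias (e.g. paralogy) is not modelled, and discordant peaks are discarded
  rather than rescued.
* No statistical test accompanies the classification — the Y-range and the
  fixed S cut-offs are the decision rules; a binomial or beta-binomial
  imbalance test is deliberately out of scope.
* Base qualities are ignored; every mismatch counts equally.
* The hexamer scanner is exact-match only; degenerate positions or PWM
  scoring are not supported, which is faithful to the motif definition used
  but limits transfer to factors with softer motifs.
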