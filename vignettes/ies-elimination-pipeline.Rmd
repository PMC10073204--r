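---
title: "Methods: IES retention, nucleosome density and small-RNA profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IES retention, nucleosome density and small-RNA profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

Ciliates such as *Paramecium tetraurelia* carry two kinds of nuclei: a
germline micronucleus (MIC) and a somatic macronucleus (MAC). During sexual
development a new MAC is built from the germline genome by programmed DNA
elimination, which precisely excises tens of thousands of short,
transposon-derived internally eliminated sequences (IESs) and imprecisely
removes transposons and other germline-limited DNA. `iesight` implements the
computational stages used to study this process from sequencing data:

1. **IES retention scoring.** Reads from a developing MAC are compared
   against the IES-containing (MAC+IES) and IES-free (MAC) references. For
   each IES, IES+ evidence supports the unexcised form and IES- evidence the
   excised junction; the retention score is IRS = IES+ / (IES+ + IES-), the
   fraction of informative evidence supporting retention. Knockdowns (KD) of
   elimination factors raise IRS; an empty-vector (EV) control keeps it near
   zero.
2. **DNA-seq-normalized nucleosome density.** From a mononucleosomal
   (MNase-style) library and a matched total-DNA library, each IES receives
   r = (n/N) / (d/D), where n and d are the fragments overlapping the IES by
   at least 9 bp and N and D the total mapped fragments. The per-bp length
   normalizations of the two rates cancel in the ratio, so r is
   dimensionless and centres at 1 for an IES packaged like the genome
   average. Distributions of r are compared between conditions within IES
   strata using a two-sample, two-sided Kolmogorov-Smirnov (KS) test at
   alpha = 0.05.
3. **Small-RNA compartment profiling.** Size-selected small RNAs (15-45 nt)
   are classified into genomic compartments (vector, MDS, IES, TE, OES) and
   tabulated per length, normalized by the total read count. The 25-nt
   scanning class (scnRNAs) arises from all compartments, while the
   26-31-nt class (iesRNAs) is exclusively IES-matching.

All coordinates are 0-based half-open internally; SAM and BED conversion
happens at the IO boundary. Strand is ignored for all counting, as both
retention and density are strand-symmetric quantities.

# The synthetic-data generator

Every stage is driven by simulated inputs with known ground truth, so the
whole pipeline is testable without any external download. The generator
(`sim_config()`, `build_genome()`, `simulate_*()`) emulates:

* a MAC assembly of 2 x 100 kb contigs carrying 500 IESs (a scaled-down
  genome; the real organism has ~45,000 IESs in a ~72 Mb somatic genome);
* an IES length distribution drawn from weighted length classes with the
  first peak at 26-31 bp (weight 0.70) and 93% of IESs shorter than a
  nucleosome footprint (147 bp), with a long tail up to 400 bp;
* TA-bounded IESs: each IES sequence begins and ends with "TA" and the MAC
  carries a "TA" at the insertion point. This is a simulator convention;
  for real annotations the package treats the supplied span as
  authoritative;
* per-IES knockdown retention: 65% of IESs are "strong"
  (retention probability drawn uniformly from 0.2-0.9 per IES, emulating
  the broad IRS distributions seen after silencing elimination factors,
  where 60-70% of IESs exceed the 0.1 cutoff), the rest nearly unaffected
  (0-0.02); the EV control has retention 0;
* mononucleosomal fragments with outer distances 125-175 bp and total-DNA
  fragments of 100-200 bp (same mean, wider sonication-like spread);
* maternal-MAC contamination: a configurable fraction of fragments
  (default 0.1) drawn from the old, IES-free somatic genome;
* unequal nucleosomal sequencing depth between conditions (default
  knockdown/control ratio 1.1702, mirroring the unequal totals this
  scenario emulates), so the library-matching downsampling path is
  exercised;
* a small-RNA pool with 70% 25-nt reads spread over compartments and 30%
  26-31-nt reads drawn exclusively from IES sequences.

## Fragment sampling model

Per fragment, independently: the outer distance is uniform in the
configured range; the template is a maternal-MAC contaminant with
probability c (every IES absent) or a developing-MAC template in which each
IES is present with its retention probability, resampled per fragment (a
template-pool abstraction under which IRS estimates a per-fragment binomial
probability); the start position is uniform over the positions that exist
on that template, with the weight of any start whose fragment would cover
IES i multiplied by the occupancy m_i (1 for DNA-seq).

Because the minimum insertion-point spacing (200 bp) is at least the
maximum fragment length, a fragment can touch at most one IES. This makes
the sampler exact as a mixture over three disjoint start categories per
IES: plain MDS background; "IES present" (weight q_i (len_i + l - 1) m_i,
with q_i = (1 - c) p_i); and "excised junction" (weight (1 - q_i)(l - 1)).
The mixture uses the expected per-category weights; this is exact whenever
q_i is 0 or 1 (all calibration scenarios, and the nucleosome-profiling
libraries where the excision machinery is co-silenced) and a close
approximation otherwise (the relative error is bounded by the variance of
the total template weight, which is small at the configured IES densities).

Fragments are emitted pre-aligned, on the MAC+IES stream when contiguous
there (background and IES-present fragments), on the MAC stream when
contiguous there (background and junction fragments). Junction fragments
therefore register as IES- evidence and never as spurious IES overlap --
the single-span analogue of what a split-aware aligner plus block-aware
overlap extraction produce on real data.

What the generator does **not** emulate: sequencing errors and quality
scores, mapping ambiguity and multi-mapping, spliced alignments, chromosome
fragmentation and telomere addition, imprecise TE elimination, nucleosome
positioning/phasing within an IES, and biological correlation between IES
retention across cells. Passing tests therefore demonstrate correctness of
the counting and statistics under idealized alignments, not robustness to
aligner artefacts.

# IES retention counting

Evidence is boundary-anchored with a configurable anchor (default
`min_anchor = 5` bp on each side): on MAC+IES, a fragment adds one unit of
IES+ evidence for each IES boundary it crosses with the anchor satisfied
(0, 1 or 2 units per IES); on MAC, a fragment crossing the excision
junction adds two units of IES- evidence, one per boundary of the excised
IES. Fragments fully inside an IES, or not reaching any boundary, are
uninformative, and no fragment contributes to both categories.

The two-units rule keeps both kinds of evidence on a common per-boundary
scale. Counting fragments once per category instead would accrue IES+
evidence at a rate proportional to (IES length + fragment length - 9) but
IES- evidence at (fragment length - 9), biasing IRS upward, most severely
for long IESs. With per-boundary units both rates are proportional to
2 x (fragment length - 9) x (retention probability or its complement), so
IRS is an unbiased estimator of the per-fragment retention probability for
every IES length -- which is what the estimator-recovery validation
(`irs_recovery_experiment()`) checks, comparing each IES's IRS with its
ground truth at three binomial standard errors of its own informative
count.

IESs with no informative evidence have undefined IRS and are excluded from
summaries, correlations and strata; absence of coverage is not evidence of
excision. Cross-knockdown comparison reports Pearson's r, an ordinary
least-squares fit, and pointy-top hexagonal bin counts (default 25 cells
across the unit square; the resolution is a reproducibility convention, as
is the choice of hexagon orientation).

# Nucleosome density analysis

* **Mononucleosome gating**: properly paired fragments (SAM flag bit 2)
  with outer distance in [125, 175] bp, bounds inclusive. DNA-seq fragments
  are not size-gated (configurable); only the nucleosomal library carries a
  mononucleosome interpretation.
* **Overlap counting**: a fragment counts for an IES at >= 9 bp overlap
  (the absolute-overlap reading of a 6% fractional rule at ~150 bp
  fragments); fragments meeting the threshold for more than one IES are
  discarded as ambiguous rather than double-counted. Delegated to
  `GenomicRanges::findOverlaps(minoverlap = )`.
* **Library matching**: when total mapped nucleosomal fragments differ
  between conditions by more than 2%, the larger library is Bernoulli-
  downsampled by `library_match_fraction()` -- the totals ratio truncated
  (not rounded) to four decimal places, matching how such switches are
  passed to sampling tools. DNA libraries are left unscaled below the
  threshold. The fraction is derived from total mapped reads and applied to
  the fragment stream before counting, so both the per-IES counts and the
  library total are thinned coherently.
* **Densities and strata**: r = (n/N)/(d/D); r is 0 when n = 0 and
  undefined when d = 0, and undefined-density IESs are excluded from
  histograms and KS samples (reported separately in the per-IES tables).
  Strata combine an IRS side (below / at-or-above 0.1, i.e. weakly /
  strongly affected) with an optional inclusive length window, by default
  the first IES length peak 26-31 bp.
* **Histograms**: 40 equal bins on [0, 4], unit-area normalized, with
  values above the last edge pooled into the last bin; bin edges are
  recorded in the outputs.

## KS test

`ks_two_sample()` evaluates the exact statistic -- the supremum of the
absolute ECDF difference over the pooled unique values, which handles ties
-- and an asymptotic two-sided p-value from the Kolmogorov distribution at
effective size n1 n2/(n1 + n2). The statistic, not the p-value, is the
primary contract; the implementation is verified against exhaustive ECDF
maximization on all integer sample pairs up to size 8 over a 5-point grid,
and against the independent reference implementation in `stats::ks.test`.
At stratum sizes around 100-150 the asymptotic p is slightly conservative
(and ties among density ratios add a little more conservatism), so the null
calibration experiment (`ks_null_calibration()`: identical occupancy in
both conditions, 200 replicates over the first-length-peak stratum of a
150-IES genome) is expected to reject somewhat below the nominal 5%, within
the 2-8% band. The length-restricted stratum is used for calibration
because it makes the per-IES density distributions essentially identically
distributed, which is what the two-sample test assumes.

The power scenario (`ks_effect_recovery()`: occupancy doubled on strong
IESs in the knockdown, stratified by a per-replicate IRS at the 0.1 cutoff,
250-IES genome) detects the shift essentially always. Note that boosting
the occupancy of many IESs also inflates the library total, so the whole-
library density ratio between conditions is somewhat below 2; the
within-library contrast between boosted and neutral IESs is exactly the
multiplier, which is how the simulator unit test checks it.

# Small-RNA profiling

Reads are size-selected to 15-45 nt inclusive (a fixed reading of an
approximate gel range) and classified by exact-substring membership on both
strands of each compartment's references, in priority order vector > MDS >
IES > TE > OES. Exact matching replaces a short-read mapper because the
simulated reads are error-free substrings; the tested contract is the
classification and normalization. The priority order is a convention for
multi-compartment hits (unstated in how such histograms are usually
plotted): vector first removes silencing-construct reads, MDS-first is the
conservative choice for the scanning ratio; the order is configurable and
recorded. Normalization divides by the total size-selected input (mapped
plus unassigned). The scanning ratio compares MDS/IES normalized counts at
25 nt between an early and a late sample; a working scanning process lowers
the late ratio, and a scanning defect leaves the fold change near 1.

# Reproducibility and problem sizes

A single master seed drives everything; per-stage seeds are derived by
hashing the stage name, so stages have independent, reproducible streams.
Two pipeline runs with the same configuration are byte-identical, which the
determinism check verifies via MD5 digests of every output file.

Validation problem sizes were chosen once as the package's reference
conditions: the default genome (2 x 100 kb, 500 IESs) with 200k fragments
per library for estimator recovery and the neutral-occupancy identity;
reduced single-contig genomes (150 / 250 IESs, 16k / 25k fragments per
library) for the 200-replicate null calibration and 50-replicate power
experiments, keeping every stratum at or above 100 IESs; 10,000 reads for
the small-RNA mixture; and 50k-fragment libraries for the demo pipeline.

# Known limitations

* The counting rules (anchor, per-boundary units, ambiguity discard) are
  this package's explicit conventions for methods that published tools
  implement with unstated parameters; all are configurable and echoed in
  the run manifest.
* The occupancy multiplier is a free scenario parameter: the literature
  describes IESs qualitatively as nucleosome-poor without a quantitative
  model, so no default effect size is claimed.
* The KS p-value is asymptotic; no exact small-sample enumeration is
  offered beyond the oracle used in testing.
* Real-data import is limited to plain SAM (convert BAM with
  `samtools view -h`), BED-like IES annotations and FASTA references.
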