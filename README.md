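# iesight

Analysis toolkit for programmed DNA elimination in ciliates. During sexual
development, *Paramecium*-like ciliates rebuild their somatic macronucleus
(MAC) from the germline genome, precisely excising tens of thousands of
short, transposon-derived **internally eliminated sequences (IESs)**.
`iesight` implements the three computational assays used to study how
silencing of elimination factors (knockdowns, KD) perturbs this process,
plus a synthetic-data generator so that every stage runs and is tested
without any external data.

**Who it is for:** computational biologists analysing developing-MAC
DNA-seq, nucleosome profiling and small-RNA sequencing against paired
MAC / MAC+IES references, and anyone who needs a fully simulated,
ground-truthed testbed for such pipelines.

## The quantities computed

* **IES retention score.** For IES *i*, reads aligned to the MAC+IES
  reference that cross an IES boundary (with ≥ 5 bp anchor on each side)
  are IES⁺ evidence; reads aligned to the MAC reference that cross the
  excision junction are IES⁻ evidence. The retention score is

  IRS = IES⁺ / (IES⁺ + IES⁻) ∈ [0, 1],

  an unbiased estimate of the per-fragment retention probability.
  Knockdown effects are summarized as the number and percentage of IESs
  with IRS ≥ 0.1, and compared across knockdowns by Pearson correlation,
  OLS regression and hexagonal binning.
* **DNA-seq-normalized nucleosome density.** From a mononucleosomal
  library (properly paired fragments, outer distance 125–175 bp) and a
  total-DNA library, each IES gets

  r = (n/N) ÷ (d/D),

  with n, d the fragments overlapping the IES by ≥ 9 bp and N, D the
  library totals (the larger nucleosomal library is first downsampled by
  the totals ratio truncated to 4 decimals when totals differ by > 2%).
  Distributions of r are compared between conditions within IRS/length
  strata by a two-sample, two-sided Kolmogorov–Smirnov test (α = 0.05).
* **Small-RNA compartment profiles.** Reads of 15–45 nt are classified by
  exact substring membership (both strands; priority vector > MDS > IES >
  TE > OES) and tabulated per length, normalized by total reads — the
  25-nt scnRNA scanning class versus the exclusively IES-matching
  26–31-nt iesRNA class.

## Worked example

Simulate a knockdown scenario (60 IESs, doubled nucleosomal occupancy on
knockdown-sensitive IESs), score retention, and compare nucleosome
densities between weakly and strongly affected IESs:

```r
library(iesight)

cfg <- sim_config(seed = 11L, n_contigs = 1L, contig_length = 30000L,
                  n_ies = 60L, occupancy_kd_strong = 2,
                  n_dna_fragments = 20000L, n_nuc_fragments = 20000L)
built <- build_genome(cfg)
genome <- built$genome
ies_set <- build_interval_set(genome$ies)

## retention scoring from a simulated KD genome-sequencing library
lib <- simulate_dna_fragments(genome, built$truth, cfg, "KD")
scores <- compute_irs(count_retention_reads(lib$mac_ies, lib$mac, ies_set))
summ <- summarize_retention(scores, cutoff = 0.1)
#> KD: 37 of 60 IESs with IRS >= 0.1 (61.7%)

## nucleosome density with the excision machinery co-silenced
nl <- simulate_nucleosomal_fragments(genome, built$truth, cfg, "KD")
dl <- simulate_dna_fragments(genome, built$truth, cfg, "KD", retain_all = TRUE)
nuc <- select_mononucleosomal(nl$mac_ies)
oc_n <- count_fragment_overlaps(nuc, ies_set)
oc_d <- count_fragment_overlaps(dl$mac_ies, ies_set)
dens <- density_table(oc_n$counts, oc_d$counts,
                      oc_n$total_mapped, oc_d$total_mapped, "KD")
r_weak <- stratify_densities(dens, scores, stratum_spec(0.1, "below"), genome$ies)
r_strong <- stratify_densities(dens, scores, stratum_spec(0.1, "at_or_above"), genome$ies)
ks_two_sample(r_weak, r_strong)
#> two-sample KS: D = 0.9565, p = 1.07e-11 (n1 = 23, n2 = 37)
median(r_weak); median(r_strong)
#> 0.79; 1.642
```

61.7% of IESs exceed the retention cutoff, matching the simulated 65%
knockdown-sensitive fraction; the strongly affected stratum shows roughly
double the median normalized nucleosome density of the weak stratum,
recovering the simulated occupancy multiplier, and the KS test separates
the two distributions decisively.

`run_pipeline(demo_config(), "out/")` runs every stage end to end
(genome, SAM/FASTA/BED outputs, IRS tables, density strata, KS summary,
sRNA profiles) and writes a `manifest.json` recording every threshold,
seed and output digest. Identical seeds reproduce byte-identical outputs.

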