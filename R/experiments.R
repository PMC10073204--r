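# Pre-specified simulation experiments: statistical calibration and
# parameter-recovery scenarios built from the package's own stages. They
# serve as the package's validation surface (run by the test suite and the
# acceptance script) and as worked examples of composing the stages.

#' Scenario: KS null calibration
#'
#' A single-contig genome with 150 IESs, no maternal-MAC contamination and
#' identical (neutral) occupancy in both conditions. With both conditions
#' simulated from the same generative model, the two-sample KS test on the
#' density samples of the first IES length peak should reject at close to
#' its nominal level.
#'
#' @param seed master seed.
#' @export
null_calibration_config <- function(seed = 1L) {
  sim_config(seed = seed, n_contigs = 1L, contig_length = 45000L,
             n_ies = 150L, contamination_fraction = 0,
             n_dna_fragments = 16000L, n_nuc_fragments = 16000L)
}

#' Scenario: occupancy-effect recovery
#'
#' A single-contig genome with 250 IESs; strong (knockdown-sensitive) IESs
#' carry a doubled nucleosomal occupancy in the knockdown condition, so the
#' KS comparison of the strongly-affected stratum should reject.
#'
#' @param seed master seed.
#' @export
effect_recovery_config <- function(seed = 1L) {
  sim_config(seed = seed, n_contigs = 1L, contig_length = 75000L,
             n_ies = 250L, contamination_fraction = 0,
             occupancy_kd_strong = 2,
             n_dna_fragments = 25000L, n_nuc_fragments = 25000L)
}

# One density contrast: simulate nucleosomal + DNA libraries for both
# conditions (excision co-silenced), count, and return per-condition
# density tables.
.density_contrast <- function(genome, truth, config, ies_set, rep_seed,
                              min_outer = 125L, max_outer = 175L,
                              min_overlap = 9L) {
  dens <- list()
  for (cond in c("EV_control", "KD")) {
    nl <- simulate_nucleosomal_fragments(
      genome, truth, config, cond,
      seed = derive_seed(rep_seed, paste0("nuc_", cond)))
    dl <- simulate_dna_fragments(
      genome, truth, config, cond, retain_all = TRUE,
      seed = derive_seed(rep_seed, paste0("dnaP_", cond)))
    nuc <- select_mononucleosomal(nl$mac_ies, min_outer, max_outer)
    oc_n <- count_fragment_overlaps(nuc, ies_set, min_overlap)
    oc_d <- count_fragment_overlaps(dl$mac_ies, ies_set, min_overlap)
    dens[[cond]] <- density_table(oc_n$counts, oc_d$counts,
                                  oc_n$total_mapped, oc_d$total_mapped, cond)
  }
  dens
}

#' KS rejection rate under the null (identical occupancy)
#'
#' Builds the scenario genome once, then repeatedly resimulates all four
#' sequencing libraries, recomputes densities, and tests the first-length-
#' peak stratum with the two-sample KS test. Under the null the rejection
#' rate should be close to `alpha`.
#'
#' @param n_reps number of replicates (default 200).
#' @param alpha rejection level (default 0.05).
#' @param seed master seed.
#' @param config scenario configuration.
#' @return list with `rate`, `n_reps`, `alpha`, `stratum_size`.
#' @export
ks_null_calibration <- function(n_reps = 200L, alpha = 0.05, seed = 1L,
                                config = null_calibration_config(seed)) {
  built <- build_genome(config)
  genome <- built$genome; truth <- built$truth
  ies_set <- build_interval_set(genome$ies)
  all_in <- data.frame(ies_id = truth$ies_id, irs = 1)  # stratify by length only
  spec <- stratum_spec(0, "at_or_above", length_range = c(26L, 31L))
  reject <- logical(n_reps)
  sizes <- integer(n_reps)
  for (i in seq_len(n_reps)) {
    dens <- .density_contrast(genome, truth, config, ies_set,
                              rep_seed = derive_seed(seed, paste0("null", i)))
    re <- stratify_densities(dens$EV_control, all_in, spec, truth)
    rp <- stratify_densities(dens$KD, all_in, spec, truth)
    ks <- ks_two_sample(re, rp)
    reject[i] <- ks$p_value < alpha
    sizes[i] <- min(ks$n1, ks$n2)
  }
  list(rate = mean(reject), n_reps = n_reps, alpha = alpha,
       stratum_size = min(sizes))
}

#' KS rejection rate under a doubled-occupancy effect
#'
#' Per replicate: a knockdown genome-sequencing library yields the IRS used
#' for stratification; four density libraries are simulated with doubled
#' occupancy on strong IESs in the knockdown; the strongly-affected stratum
#' (IRS >= cutoff) is compared between conditions with the KS test.
#'
#' @inheritParams ks_null_calibration
#' @param irs_cutoff stratification cutoff (default 0.1).
#' @export
ks_effect_recovery <- function(n_reps = 50L, alpha = 0.05, seed = 1L,
                               irs_cutoff = 0.1,
                               config = effect_recovery_config(seed)) {
  built <- build_genome(config)
  genome <- built$genome; truth <- built$truth
  ies_set <- build_interval_set(genome$ies)
  spec <- stratum_spec(irs_cutoff, "at_or_above")
  reject <- logical(n_reps)
  sizes <- integer(n_reps)
  for (i in seq_len(n_reps)) {
    rep_seed <- derive_seed(seed, paste0("effect", i))
    lib <- simulate_dna_fragments(genome, truth, config, "KD",
                                  seed = derive_seed(rep_seed, "irs_lib"))
    scores <- compute_irs(count_retention_reads(lib$mac_ies, lib$mac, ies_set))
    dens <- .density_contrast(genome, truth, config, ies_set, rep_seed)
    re <- stratify_densities(dens$EV_control, scores, spec, truth)
    rp <- stratify_densities(dens$KD, scores, spec, truth)
    ks <- ks_two_sample(re, rp)
    reject[i] <- ks$p_value < alpha
    sizes[i] <- min(ks$n1, ks$n2)
  }
  list(rate = mean(reject), n_reps = n_reps, alpha = alpha,
       stratum_size = min(sizes))
}

#' IRS estimator recovery against ground truth
#'
#' Every IES draws a true retention probability uniformly from
#' `retention_range`; a deep knockdown genome-sequencing library is
#' simulated without contamination, retention is counted, and each IES's IRS
#' is compared with its truth at three binomial standard errors (computed
#' from its own informative evidence count).
#'
#' @param seed master seed.
#' @param retention_range range of true per-IES retention probabilities.
#' @param n_fragments library size.
#' @return list with `fraction_within` (of IESs within 3 SE),
#'   `n_ies`, `median_informative`.
#' @export
irs_recovery_experiment <- function(seed = 1L, retention_range = c(0.1, 0.9),
                                    n_fragments = 200000L) {
  config <- sim_config(seed = seed, strong_fraction = 1,
                       retention_kd_strong = retention_range,
                       contamination_fraction = 0,
                       n_dna_fragments = n_fragments)
  built <- build_genome(config)
  genome <- built$genome; truth <- built$truth
  ies_set <- build_interval_set(genome$ies)
  lib <- simulate_dna_fragments(genome, truth, config, "KD")
  scores <- compute_irs(count_retention_reads(lib$mac_ies, lib$mac, ies_set))
  m <- merge(scores, truth[c("ies_id", "retention_KD")], by = "ies_id")
  n_inf <- m$n_plus + m$n_minus
  ok <- n_inf > 0L
  p <- m$retention_KD[ok]
  se <- sqrt(p * (1 - p) / n_inf[ok])
  within <- abs(m$irs[ok] - p) <= 3 * se
  list(fraction_within = mean(within), n_ies = sum(ok),
       median_informative = stats::median(n_inf[ok]))
}

#' Neutral-occupancy density identity
#'
#' With occupancy 1 everywhere, no contamination and all IESs present, the
#' DNA-seq-normalized nucleosome density should concentrate around 1; the
#' experiment reports the median r over IESs with DNA coverage d >= 20.
#'
#' @param seed master seed.
#' @param n_fragments fragments per library.
#' @param min_d minimum DNA count for an IES to enter the median.
#' @export
neutral_density_experiment <- function(seed = 1L, n_fragments = 200000L,
                                       min_d = 20L) {
  config <- sim_config(seed = seed, contamination_fraction = 0,
                       n_dna_fragments = n_fragments,
                       n_nuc_fragments = n_fragments)
  built <- build_genome(config)
  genome <- built$genome; truth <- built$truth
  ies_set <- build_interval_set(genome$ies)
  nl <- simulate_nucleosomal_fragments(genome, truth, config, "EV_control")
  dl <- simulate_dna_fragments(genome, truth, config, "EV_control",
                               retain_all = TRUE)
  nuc <- select_mononucleosomal(nl$mac_ies)
  oc_n <- count_fragment_overlaps(nuc, ies_set)
  oc_d <- count_fragment_overlaps(dl$mac_ies, ies_set)
  dens <- density_table(oc_n$counts, oc_d$counts, oc_n$total_mapped,
                        oc_d$total_mapped, "EV_control")
  keep <- dens$d >= min_d
  list(median_r = stats::median(dens$r[keep]), n_ies = sum(keep))
}

#' Small-RNA mixture recovery
#'
#' Simulates the default small-RNA mixture (30\% iesRNA-class reads of
#' 26-31 nt drawn exclusively from IESs) and recovers the classified
#' IES-matching 26-31-nt fraction, plus the mass any other compartment
#' carries in that length range (structurally zero).
#'
#' @param seed master seed.
#' @param n_reads library size.
#' @export
srna_recovery_experiment <- function(seed = 1L, n_reads = 10000L) {
  config <- sim_config(seed = seed)
  built <- build_genome(config)
  genome <- built$genome
  reads <- simulate_srna_reads(genome, config, n = n_reads)
  profile <- build_profile(size_select(reads), compartment_references(genome))
  in_peak <- profile$length >= 26L & profile$length <= 31L
  ies_frac <- sum(profile$normalized[in_peak & profile$compartment == "IES"])
  other <- sum(profile$normalized[in_peak & !profile$compartment %in%
                                    c("IES", "unassigned")])
  unassigned <- sum(profile$normalized[in_peak &
                                         profile$compartment == "unassigned"])
  list(ies_fraction = ies_frac, other_fraction = other,
       unassigned_fraction = unassigned,
       true_fraction = unname(config$srna_mixture["iesRNA"]),
       n_reads = n_reads)
}

#' Pipeline determinism check
#'
#' Runs the demo pipeline twice with the same seed into fresh directories
#' and compares the MD5 digests of every output file.
#'
#' @param seed master seed.
#' @param config pipeline configuration (default [demo_config()]).
#' @return list with `identical` (logical), `n_files`, and the two digest
#'   sets.
#' @export
check_pipeline_determinism <- function(seed = 17L, config = demo_config(seed)) {
  d1 <- tempfile("run1_"); d2 <- tempfile("run2_")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  m1 <- run_pipeline(config, d1, seed = seed)
  m2 <- run_pipeline(config, d2, seed = seed)
  list(identical = identical(m1$file_md5, m2$file_md5),
       n_files = length(m1$file_md5),
       digests1 = m1$file_md5, digests2 = m2$file_md5)
}
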