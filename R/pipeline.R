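# End-to-end orchestration: simulate -> IRS -> nucleosome density -> sRNA,
# with a machine-readable run manifest.

#' Demo configuration
#'
#' The default simulation scenario at a library scale suited to an
#' interactive demonstration (the genome scale is unchanged; library sizes
#' are reduced from the reference 200k to 50k fragments per library).
#'
#' @param seed master seed.
#' @export
demo_config <- function(seed = 17L) {
  sim_config(seed = seed,
             occupancy_kd_strong = 2,
             n_dna_fragments = 50000L,
             n_nuc_fragments = 50000L)
}

#' Run the full analysis pipeline on simulated inputs
#'
#' Stages, in dependency order:
#' \enumerate{
#'   \item build the synthetic genome pair; write MAC / MAC+IES / TE / OES /
#'     vector FASTA, the IES BED annotation and the ground-truth TSV;
#'   \item simulate genome-sequencing DNA libraries for the EV control and
#'     the knockdown, written as SAM against both references;
#'   \item compute per-IES retention scores for both conditions from the SAM
#'     files, summarize them against the IRS cutoff, and correlate the two
#'     conditions;
#'   \item simulate nucleosomal and DNA libraries for both conditions with
#'     the excision machinery co-silenced (all IESs present), gate
#'     mononucleosomal fragments, count IES overlaps, downsample the larger
#'     nucleosomal library when totals differ by more than
#'     `library_match_tolerance`, compute DNA-seq-normalized densities, and
#'     compare strata with two-sample KS tests;
#'   \item simulate early and late small-RNA samples and profile them by
#'     compartment.
#' }
#' Identical `config` and `seed` reproduce byte-identical outputs.
#'
#' @param config a [sim_config()]; defaults to [demo_config()].
#' @param outdir output directory (created if needed).
#' @param seed master seed; overrides `config$seed` when given.
#' @param irs_cutoff IRS cutoff separating weakly / strongly affected IESs.
#' @param min_anchor retention-counting anchor (bp).
#' @param min_outer,max_outer mononucleosome outer-distance gate (bp).
#' @param min_overlap minimum fragment/IES overlap (bp).
#' @param length_peak inclusive length range of the first IES length peak.
#' @param library_match_tolerance relative difference of nucleosomal library
#'   totals above which the larger library is downsampled.
#' @param srna_range small-RNA size-selection bounds (nt).
#' @return the run manifest (also written as `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config = demo_config(), outdir, seed = NULL,
                         irs_cutoff = 0.1, min_anchor = 5L,
                         min_outer = 125L, max_outer = 175L,
                         min_overlap = 9L, length_peak = c(26L, 31L),
                         library_match_tolerance = 0.02,
                         srna_range = c(15L, 45L)) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(outdir, ...)

  ## stage 1: genome
  built <- build_genome(config)
  genome <- built$genome; truth <- built$truth
  write_fasta(genome$mac, pth("mac.fa"))
  write_fasta(genome$mac_ies, pth("mac_ies.fa"))
  write_fasta(genome$aux$TE, pth("te.fa"))
  write_fasta(genome$aux$OES, pth("oes.fa"))
  write_fasta(genome$aux$vector, pth("vector.fa"))
  write_ies_bed(genome$ies, pth("ies.bed"))
  data.table::fwrite(truth, pth("ground_truth.tsv"), sep = "\t")
  ies_set <- build_interval_set(genome$ies)
  len_macies <- Biostrings::width(genome$mac_ies)
  names(len_macies) <- names(genome$mac_ies)
  len_mac <- Biostrings::width(genome$mac)
  names(len_mac) <- names(genome$mac)

  ## stage 2 + 3: genome-seq libraries and IRS
  scores <- list()
  for (cond in c("EV_control", "KD")) {
    lib <- simulate_dna_fragments(genome, truth, config, cond)
    write_sam(lib$mac_ies, len_macies, pth(sprintf("dna_%s.mac_ies.sam", cond)),
              read_length = config$read_length,
              reference_seqs = as.character(genome$mac_ies))
    write_sam(lib$mac, len_mac, pth(sprintf("dna_%s.mac.sam", cond)),
              read_length = config$read_length,
              reference_seqs = as.character(genome$mac))
    al_plus <- read_alignments(pth(sprintf("dna_%s.mac_ies.sam", cond)), cond)
    al_minus <- read_alignments(pth(sprintf("dna_%s.mac.sam", cond)), cond)
    sc <- compute_irs(count_retention_reads(al_plus, al_minus, ies_set,
                                            min_anchor = min_anchor))
    write_irs_tsv(sc, pth(sprintf("irs_%s.tsv", cond)))
    scores[[cond]] <- sc
  }
  summ <- summarize_retention(scores$KD, cutoff = irs_cutoff)
  corr <- correlate_irs(scores$EV_control, scores$KD)
  data.table::fwrite(
    data.frame(condition = "KD", cutoff = irs_cutoff,
               n_defined = summ$n_defined, n_retained = summ$count,
               pct_retained = summ$percentage,
               pearson_r_vs_EV = corr$pearson_r,
               ols_slope = corr$ols_slope, ols_intercept = corr$ols_intercept,
               n_pairs = corr$n_pairs),
    pth("irs_summary.tsv"), sep = "\t")

  ## stage 4: nucleosome density
  nuc <- list(); dna <- list()
  for (cond in c("EV_control", "KD")) {
    n_nuc <- if (cond == "KD") {
      as.integer(round(config$n_nuc_fragments * config$nuc_library_imbalance))
    } else config$n_nuc_fragments
    nl <- simulate_nucleosomal_fragments(genome, truth, config, cond, n = n_nuc)
    dl <- simulate_dna_fragments(genome, truth, config, cond, retain_all = TRUE)
    write_sam(nl$mac_ies, len_macies, pth(sprintf("nuc_%s.mac_ies.sam", cond)),
              read_length = config$read_length,
              reference_seqs = as.character(genome$mac_ies))
    write_sam(dl$mac_ies, len_macies,
              pth(sprintf("dna_pgm_%s.mac_ies.sam", cond)),
              read_length = config$read_length,
              reference_seqs = as.character(genome$mac_ies))
    nuc[[cond]] <- select_mononucleosomal(
      read_alignments(pth(sprintf("nuc_%s.mac_ies.sam", cond)), cond),
      min_outer, max_outer)
    dna[[cond]] <- read_alignments(pth(sprintf("dna_pgm_%s.mac_ies.sam", cond)),
                                   cond)
  }
  totals <- vapply(nuc, nrow, integer(1))
  down_fraction <- NA_real_
  if (abs(diff(totals)) / min(totals) > library_match_tolerance) {
    larger <- names(totals)[which.max(totals)]
    down_fraction <- library_match_fraction(min(totals), max(totals))
    nuc[[larger]] <- downsample_fragments(nuc[[larger]], down_fraction,
                                          seed = derive_seed(config$seed,
                                                             "downsample"))
  }
  dens <- list()
  for (cond in c("EV_control", "KD")) {
    oc_n <- count_fragment_overlaps(nuc[[cond]], ies_set, min_overlap)
    oc_d <- count_fragment_overlaps(dna[[cond]], ies_set, min_overlap)
    dens[[cond]] <- density_table(oc_n$counts, oc_d$counts,
                                  N = oc_n$total_mapped, D = oc_d$total_mapped,
                                  cond)
    data.table::fwrite(as.data.frame(dens[[cond]]),
                       pth(sprintf("density_%s.tsv", cond)), sep = "\t")
  }
  strata <- list(
    stratum_spec(irs_cutoff, "below"),
    stratum_spec(irs_cutoff, "at_or_above"),
    stratum_spec(irs_cutoff, "below", length_peak),
    stratum_spec(irs_cutoff, "at_or_above", length_peak))
  ks_tab <- ks_by_stratum(dens$EV_control, dens$KD, scores$KD, strata,
                          genome$ies)
  data.table::fwrite(ks_tab, pth("ks_summary.tsv"), sep = "\t")
  for (si in seq_along(strata)) {
    for (cond in c("EV_control", "KD")) {
      rv <- stratify_densities(dens[[cond]], scores$KD, strata[[si]],
                               genome$ies)
      hg <- histogram_densities(rv)
      data.table::fwrite(hg, pth(sprintf("hist_stratum%d_%s.tsv", si, cond)),
                         sep = "\t")
    }
  }

  ## stage 5: small RNA
  mx_late <- config$srna_mixture
  mx_early <- mx_late
  mx_early["iesRNA"] <- 0
  mx_early["MDS_25"] <- mx_early["MDS_25"] + mx_late[["iesRNA"]]
  refs <- compartment_references(genome)
  reads_early <- simulate_srna_reads(genome, config, mixture = mx_early,
                                     seed = derive_seed(config$seed, "srna_early"))
  reads_late <- simulate_srna_reads(genome, config,
                                    seed = derive_seed(config$seed, "srna_late"))
  write_srna_fasta(reads_early, pth("srna_early.fa"))
  write_srna_fasta(reads_late, pth("srna_late.fa"))
  prof_early <- build_profile(size_select(reads_early, srna_range[1], srna_range[2]),
                              refs)
  prof_late <- build_profile(size_select(reads_late, srna_range[1], srna_range[2]),
                             refs)
  write_profile_tsv(prof_early, pth("srna_profile_early.tsv"))
  write_profile_tsv(prof_late, pth("srna_profile_late.tsv"))
  scan <- scanning_ratio(prof_early, prof_late)

  ## manifest
  files <- sort(list.files(outdir, pattern = "\\.(tsv|sam|fa|bed)$"))
  digests <- as.list(tools::md5sum(file.path(outdir, files)))
  names(digests) <- files
  manifest <- list(
    tool = "iesight",
    version = as.character(utils::packageVersion("iesight")),
    seed = config$seed,
    parameters = list(
      irs_cutoff = irs_cutoff, min_anchor = min_anchor,
      mononucleosome_outer_distance = c(min_outer, max_outer),
      min_overlap_bp = min_overlap, ies_length_peak = length_peak,
      library_match_tolerance = library_match_tolerance,
      nucleosomal_downsample_fraction = down_fraction,
      srna_size_range = srna_range, ks_alpha = 0.05),
    config = unclass(config)[!vapply(unclass(config), is.data.frame, logical(1))],
    ies_length_classes = config$ies_length_classes,
    scanning_ratio = scan,
    file_md5 = digests)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(manifest)
}
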