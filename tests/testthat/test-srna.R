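# Handcrafted compartment references for classification tests. Sequences
# are chosen so membership across compartments is fully controlled.
.toy_refs <- function() {
  list(vector = "GGGGGGGGGGGGGGGGGGGGGGGGGGGGGG",
       MDS = "ACGTACGTACGTACGTACGTACGTACGTAC",
       IES = c("TATTTTTTTTTTTTTTTTTTTTTTTTTTTA",
               "TACCCCCCCCCCCCCCCCCCCCCCCCCCTA"),
       TE = "AGAGAGAGAGAGAGAGAGAGAGAGAGAGAG",
       OES = "CTCTCTCTCTCTCTCTCTCTCTCTCTCTCT")
}

.reads <- function(seqs) {
  data.frame(read_id = sprintf("r%02d", seq_along(seqs)), sequence = seqs,
             length = nchar(seqs), stringsAsFactors = FALSE)
}

test_that("size selection keeps the inclusive 15-45 nt window", {
  reads <- .reads(vapply(10:50, function(n) strrep("A", n), character(1)))
  kept <- size_select(reads)
  expect_equal(range(kept$length), c(15L, 45L))
  expect_equal(nrow(kept), 31L)
  expect_equal(nrow(kept) / nrow(reads), 31 / 41)
  expect_equal(nrow(size_select(reads[0, ])), 0L)
})

test_that("classification follows substring membership, strand and priority", {
  refs <- .toy_refs()
  lab <- classify_reads(.reads(c(
    "TTTTTTTTTTTTTTTTTTTTTTTTT",   # only inside IES 1            -> IES
    "ACGTACGTACGTACGTACGTACGTA",   # MAC substring                -> MDS
    "TACGTACGTACGTACGTACGTACGT",   # revcomp of a MAC substring   -> MDS
    "GGGGGGGGGGGGGGGGGGGGGGGGG",   # vector beats everything      -> vector
    "AGAGAGAGAGAGAGAGAGAGAGAGA",   # TE (revcomp also matches TE) -> TE
    "TGCATGCATGCATGCATGCATGCAT")), # matches nothing              -> unassigned
    refs)
  expect_equal(lab, c("IES", "MDS", "MDS", "vector", "TE", "unassigned"))

  # a read present in both MDS and IES resolves to MDS by priority
  both <- classify_reads(.reads("ACGTACGTACGTACGTACGTACGTAC"),
                         list(MDS = refs$MDS, IES = refs$MDS))
  expect_equal(both, "MDS")

  expect_error(classify_reads(.reads("ACGT"), list()), "empty reference")
})

test_that("profiles conserve reads per length and normalize by total input", {
  refs <- .toy_refs()
  seqs <- c(rep(substr(refs$MDS, 1, 25), 3),
            rep(substr(refs$IES[1], 1, 28), 2),
            "TGCATGCATGCATGCATGCATGCAT")
  prof <- build_profile(.reads(seqs), refs)
  expect_equal(attr(prof, "total_reads"), 6L)
  expect_equal(sum(prof$count), 6L)
  # conservation at each length: compartments + unassigned = reads of that length
  expect_equal(sum(prof$count[prof$length == 25L]), 4L)
  expect_equal(sum(prof$count[prof$length == 28L]), 2L)
  expect_equal(sum(prof$normalized), 1)
  expect_equal(sum(prof$normalized[prof$compartment == "IES"]), 2 / 6)

  # classification is independent of read order
  shuffled <- build_profile(.reads(rev(seqs)), refs)
  expect_equal(prof$count, shuffled$count)
})

test_that("scanning ratio compares MDS/IES 25-nt balance across time points", {
  refs <- .toy_refs()
  mk <- function(n_mds, n_ies) {
    .reads(c(rep(substr(refs$MDS, 1, 25), n_mds),
             rep(substr(refs$IES[1], 3, 27), n_ies)))
  }
  early <- build_profile(mk(40, 20), refs)
  late_same <- build_profile(mk(40, 20), refs)
  expect_equal(scanning_ratio(early, late_same)$fold_change, 1)
  late_half <- build_profile(mk(20, 20), refs)
  sc <- scanning_ratio(early, late_half)
  expect_equal(sc$ratio_early, 2)
  expect_equal(sc$ratio_late, 1)
  expect_equal(sc$fold_change, 0.5)
  no_ies <- build_profile(mk(10, 0), refs)
  expect_true(is.na(scanning_ratio(early, no_ies)$ratio_late))
})

test_that("simulated sRNA mixtures are recovered by classification", {
  cfg <- tiny_config(n_srna_reads = 2000L)
  built <- build_genome(cfg)
  reads <- simulate_srna_reads(built$genome, cfg)
  expect_true(all(nchar(reads$sequence) == reads$length))
  refs <- compartment_references(built$genome)
  prof <- build_profile(size_select(reads), refs)
  in_peak <- prof$length >= 26L & prof$length <= 31L
  ies_frac <- sum(prof$normalized[in_peak & prof$compartment == "IES"])
  expect_lt(abs(ies_frac - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
  # iesRNA lengths are exclusively IES-matching
  expect_equal(sum(prof$count[in_peak & !prof$compartment %in%
                                c("IES", "unassigned")]), 0L)

  # no iesRNA class -> no 26-31 nt reads at all
  mx <- cfg$srna_mixture; mx["iesRNA"] <- 0; mx["MDS_25"] <- mx[["MDS_25"]] + 0.3
  r2 <- simulate_srna_reads(built$genome, cfg, mixture = mx)
  expect_equal(sum(r2$length >= 26), 0L)

  # ground-truth labels agree with classification up to priority collisions
  lab <- classify_reads(reads, refs)
  informative <- lab != "unassigned" & reads$compartment == lab
  expect_gt(mean(informative), 0.95)
})
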