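test_that("read_fasta parses, folds case and enforces the DNA alphabet", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT"), p)
  x <- read_fasta(p)
  expect_equal(as.character(x), c(c1 = "ACGT"))

  writeLines(c(">c1", "ac", "gt"), p)
  expect_equal(as.character(read_fasta(p)), c(c1 = "ACGT"))

  writeLines(c(">c1", "ACGN"), p)
  expect_error(read_fasta(p), "outside A/C/G/T")

  writeLines(c(">c1", "ACGT", ">c1", "GGGG"), p)
  expect_error(read_fasta(p), "duplicate")

  expect_error(read_fasta(tempfile()), "no such file")
})

test_that("fasta round-trips through write_fasta", {
  p <- tempfile(fileext = ".fa")
  seqs <- c(a = "ACGTACGT", b = paste(rep("GATTACA", 30), collapse = ""))
  write_fasta(seqs, p)
  expect_equal(as.character(read_fasta(p)), seqs)
})

test_that("build_interval_set sorts, validates and round-trips through BED", {
  ies <- data.frame(contig_id = c("c2", "c1", "c1"),
                    start = c(50L, 300L, 100L), end = c(70L, 350L, 140L),
                    ies_id = c("i3", "i2", "i1"))
  iv <- build_interval_set(ies)
  expect_equal(iv$feature_id, c("i1", "i2", "i3"))
  expect_true(all(diff(iv$start[iv$reference_id == "c1"]) > 0))

  expect_equal(nrow(build_interval_set(ies[0, ])), 0L)

  bad <- data.frame(contig_id = "c1", start = c(0L, 10L), end = c(20L, 30L),
                    ies_id = c("a", "b"))
  expect_error(build_interval_set(bad), "overlapping")

  p <- tempfile(fileext = ".bed")
  write_ies_bed(iv, p)
  expect_equal(read_ies_bed(p), iv)
})

test_that("genome_pair rejects inconsistent MAC / MAC+IES assemblies", {
  mac <- Biostrings::DNAStringSet(c(c1 = "AAAATTTTGGGG"))
  good_ies <- data.frame(ies_id = "i1", contig_id = "c1",
                         mac_insertion_point = 4L, length = 6L,
                         start = 4L, end = 10L, sequence = "TACGTA")
  mac_ies <- Biostrings::DNAStringSet(c(c1 = "AAAATACGTATTTTGGGG"))
  gp <- genome_pair(mac, mac_ies, good_ies)
  expect_s3_class(gp, "GenomePair")
  # corrupt the insertion: excision no longer reproduces MAC
  bad <- Biostrings::DNAStringSet(c(c1 = "AAATTACGTATTTTGGGG"))
  expect_error(genome_pair(mac, bad, good_ies), "does not reproduce MAC")
})

test_that("synthetic genome honours spacing, TA convention and coordinates", {
  built <- build_genome(tiny_config())
  g <- built$genome
  expect_equal(sum(Biostrings::width(g$mac_ies)),
               sum(Biostrings::width(g$mac)) + sum(g$ies$length))
  # IES sequences begin and end with TA
  expect_true(all(startsWith(g$ies$sequence, "TA")))
  expect_true(all(endsWith(g$ies$sequence, "TA")))
  # spacing between insertion points
  expect_true(all(diff(g$ies$mac_insertion_point) >= 200L))
  # IES span sequence on MAC+IES equals the recorded sequence
  full <- as.character(g$mac_ies[[1]])
  extracted <- substring(full, g$ies$start + 1L, g$ies$end)
  expect_equal(extracted, g$ies$sequence)
  # coordinate map round-trip on MDS positions
  mds <- setdiff(0:4999, unlist(Map(seq, g$ies$start, g$ies$end - 1L)))
  ctg <- g$ies$contig_id[1]
  back <- mac_to_macies(g, ctg, macies_to_mac(g, ctg, mds))
  expect_equal(back, mds)
  # positions inside IESs have no MAC image
  expect_true(all(is.na(macies_to_mac(g, ctg, g$ies$start[1] + 0:2))))
})

test_that("genome build is deterministic and n_ies = 0 collapses the pair", {
  a <- build_genome(tiny_config())
  b <- build_genome(tiny_config())
  expect_identical(as.character(a$genome$mac_ies), as.character(b$genome$mac_ies))
  expect_identical(a$truth, b$truth)

  z <- build_genome(tiny_config(n_ies = 0L))
  expect_identical(as.character(z$genome$mac), as.character(z$genome$mac_ies))
  expect_equal(nrow(z$genome$ies), 0L)
})

test_that("IES length distribution matches the configured classes", {
  built <- build_genome(sim_config(seed = 11L))
  len <- built$truth$length
  expect_equal(length(len), 500L)
  # first-peak class weight 0.7: binomial oracle at 3 SE
  in_peak <- mean(len >= 26 & len <= 31)
  expect_lt(abs(in_peak - 0.7), 3 * sqrt(0.7 * 0.3 / 500))
  # emulation fidelity: sub-nucleosomal fraction within 0.03 of target
  expect_lt(abs(mean(len < 147) - 0.93), 0.03)
  # mode of the realized histogram lies inside the first peak
  expect_true(as.integer(names(which.max(table(len)))) %in% 26:31)
})

test_that("infeasible IES placement is rejected", {
  expect_error(build_genome(tiny_config(n_ies = 200L)),
               "too large for contig_length")
  expect_error(sim_config(ies_length_classes = data.frame(
    min = 26L, max = 31L, weight = 1), frac_subnucleosomal = 0.93),
    "disagree")
  expect_error(sim_config(srna_mixture = c(MDS_25 = 0.5, iesRNA = 0.4)),
               "sum to 1")
})
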