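# Shared fixtures: everything is generated in code at test time.

tiny_config <- function(seed = 42L, ...) {
  defaults <- list(seed = seed, n_contigs = 1L, contig_length = 20000L,
                   n_ies = 30L, n_dna_fragments = 4000L,
                   n_nuc_fragments = 4000L, contamination_fraction = 0,
                   n_srna_reads = 500L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

frag_df <- function(start, end, reference_id = "contig_01",
                    read_id = sprintf("r%04d", seq_along(start)),
                    properly_paired = TRUE, condition_label = "EV_control") {
  n <- length(start)
  data.frame(read_id = rep_len(read_id, n),
             reference_id = rep_len(reference_id, n),
             start = as.integer(start), end = as.integer(end),
             outer_distance = as.integer(end - start),
             properly_paired = rep_len(properly_paired, n),
             condition_label = rep_len(condition_label, n),
             stringsAsFactors = FALSE)
}

# Independent brute-force oracle for the two-sample KS statistic: evaluate
# the ECDF difference by direct counting at every pooled observation.
ks_brute_stat <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# Write SAM lines to a temp file and return the path.
write_sam_text <- function(lines, sq = "@SQ\tSN:chr1\tLN:100000") {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", sq, lines), path)
  path
}
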