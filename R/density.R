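# DNA-seq-normalized nucleosome densities over IESs.
#
# For one condition with N total mapped nucleosomal fragments and D total
# mapped DNA fragments, an IES with n nucleosomal and d DNA fragments
# overlapping it by at least `min_overlap` bp gets the dimensionless density
#     r = (n / N) / (d / D),
# undefined when d = 0. The implicit per-bp length normalizations of the two
# rates cancel in the division.

#' Select mononucleosomal fragments
#'
#' Keeps properly paired fragments with outer distance inside
#' `[min_outer, max_outer]` (inclusive bounds; defaults 125-175 bp, the range
#' expected for mononucleosomes).
#'
#' @param fragments fragment data.frame (see [read_alignments()]).
#' @param min_outer,max_outer inclusive outer-distance gate in bp.
#' @return the gated data.frame, with integer attributes `kept` and
#'   `dropped`.
#' @export
select_mononucleosomal <- function(fragments, min_outer = 125L,
                                   max_outer = 175L) {
  stopifnot(min_outer <= max_outer)
  keep <- fragments$properly_paired &
    fragments$outer_distance >= min_outer &
    fragments$outer_distance <= max_outer
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kept") <- sum(keep)
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Count fragments overlapping IESs
#'
#' A fragment is counted for an IES when their overlap is at least
#' `min_overlap` bp. Fragments meeting the threshold for more than one IES
#' are discarded as ambiguous and reported. Overlap detection is delegated
#' to [GenomicRanges::findOverlaps()].
#'
#' @param fragments fragment data.frame on the MAC+IES reference.
#' @param ies_set an [build_interval_set()].
#' @param min_overlap minimum overlap in bp (default 9).
#' @return list with `counts` (data.frame `feature_id`, `count`),
#'   `total_mapped` (fragments in the input stream, for library totals) and
#'   `ambiguous` (discarded fragment count).
#' @export
count_fragment_overlaps <- function(fragments, ies_set, min_overlap = 9L) {
  stopifnot(min_overlap >= 1L)
  iv <- build_interval_set(ies_set)
  if (nrow(iv) == 0L) stop("empty interval set")
  frag_gr <- GenomicRanges::GRanges(
    fragments$reference_id,
    IRanges::IRanges(start = fragments$start + 1L, end = fragments$end))
  ies_gr <- GenomicRanges::GRanges(
    iv$reference_id, IRanges::IRanges(start = iv$start + 1L, end = iv$end))
  hits <- GenomicRanges::findOverlaps(frag_gr, ies_gr,
                                      minoverlap = as.integer(min_overlap))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  multi <- unique(qh[duplicated(qh)])
  keep <- !(qh %in% multi)
  counts <- tabulate(sh[keep], nbins = nrow(iv))
  list(counts = data.frame(feature_id = iv$feature_id, count = counts,
                           stringsAsFactors = FALSE),
       total_mapped = nrow(fragments),
       ambiguous = length(multi))
}

#' Bernoulli downsampling of a fragment stream (or of counts)
#'
#' Each fragment is kept independently with probability `fraction`;
#' deterministic given `seed`. A named integer vector of counts is thinned
#' binomially instead.
#'
#' @param x fragment data.frame, or integer vector of per-feature counts.
#' @param fraction keep probability between 0 and 1.
#' @param seed integer seed.
#' @export
downsample_fragments <- function(x, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  set.seed(as.integer(seed))
  if (is.data.frame(x)) {
    keep <- stats::runif(nrow(x)) < fraction
    out <- x[keep, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  stats::setNames(stats::rbinom(length(x), as.integer(x), fraction), names(x))
}

#' Library-matching downsampling fraction
#'
#' The fraction `N_target / N_source`, truncated (floored) to four decimal
#' places -- the value passed as a sampling switch when downsampling the
#' larger of two libraries to match the smaller.
#'
#' @param n_target total mapped fragments of the smaller library.
#' @param n_source total mapped fragments of the larger library (must be
#'   at least `n_target`).
#' @return the truncated fraction.
#' @export
library_match_fraction <- function(n_target, n_source) {
  if (n_target < 1L || n_source < 1L) stop("library totals must be >= 1")
  if (n_target > n_source) {
    stop("n_target exceeds n_source: downsample the larger library only")
  }
  a <- as.numeric(n_target) * 10000
  b <- as.numeric(n_source)
  ((a - a %% b) / b) / 10000
}

#' DNA-seq-normalized nucleosome density
#'
#' r = (n/N) / (d/D); 0 when n = 0 and d > 0; undefined (`NA`) when d = 0.
#'
#' @param n,d per-IES nucleosomal and DNA fragment counts (vectorized).
#' @param N,D total mapped nucleosomal and DNA fragments (>= 1).
#' @export
compute_density <- function(n, N, d, D) {
  if (N < 1L || D < 1L) stop("library totals N and D must be >= 1")
  if (any(n < 0L) || any(d < 0L)) stop("counts must be non-negative")
  ifelse(d > 0L, (n / N) / (d / D), NA_real_)
}

#' Per-IES density table for one condition
#'
#' @param nuc_counts,dna_counts `counts` data.frames from
#'   [count_fragment_overlaps()] (same feature order).
#' @param N,D library totals (total mapped nucleosomal / DNA fragments).
#' @param condition_label condition tag.
#' @return `data.frame` of class `DensityRecord` with columns `ies_id`, `n`,
#'   `d`, `r`, `condition_label`.
#' @export
density_table <- function(nuc_counts, dna_counts, N, D, condition_label) {
  stopifnot(identical(nuc_counts$feature_id, dna_counts$feature_id))
  out <- data.frame(ies_id = nuc_counts$feature_id, n = nuc_counts$count,
                    d = dna_counts$count,
                    r = compute_density(nuc_counts$count, N,
                                        dna_counts$count, D),
                    condition_label = condition_label,
                    stringsAsFactors = FALSE)
  class(out) <- c("DensityRecord", "data.frame")
  out
}

#' Stratum specification for density comparisons
#'
#' @param irs_cutoff IRS cutoff (default 0.1).
#' @param side `"below"` (IRS < cutoff: weakly affected) or `"at_or_above"`
#'   (IRS >= cutoff: strongly affected).
#' @param length_range optional inclusive IES length interval in bp (e.g.
#'   `c(26, 31)` for the first IES length peak).
#' @export
stratum_spec <- function(irs_cutoff = 0.1, side = c("below", "at_or_above"),
                         length_range = NULL) {
  side <- match.arg(side)
  if (!is.null(length_range)) {
    stopifnot(length(length_range) == 2L, length_range[1] <= length_range[2])
  }
  structure(list(irs_cutoff = irs_cutoff, side = side,
                 length_range = length_range), class = "StratumSpec")
}

.stratum_label <- function(spec) {
  lab <- if (spec$side == "below") {
    sprintf("IRS<%.3g", spec$irs_cutoff)
  } else sprintf("IRS>=%.3g", spec$irs_cutoff)
  if (!is.null(spec$length_range)) {
    lab <- sprintf("%s,len %d-%d", lab, spec$length_range[1],
                   spec$length_range[2])
  }
  lab
}

#' Extract the density sample of one stratum
#'
#' Keeps IESs with a defined IRS on the stratifying scores and a defined
#' density (d > 0), matching the IRS side of the stratum and, when set, with
#' IES length inside the inclusive `length_range`.
#'
#' @param densities a [density_table()].
#' @param scores a [compute_irs()] result used for stratification (e.g. the
#'   knockdown IRS).
#' @param spec a [stratum_spec()].
#' @param ies_lengths data.frame with columns `ies_id` and `length` (e.g.
#'   the `ies` table of a [genome_pair()], or the simulator truth).
#' @return numeric vector of r values.
#' @export
stratify_densities <- function(densities, scores, spec, ies_lengths) {
  stopifnot(inherits(spec, "StratumSpec"))
  m <- merge(as.data.frame(densities), scores[c("ies_id", "irs")], by = "ies_id")
  m <- merge(m, ies_lengths[c("ies_id", "length")], by = "ies_id")
  m <- m[!is.na(m$irs) & !is.na(m$r), ]
  keep <- if (spec$side == "below") m$irs < spec$irs_cutoff else
    m$irs >= spec$irs_cutoff
  if (!is.null(spec$length_range)) {
    keep <- keep & m$length >= spec$length_range[1] &
      m$length <= spec$length_range[2]
  }
  r <- m$r[keep]
  if (length(r) == 0L) stop("empty stratum: ", .stratum_label(spec))
  r
}

#' Unit-area histogram of density values
#'
#' Bin heights are normalized so that sum(height x bin width) = 1. Values
#' above the last edge are pooled into the last bin.
#'
#' @param r_values numeric vector (>= 1 value).
#' @param bin_edges strictly increasing edges; default 40 equal bins on
#'   0 to 4.
#' @return data.frame with `bin_lo`, `bin_hi`, `count`, `density`.
#' @export
histogram_densities <- function(r_values, bin_edges = seq(0, 4, length.out = 41)) {
  if (length(r_values) == 0L) stop("empty input")
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  nb <- length(bin_edges) - 1L
  idx <- findInterval(r_values, bin_edges)
  idx[idx < 1L] <- 1L
  idx[idx > nb] <- nb      # overflow pooled into the last bin
  counts <- tabulate(idx, nbins = nb)
  widths <- diff(bin_edges)
  data.frame(bin_lo = bin_edges[-length(bin_edges)], bin_hi = bin_edges[-1],
             count = counts,
             density = counts / (length(r_values) * widths))
}

# Asymptotic two-sided Kolmogorov probability Q(t) = 2 sum (-1)^{k-1} e^{-2 k^2 t^2}.
.ks_q <- function(t) {
  if (t < 1e-8) return(1)
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the supremum of the absolute ECDF difference, evaluated
#' at the pooled unique values (which handles ties). The two-sided p-value
#' uses the asymptotic Kolmogorov distribution at effective sample size
#' n1 n2 / (n1 + n2).
#'
#' @param sample1,sample2 numeric vectors (>= 1 value each).
#' @return list of class `KsResult` with `statistic`, `p_value`, `n1`, `n2`.
#' @export
ks_two_sample <- function(sample1, sample2) {
  n1 <- length(sample1); n2 <- length(sample2)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty")
  z <- sort(unique(c(sample1, sample2)))
  d <- max(abs(findInterval(z, sort(sample1)) / n1 -
                 findInterval(z, sort(sample2)) / n2))
  ne <- n1 * n2 / (n1 + n2)
  structure(list(statistic = d, p_value = .ks_q(sqrt(ne) * d),
                 n1 = n1, n2 = n2), class = "KsResult")
}

#' @export
print.KsResult <- function(x, ...) {
  cat(sprintf("two-sample KS: D = %.4f, p = %.4g (n1 = %d, n2 = %d)\n",
              x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Stratified KS comparison of two density tables
#'
#' For each stratum, extracts the r samples of the two conditions and runs
#' the two-sample KS test.
#'
#' @param dens_a,dens_b [density_table()]s of the two conditions.
#' @param scores stratifying IRS scores.
#' @param strata list of [stratum_spec()]s.
#' @param ies_lengths see [stratify_densities()].
#' @return data.frame with one row per stratum: `stratum`, `statistic`,
#'   `p_value`, `n1`, `n2`.
#' @export
ks_by_stratum <- function(dens_a, dens_b, scores, strata, ies_lengths) {
  rows <- lapply(strata, function(spec) {
    ra <- stratify_densities(dens_a, scores, spec, ies_lengths)
    rb <- stratify_densities(dens_b, scores, spec, ies_lengths)
    ks <- ks_two_sample(ra, rb)
    data.frame(stratum = .stratum_label(spec), statistic = ks$statistic,
               p_value = ks$p_value, n1 = ks$n1, n2 = ks$n2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
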