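# IES retention scores (IRS) and cross-knockdown comparison.
#
# Counting model: retention evidence is boundary-anchored. On the MAC+IES
# stream a fragment adds one unit of IES+ evidence for every IES boundary it
# crosses with at least `min_anchor` bases on each side (0, 1 or 2 units per
# IES). On the MAC stream a fragment crossing the excision junction with the
# same anchor adds two units of IES- evidence, one per boundary of the
# excised IES, so both kinds of evidence are measured on a common
# per-boundary scale and IRS is an unbiased estimator of the per-fragment
# retention probability (see the methods vignette). A fragment never
# contributes to both categories, and fragments fully inside an IES or not
# reaching any boundary are uninformative.

# Fragments covering integer point(s) with >= anchor bases on each side:
# returns the number of covering fragments per point.
.count_point_crossings <- function(frag_start, frag_end, points, anchor) {
  lo <- frag_start + anchor
  hi <- frag_end - anchor
  keep <- hi >= lo
  slo <- sort(lo[keep])
  shi <- sort(hi[keep])
  findInterval(points, slo) - findInterval(points - 1L, shi)
}

#' Count IES+ / IES- retention evidence
#'
#' @param mac_ies_alignments fragment stream aligned to the MAC+IES
#'   reference (see [read_alignments()]).
#' @param mac_alignments fragment stream aligned to the MAC reference.
#' @param ies_set an [build_interval_set()] of IES spans on MAC+IES. MAC
#'   excision points are derived from it (span start minus the cumulative
#'   length of the preceding IESs on the contig).
#' @param min_anchor minimum bases required on each side of a boundary or
#'   junction (default 5).
#' @return `data.frame` of class `RetentionCount` with columns `ies_id`,
#'   `n_plus`, `n_minus`.
#' @export
count_retention_reads <- function(mac_ies_alignments, mac_alignments, ies_set,
                                  min_anchor = 5L) {
  stopifnot(min_anchor >= 1L)
  iv <- build_interval_set(ies_set)   # validates sortedness / disjointness / ids
  n_plus <- integer(nrow(iv))
  n_minus <- integer(nrow(iv))
  for (ctg in unique(iv$reference_id)) {
    rows <- which(iv$reference_id == ctg)
    sub <- iv[rows, ]
    len <- sub$end - sub$start
    junction <- sub$start - c(0L, cumsum(len))[seq_along(rows)]  # MAC offsets
    fi <- mac_ies_alignments[mac_ies_alignments$reference_id == ctg, ]
    if (nrow(fi)) {
      b_left <- .count_point_crossings(fi$start, fi$end, sub$start, min_anchor)
      b_right <- .count_point_crossings(fi$start, fi$end, sub$end, min_anchor)
      n_plus[rows] <- b_left + b_right
    }
    fm <- mac_alignments[mac_alignments$reference_id == ctg, ]
    if (nrow(fm)) {
      n_minus[rows] <- 2L * .count_point_crossings(fm$start, fm$end,
                                                   junction, min_anchor)
    }
  }
  out <- data.frame(ies_id = iv$feature_id, n_plus = n_plus,
                    n_minus = n_minus, stringsAsFactors = FALSE)
  class(out) <- c("RetentionCount", "data.frame")
  out
}

#' Compute IES retention scores
#'
#' IRS = IES+ / (IES+ + IES-); undefined (`NA`) when no informative evidence
#' was observed.
#'
#' @param counts a [count_retention_reads()] result (or any data.frame with
#'   `ies_id`, `n_plus`, `n_minus`).
#' @return `data.frame` of class `RetentionScore` with columns `ies_id`,
#'   `n_plus`, `n_minus`, `irs`.
#' @export
compute_irs <- function(counts) {
  counts <- as.data.frame(counts, stringsAsFactors = FALSE)
  if (any(counts$n_plus < 0L) || any(counts$n_minus < 0L)) {
    stop("retention counts must be non-negative")
  }
  denom <- counts$n_plus + counts$n_minus
  irs <- ifelse(denom > 0L, counts$n_plus / denom, NA_real_)
  out <- data.frame(ies_id = counts$ies_id, n_plus = counts$n_plus,
                    n_minus = counts$n_minus, irs = irs,
                    stringsAsFactors = FALSE)
  class(out) <- c("RetentionScore", "data.frame")
  out
}

#' Summarize retention against an IRS cutoff
#'
#' Reports the number and percentage of IESs with IRS at or above the
#' cutoff, among IESs with a defined IRS (IESs without informative coverage
#' are excluded from numerator and denominator: absence of coverage is not
#' evidence of excision).
#'
#' @param scores a [compute_irs()] result.
#' @param cutoff IRS cutoff between 0 and 1 (default 0.1).
#' @return list with `n_defined`, `count` and `percentage`.
#' @export
summarize_retention <- function(scores, cutoff = 0.1) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  irs <- scores$irs[!is.na(scores$irs)]
  if (length(irs) == 0L) stop("no IES with a defined IRS")
  list(n_defined = length(irs), count = sum(irs >= cutoff),
       percentage = 100 * sum(irs >= cutoff) / length(irs))
}

# Pointy-top hexagonal binning on the unit square. `gridsize` hexagons span
# the x-axis. Returns integer axial (q, r) cell indices per point.
.hex_cell <- function(x, y, gridsize = 25L) {
  size <- 1 / (gridsize * sqrt(3))      # hex circumradius; width = sqrt(3)*size
  qf <- (sqrt(3) / 3 * x - y / 3) / size
  rf <- (2 / 3 * y) / size
  # cube rounding
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  data.frame(q = as.integer(rx), r = as.integer(rz))
}

#' Correlate IRS between two knockdowns
#'
#' Pairs scores by `ies_id`, keeps IESs with a defined IRS in both inputs,
#' and reports Pearson's correlation, an ordinary least-squares fit of
#' `b ~ a`, and hexagonal-bin counts over the unit square (pointy-top
#' hexagons, `gridsize` cells across).
#'
#' @param scores_a,scores_b [compute_irs()] results.
#' @param gridsize number of hexagon widths spanning the unit interval (default 25).
#' @return list of class `IrsCorrelation` with `pearson_r`, `ols_slope`,
#'   `ols_intercept`, `hexbin_counts` (data.frame `q`, `r`, `count`) and
#'   `n_pairs`. Zero variance in either input yields `NA` coefficients.
#' @export
correlate_irs <- function(scores_a, scores_b, gridsize = 25L) {
  m <- merge(scores_a[c("ies_id", "irs")], scores_b[c("ies_id", "irs")],
             by = "ies_id", suffixes = c("_a", "_b"))
  m <- m[!is.na(m$irs_a) & !is.na(m$irs_b), ]
  if (nrow(m) < 3L) stop("need at least 3 IESs with defined IRS in both inputs")
  x <- m$irs_a; y <- m$irs_b
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    r <- NA_real_; slope <- NA_real_; intercept <- NA_real_
  } else {
    r <- stats::cor(x, y)
    fit <- stats::lm.fit(cbind(1, x), y)
    intercept <- unname(fit$coefficients[1])
    slope <- unname(fit$coefficients[2])
  }
  cell <- .hex_cell(x, y, gridsize)
  counts <- stats::aggregate(list(count = rep(1L, nrow(cell))),
                             by = list(q = cell$q, r = cell$r), FUN = sum)
  structure(list(pearson_r = r, ols_slope = slope, ols_intercept = intercept,
                 hexbin_counts = counts, n_pairs = nrow(m)),
            class = "IrsCorrelation")
}

#' @export
print.IrsCorrelation <- function(x, ...) {
  cat(sprintf("IRS correlation over %d IESs: Pearson r = %.4f, OLS slope = %.4f, intercept = %.4f\n",
              x$n_pairs, x$pearson_r, x$ols_slope, x$ols_intercept))
  invisible(x)
}

#' Write retention scores as TSV
#' @param scores a [compute_irs()] result.
#' @param path output path.
#' @export
write_irs_tsv <- function(scores, path) {
  data.table::fwrite(as.data.frame(scores), path, sep = "\t")
  invisible(path)
}

#' Read retention scores from TSV
#' @param path TSV written by [write_irs_tsv()].
#' @export
read_irs_tsv <- function(path) {
  out <- as.data.frame(data.table::fread(path, sep = "\t"))
  class(out) <- c("RetentionScore", "data.frame")
  out
}
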