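# Minimal SAM IO for paired-end fragment records.
#
# The dialect honoured here is the one the simulator writes: @SQ headers,
# FLAG, RNAME, POS, TLEN; CIGAR is parsed for reference-consumed length.
# BAM/CRAM are out of scope; convert with `samtools view -h` first.

.FLAG_PAIRED <- 1L
.FLAG_PROPER <- 2L
.FLAG_UNMAPPED <- 4L
.FLAG_MREVERSE <- 32L
.FLAG_READ1 <- 64L
.FLAG_READ2 <- 128L
.FLAG_REVERSE <- 16L
.FLAG_SECONDARY <- 256L
.FLAG_SUPPLEMENTARY <- 2048L

#' Write a fragment stream as a paired-end SAM file
#'
#' Each fragment row becomes one properly-paired read pair with full-match
#' CIGARs at the fragment's outer coordinates: mate 1 at `[start, start+rl)`
#' forward, mate 2 at `[end-rl, end)` reverse, TLEN = +/- outer distance.
#'
#' @param fragments data.frame with columns `read_id`, `reference_id`,
#'   `start`, `end` (0-based half-open), `outer_distance`, `properly_paired`.
#' @param reference_lengths named integer vector of reference contig lengths
#'   (for `@SQ` headers).
#' @param path output SAM path.
#' @param read_length mate read length in bp; truncated to the fragment
#'   length when the fragment is shorter.
#' @param reference_seqs optional named character vector (or `DNAStringSet`)
#'   of reference sequences; when supplied, real mate sequences are written,
#'   otherwise SEQ is "*".
#' @return `path`, invisibly.
#' @export
write_sam <- function(fragments, reference_lengths, path, read_length = 50L,
                      reference_seqs = NULL) {
  fr <- as.data.frame(fragments, stringsAsFactors = FALSE)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference_lengths),
                   as.integer(reference_lengths)))
  if (nrow(fr) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  if (!all(fr$reference_id %in% names(reference_lengths))) {
    stop("fragment reference absent from reference_lengths")
  }
  len <- fr$end - fr$start
  rl <- pmin(as.integer(read_length), len)
  p1 <- fr$start + 1L                 # SAM 1-based leftmost of mate 1
  p2 <- fr$end - rl + 1L              # leftmost of mate 2
  flag1 <- .FLAG_PAIRED + .FLAG_MREVERSE + .FLAG_READ1 +
    ifelse(fr$properly_paired, .FLAG_PROPER, 0L)
  flag2 <- .FLAG_PAIRED + .FLAG_REVERSE + .FLAG_READ2 +
    ifelse(fr$properly_paired, .FLAG_PROPER, 0L)
  cig <- sprintf("%dM", rl)
  if (!is.null(reference_seqs)) {
    seqs <- if (is.character(reference_seqs)) reference_seqs else
      as.character(reference_seqs)
    s1 <- character(nrow(fr)); s2 <- character(nrow(fr))
    for (r in unique(fr$reference_id)) {
      i <- fr$reference_id == r
      s1[i] <- substring(seqs[[r]], p1[i], p1[i] + rl[i] - 1L)
      s2[i] <- substring(seqs[[r]], p2[i], p2[i] + rl[i] - 1L)
    }
    s2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s2)))
  } else {
    s1 <- "*"; s2 <- "*"
  }
  tl <- fr$outer_distance
  l1 <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t*",
                fr$read_id, flag1, fr$reference_id, p1, cig, p2, tl, s1)
  l2 <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t*",
                fr$read_id, flag2, fr$reference_id, p2, cig, p1, -tl, s2)
  body <- character(2L * nrow(fr))
  body[c(TRUE, FALSE)] <- l1
  body[c(FALSE, TRUE)] <- l2
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Reference-consumed length of a CIGAR string (M/D/N/=/X operations).
.cigar_reference_length <- function(cigar) {
  out <- integer(length(cigar))
  simple <- grepl("^[0-9]+M$", cigar)
  out[simple] <- as.integer(sub("M$", "", cigar[simple]))
  if (any(!simple)) {
    out[!simple] <- vapply(cigar[!simple], function(cg) {
      ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
      n <- as.integer(sub("[A-Z=]$", "", ops))
      op <- sub("^[0-9]+", "", ops)
      sum(n[op %in% c("M", "D", "N", "=", "X")])
    }, integer(1))
  }
  out
}

#' Read paired-end alignments from SAM into a fragment stream
#'
#' Mate pairs are joined on the read name; the fragment span is the union
#' span of the two mates on the reference, the outer distance is |TLEN|, and
#' `properly_paired` is taken from SAM flag bit 2. Unmapped, secondary and
#' supplementary records are dropped. Read names whose mate is missing, or
#' whose mates map to different references, are skipped and counted in the
#' `skipped` attribute. Duplicate read names beyond the first pair are
#' dropped with a warning.
#'
#' @param path SAM file path.
#' @param condition_label label stored in the `condition_label` column
#'   (e.g. `"EV_control"` or `"KD"`).
#' @return `data.frame` with columns `read_id`, `reference_id`, `start`,
#'   `end`, `outer_distance`, `properly_paired`, `condition_label`, plus an
#'   integer attribute `skipped`.
#' @export
read_alignments <- function(path, condition_label = "EV_control") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  sq <- lines[startsWith(lines, "@SQ")]
  refs <- sub("^.*\tSN:([^\t]+).*$", "\\1", sq)
  body <- lines[!is_hdr]
  empty <- data.frame(read_id = character(), reference_id = character(),
                      start = integer(), end = integer(),
                      outer_distance = integer(), properly_paired = logical(),
                      condition_label = character(), stringsAsFactors = FALSE)
  if (length(body) == 0L) {
    attr(empty, "skipped") <- 0L
    return(empty)
  }
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE, keep = 1:9)
  dt <- data.table::data.table(
    qname = f[[1]], flag = as.integer(f[[2]]), rname = f[[3]],
    pos = as.integer(f[[4]]), cigar = f[[6]], tlen = as.integer(f[[9]]))
  keep <- bitwAnd(dt$flag, .FLAG_UNMAPPED + .FLAG_SECONDARY + .FLAG_SUPPLEMENTARY) == 0L
  dt <- dt[keep]
  n_in <- length(unique(dt$qname))
  if (nrow(dt) > 0L && !all(dt$rname %in% refs)) {
    stop("alignment reference missing from @SQ headers in ", path)
  }
  dt[, ref_end := pos - 1L + .cigar_reference_length(cigar)]  # 0-based exclusive
  # keep at most one record per (read, mate) slot
  dt[, mate := bitwAnd(flag, .FLAG_READ2) > 0L]
  dup <- duplicated(dt[, list(qname, mate)])
  if (any(dup)) {
    warning("dropping ", sum(dup), " duplicate read record(s), keeping first")
    dt <- dt[!dup]
  }
  pairs <- dt[, list(n = .N, nref = data.table::uniqueN(rname),
                     reference_id = rname[1L],
                     start = min(pos) - 1L, end = max(ref_end),
                     outer_distance = abs(tlen[1L]),
                     properly_paired = bitwAnd(flag[1L], .FLAG_PROPER) > 0L),
              by = "qname"]
  ok <- pairs$n == 2L & pairs$nref == 1L
  skipped <- sum(!ok)
  pairs <- pairs[ok]
  if (nrow(pairs) == 0L) {
    attr(empty, "skipped") <- skipped
    return(empty)
  }
  out <- data.frame(read_id = pairs$qname, reference_id = pairs$reference_id,
                    start = pairs$start, end = pairs$end,
                    outer_distance = pairs$outer_distance,
                    properly_paired = pairs$properly_paired,
                    condition_label = condition_label,
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}
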