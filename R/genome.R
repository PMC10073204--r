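# Core domain model: MAC / MAC+IES genome pair, IES annotation table,
# interval sets and coordinate lifting between the two assemblies.
#
# Conventions used throughout the package:
#   * all coordinates are 0-based half-open internally; SAM/BED IO converts
#     at the boundary (SAM POS is 1-based inclusive, BED is already 0-based);
#   * IES spans live on the MAC+IES assembly; the "insertion point" of an IES
#     is a 0-based between-base offset on the corresponding MAC contig;
#   * strand is ignored for all counting.

#' Construct a GenomePair
#'
#' A `GenomePair` ties an IES-free somatic (MAC) assembly to the IES-containing
#' (MAC+IES) assembly through a table of IES records. Excising every IES span
#' from the MAC+IES contigs must reproduce the MAC contigs exactly; this is
#' checked at construction time.
#'
#' @param mac named [Biostrings::DNAStringSet] of MAC contigs.
#' @param mac_ies named [Biostrings::DNAStringSet] of MAC+IES contigs, same
#'   names as `mac`.
#' @param ies `data.frame` with one row per IES and columns `ies_id`,
#'   `contig_id`, `mac_insertion_point` (0-based between-base offset on the MAC
#'   contig), `length`, `start`, `end` (0-based half-open span on the MAC+IES
#'   contig) and `sequence`.
#' @param aux optional named list of auxiliary reference sets
#'   (`DNAStringSet`s), e.g. TE / OES / vector sequences used for small-RNA
#'   compartment classification. Not part of the MAC/MAC+IES coordinate model.
#' @return an object of class `GenomePair`.
#' @export
genome_pair <- function(mac, mac_ies, ies, aux = list()) {
  stopifnot(inherits(mac, "DNAStringSet"), inherits(mac_ies, "DNAStringSet"))
  if (!identical(sort(names(mac)), sort(names(mac_ies)))) {
    stop("MAC and MAC+IES assemblies must share contig names")
  }
  if (anyDuplicated(names(mac))) stop("contig_id must be unique within a genome")
  ies <- as.data.frame(ies, stringsAsFactors = FALSE)
  req <- c("ies_id", "contig_id", "mac_insertion_point", "length",
           "start", "end", "sequence")
  if (!all(req %in% names(ies))) {
    stop("ies table must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(ies$ies_id)) stop("ies_id must be unique")
  if (any(ies$length < 1L)) stop("IES length must be >= 1")
  if (any(ies$end - ies$start != ies$length)) {
    stop("IES span length must equal sequence length")
  }
  if (any(nchar(ies$sequence) != ies$length)) {
    stop("IES sequence length disagrees with recorded length")
  }
  ies <- ies[order(ies$contig_id, ies$start), , drop = FALSE]
  rownames(ies) <- NULL
  for (ctg in unique(ies$contig_id)) {
    sub <- ies[ies$contig_id == ctg, ]
    if (any(sub$start[-1] < sub$end[-nrow(sub)])) {
      stop("IES spans on contig ", ctg, " overlap")
    }
    L <- length(mac[[ctg]])
    if (any(sub$mac_insertion_point < 0L | sub$mac_insertion_point > L)) {
      stop("mac_insertion_point outside [0, contig length] on ", ctg)
    }
  }
  gp <- structure(list(mac = mac, mac_ies = mac_ies, ies = ies, aux = aux),
                  class = "GenomePair")
  .check_excision_roundtrip(gp)
  gp
}

# Removing all IES spans from MAC+IES must reproduce MAC exactly.
.check_excision_roundtrip <- function(gp) {
  for (ctg in names(gp$mac)) {
    sub <- gp$ies[gp$ies$contig_id == ctg, ]
    full <- as.character(gp$mac_ies[[ctg]])
    if (nrow(sub) == 0L) {
      kept <- full
    } else {
      keep_start <- c(0L, sub$end)              # 0-based starts of MDS blocks
      keep_end <- c(sub$start, nchar(full))     # 0-based ends
      pieces <- substring(full, keep_start + 1L, keep_end)
      kept <- paste(pieces, collapse = "")
    }
    if (!identical(kept, as.character(gp$mac[[ctg]]))) {
      stop("excising IES spans from MAC+IES does not reproduce MAC on ", ctg)
    }
  }
  invisible(TRUE)
}

#' @export
print.GenomePair <- function(x, ...) {
  cat("GenomePair:", length(x$mac), "contig(s),", nrow(x$ies), "IES(s)\n")
  cat("  MAC length:    ", sum(Biostrings::width(x$mac)), "bp\n")
  cat("  MAC+IES length:", sum(Biostrings::width(x$mac_ies)), "bp\n")
  invisible(x)
}

#' Lift MAC coordinates to MAC+IES coordinates
#'
#' Maps 0-based MAC offsets to their position on the MAC+IES contig. Both
#' base offsets and between-base offsets lift consistently: an offset is
#' shifted by the total length of IESs whose insertion point is at or before
#' it.
#'
#' @param gp a [genome_pair()].
#' @param contig_id single contig name.
#' @param pos integer vector of 0-based MAC offsets.
#' @return integer vector of 0-based MAC+IES offsets.
#' @export
mac_to_macies <- function(gp, contig_id, pos) {
  sub <- gp$ies[gp$ies$contig_id == contig_id, ]
  if (nrow(sub) == 0L) return(as.integer(pos))
  shift <- c(0L, cumsum(sub$length))
  as.integer(pos + shift[findInterval(pos, sub$mac_insertion_point) + 1L])
}

#' Lift MAC+IES coordinates back to MAC coordinates
#'
#' Positions inside an IES span have no MAC image and map to `NA`.
#'
#' @inheritParams mac_to_macies
#' @param pos integer vector of 0-based MAC+IES offsets.
#' @return integer vector of 0-based MAC offsets, `NA` inside IESs.
#' @export
macies_to_mac <- function(gp, contig_id, pos) {
  sub <- gp$ies[gp$ies$contig_id == contig_id, ]
  if (nrow(sub) == 0L) return(as.integer(pos))
  shift <- c(0L, cumsum(sub$length))
  idx <- findInterval(pos, sub$start)
  out <- as.integer(pos - shift[idx + 1L])
  inside <- idx >= 1L & pos < sub$end[pmax(idx, 1L)]
  out[inside] <- NA_integer_
  out
}

#' Read a FASTA file of contigs
#'
#' Thin validating wrapper around [Biostrings::readDNAStringSet()]: sequences
#' are upper-cased, and any record with an empty sequence or characters
#' outside A/C/G/T is rejected.
#'
#' @param path FASTA file path.
#' @return named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("malformed FASTA in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) stop("duplicate contig_id in ", path)
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  w <- Biostrings::width(x)
  if (any(w == 0L)) {
    stop("empty sequence for record '", names(x)[which(w == 0L)[1]], "' in ", path)
  }
  freq <- Biostrings::alphabetFrequency(x)
  bad <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE]) != w
  if (any(bad)) {
    stop("record '", names(x)[which(bad)[1]],
         "' contains characters outside A/C/G/T in ", path)
  }
  x
}

#' Write contigs to FASTA
#' @param x named [Biostrings::DNAStringSet] or named character vector.
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Build an IntervalSet from IES records
#'
#' The interval set holds the IES spans on the MAC+IES assembly, sorted by
#' (reference, start), and is the container consumed by all overlap counters.
#'
#' @param ies IES table of a [genome_pair()] (or any data.frame with columns
#'   `contig_id`/`reference_id`, `start`, `end` and `ies_id`/`feature_id`).
#' @return `data.frame` of class `IntervalSet` with columns `reference_id`,
#'   `start`, `end`, `feature_id`.
#' @export
build_interval_set <- function(ies) {
  ies <- as.data.frame(ies, stringsAsFactors = FALSE)
  ref <- if ("reference_id" %in% names(ies)) ies$reference_id else ies$contig_id
  fid <- if ("feature_id" %in% names(ies)) ies$feature_id else ies$ies_id
  if (length(ref) == 0L) {
    out <- data.frame(reference_id = character(), start = integer(),
                      end = integer(), feature_id = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("IntervalSet", "data.frame")
    return(out)
  }
  out <- data.frame(reference_id = ref, start = as.integer(ies$start),
                    end = as.integer(ies$end), feature_id = fid,
                    stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) stop("intervals must satisfy end > start")
  if (anyDuplicated(out$feature_id)) stop("feature_id must be unique")
  out <- out[order(out$reference_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  for (r in unique(out$reference_id)) {
    sub <- out[out$reference_id == r, ]
    if (nrow(sub) > 1L && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      stop("overlapping intervals on reference ", r)
    }
  }
  class(out) <- c("IntervalSet", "data.frame")
  out
}

#' Write IES intervals as BED6-like TSV
#'
#' Columns: chrom, start (0-based), end, name, score ("."), strand (".").
#' @param intervals an `IntervalSet` or IES table.
#' @param path output path.
#' @export
write_ies_bed <- function(intervals, path) {
  iv <- build_interval_set(intervals)
  bed <- data.frame(iv$reference_id, iv$start, iv$end, iv$feature_id, ".", ".")
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED6-like IES annotation
#' @param path BED file path.
#' @return an `IntervalSet`.
#' @export
read_ies_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bed <- data.table::fread(path, sep = "\t", header = FALSE,
                           colClasses = list(character = 1, integer = 2:3))
  if (ncol(bed) < 4L) stop("BED file must have at least 4 columns: ", path)
  build_interval_set(data.frame(reference_id = bed[[1]], start = bed[[2]],
                                end = bed[[3]], feature_id = bed[[4]],
                                stringsAsFactors = FALSE))
}
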