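# Small-RNA size selection and compartment classification.
#
# Classification is exact-substring membership on both strands, replacing a
# short-read mapper at default parameters: the simulator emits error-free
# substrings, and the contract under test is the classification and
# normalization, not alignment heuristics. Multi-compartment hits resolve by
# a fixed priority (vector first, to remove silencing-construct reads, then
# MDS, IES, TE, OES).

.default_priority <- c("vector", "MDS", "IES", "TE", "OES")

#' Size-select small-RNA reads
#'
#' Keeps reads with length inside `[min_nt, max_nt]` inclusive (default
#' 15-45 nt, the gel-selected range).
#'
#' @param reads data.frame with columns `read_id`, `sequence` and optionally
#'   `length` (recomputed when absent).
#' @param min_nt,max_nt inclusive length bounds.
#' @export
size_select <- function(reads, min_nt = 15L, max_nt = 45L) {
  stopifnot(min_nt >= 1L, min_nt <= max_nt)
  if (is.null(reads$length)) reads$length <- nchar(reads$sequence)
  out <- reads[reads$length >= min_nt & reads$length <= max_nt, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Compartment reference list from a genome: MDS = MAC contigs, IES = IES
# sequences, plus the auxiliary TE / OES / vector sets.
#' Compartment references from a genome pair
#' @param genome a [build_genome()] genome.
#' @return named list of character vectors, one per compartment.
#' @export
compartment_references <- function(genome) {
  list(vector = as.character(genome$aux$vector),
       MDS = as.character(genome$mac),
       IES = genome$ies$sequence,
       TE = as.character(genome$aux$TE),
       OES = as.character(genome$aux$OES))
}

#' Classify small-RNA reads by genomic compartment
#'
#' Each read is assigned to the first compartment, in priority order, in
#' which it occurs as an exact substring of either strand of any reference
#' sequence; reads matching no compartment are `"unassigned"`. Matching uses
#' [Biostrings::vwhichPDict()] per read-length group.
#'
#' @param reads data.frame with `sequence` (and `length`).
#' @param references named list of character vectors / `DNAStringSet`s, one
#'   per compartment.
#' @param priority compartment priority order; must cover `names(references)`.
#' @return character vector of compartment labels, one per read.
#' @export
classify_reads <- function(reads, references,
                           priority = .default_priority) {
  if (length(references) == 0L) stop("empty reference set")
  if (!all(names(references) %in% priority)) {
    stop("priority must cover all reference compartments")
  }
  priority <- priority[priority %in% names(references)]
  n <- nrow(reads)
  label <- rep("unassigned", n)
  if (n == 0L) return(label)
  if (is.null(reads$length)) reads$length <- nchar(reads$sequence)
  # both-strand subjects per compartment
  subjects <- lapply(references, function(ref) {
    ss <- Biostrings::DNAStringSet(as.character(ref))
    c(ss, Biostrings::reverseComplement(ss))
  })
  for (w in sort(unique(reads$length))) {
    idx <- which(reads$length == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(reads$sequence[idx]))
    unmatched <- rep(TRUE, length(idx))
    for (comp in priority) {
      if (!any(unmatched)) break
      hit_lists <- Biostrings::vwhichPDict(pd, subjects[[comp]])
      hit <- unique(unlist(hit_lists, use.names = FALSE))
      take <- intersect(hit, which(unmatched))
      if (length(take)) {
        label[idx[take]] <- comp
        unmatched[take] <- FALSE
      }
    }
  }
  label
}

#' Build a per-length compartment profile
#'
#' Counts size-selected reads per (length, compartment) cell and normalizes
#' by the total number of input reads (mapped plus unassigned), one row per
#' length in `lengths` and compartment.
#'
#' @param reads size-selected read data.frame.
#' @param references see [classify_reads()].
#' @param priority see [classify_reads()].
#' @param lengths lengths to tabulate (default 15:45).
#' @return `data.frame` of class `CompartmentProfile` with columns `length`,
#'   `compartment`, `count`, `normalized`, and attribute `total_reads`.
#' @export
build_profile <- function(reads, references, priority = .default_priority,
                          lengths = 15:45) {
  comp_levels <- c(priority[priority %in% names(references)], "unassigned")
  label <- classify_reads(reads, references, priority)
  total <- nrow(reads)
  tab <- table(factor(reads$length, levels = lengths),
               factor(label, levels = comp_levels))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("length", "compartment", "count")
  out$length <- as.integer(out$length)
  out$normalized <- if (total > 0L) out$count / total else 0
  out <- out[order(out$length, match(out$compartment, comp_levels)), ]
  rownames(out) <- NULL
  attr(out, "total_reads") <- total
  class(out) <- c("CompartmentProfile", "data.frame")
  out
}

.profile_cell <- function(profile, len, comp) {
  i <- profile$length == len & profile$compartment == comp
  if (!any(i)) return(0)
  sum(profile$normalized[i])
}

#' Scanning ratio between two time points
#'
#' The ratio of MDS-matching to IES-matching normalized 25-nt counts in each
#' profile, and their fold change (late / early). A successful scanning
#' process lowers the late ratio; a scanning defect leaves it near the early
#' value.
#'
#' @param profile_early,profile_late [build_profile()] results.
#' @return list with `ratio_early`, `ratio_late`, `fold_change` (`NA` when an
#'   IES-matching 25-nt count is zero).
#' @export
scanning_ratio <- function(profile_early, profile_late) {
  ratio <- function(p) {
    ies <- .profile_cell(p, 25L, "IES")
    if (ies == 0) return(NA_real_)
    .profile_cell(p, 25L, "MDS") / ies
  }
  re <- ratio(profile_early); rl <- ratio(profile_late)
  fc <- if (is.na(re) || is.na(rl) || re == 0) NA_real_ else rl / re
  list(ratio_early = re, ratio_late = rl, fold_change = fc)
}

#' Write a compartment profile as TSV
#' @param profile a [build_profile()] result.
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  data.table::fwrite(as.data.frame(profile), path, sep = "\t")
  invisible(path)
}
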