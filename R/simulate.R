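# Synthetic-data generator: a toy Paramecium-like genome pair plus DNA-seq,
# nucleosomal-seq and small-RNA sequencing inputs with known ground truth.
#
# Simulator conventions (documented, deliberate):
#   * every IES sequence begins and ends with "TA", and the MAC carries a
#     "TA" immediately after the insertion point, so excision junctions look
#     TA-bounded as in Paramecium;
#   * reads are emitted pre-aligned with their true coordinates; no aligner
#     runs anywhere in the package;
#   * a fragment maps contiguously to MAC+IES when every IES it touches is
#     present in its template, and contiguously to MAC when every IES it
#     touches is absent (a junction fragment); fragments are emitted to the
#     corresponding alignment stream(s). Because the minimum IES spacing is
#     at least the maximum fragment length, a fragment can touch at most one
#     IES, so no chimeric fragments arise.

#' Simulation configuration
#'
#' Defines the study conditions emulated by the generator. Defaults are the
#' package's fixed reference scenario: a 2 x 100 kb MAC genome with 500 IESs
#' whose length distribution has its first peak at 26-31 bp and is dominated
#' (93\%) by sub-nucleosomal (<147 bp) lengths; 65\% of IESs are "strong"
#' (retained under knockdown with a per-IES retention probability drawn
#' uniformly from `retention_kd_strong`), the rest are nearly unaffected;
#' mononucleosomal fragments have outer distances 125-175 bp; and the
#' small-RNA pool mixes 25-nt scnRNAs from all compartments with a 26-31-nt
#' exclusively IES-matching (iesRNA) class.
#'
#' @param seed integer master seed; per-stage seeds are derived from it.
#' @param n_contigs,contig_length MAC assembly shape.
#' @param n_ies number of IESs, placed uniformly with `min_spacing` between
#'   insertion points and a margin of `min_spacing` from contig ends.
#' @param ies_length_classes data.frame with columns `min`, `max`, `weight`:
#'   an IES draws a class by weight, then a uniform integer length inside it.
#' @param frac_subnucleosomal consistency target: total weight of classes
#'   with `max` < 147 must equal this value.
#' @param min_spacing minimum distance (bp) between IES insertion points;
#'   must be >= the maximum fragment length so a fragment touches <= 1 IES.
#' @param strong_fraction fraction of IESs sensitive to the knockdown.
#' @param retention_ev per-fragment IES retention probability in the
#'   empty-vector control (excision intact, so ~0).
#' @param retention_kd_strong,retention_kd_weak ranges (min, max) from which
#'   per-IES knockdown retention probabilities are drawn for strong / weak
#'   IESs.
#' @param occupancy_ev,occupancy_kd_strong,occupancy_kd_weak relative
#'   nucleosomal occupancy multipliers (>= 0) applied to start positions of
#'   fragments covering an IES, per condition and IES class.
#' @param n_dna_fragments,n_nuc_fragments library sizes per condition.
#' @param nuc_library_imbalance multiplier applied to the knockdown
#'   nucleosomal library size, emulating unequal sequencing depth between
#'   conditions (default 1.1702, the ratio of the study conditions this
#'   scenario mirrors); triggers library-matching downsampling.
#' @param dna_fragment_length_range,nuc_fragment_length_range outer-distance
#'   ranges (bp), inclusive; nucleosomal default 125-175 (mononucleosomes).
#' @param contamination_fraction proportion of fragments drawn from the
#'   unrearranged, IES-free maternal-MAC-like template.
#' @param read_length mate length used when writing SAM.
#' @param srna_mixture named numeric summing to 1: proportions of 25-nt reads
#'   per compartment (`MDS_25`, `IES_25`, `OES_25`, `TE_25`, `vector_25`) and
#'   of 26-31-nt IES-only reads (`iesRNA`).
#' @param n_srna_reads small-RNA library size.
#' @param iesrna_length_range iesRNA length range (nt), inclusive.
#' @param n_te,te_length,n_oes,oes_length,vector_length auxiliary reference
#'   sets for small-RNA compartments.
#' @return a list of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 2L,
                       contig_length = 100000L,
                       n_ies = 500L,
                       ies_length_classes = data.frame(
                         min = c(26L, 32L, 75L, 147L),
                         max = c(31L, 74L, 146L, 400L),
                         weight = c(0.70, 0.13, 0.10, 0.07)),
                       frac_subnucleosomal = 0.93,
                       min_spacing = 200L,
                       strong_fraction = 0.65,
                       retention_ev = 0,
                       retention_kd_strong = c(0.2, 0.9),
                       retention_kd_weak = c(0, 0.02),
                       occupancy_ev = 1,
                       occupancy_kd_strong = 1,
                       occupancy_kd_weak = 1,
                       n_dna_fragments = 200000L,
                       n_nuc_fragments = 200000L,
                       nuc_library_imbalance = 1.1702,
                       dna_fragment_length_range = c(100L, 200L),
                       nuc_fragment_length_range = c(125L, 175L),
                       contamination_fraction = 0.1,
                       read_length = 50L,
                       srna_mixture = c(MDS_25 = 0.32, IES_25 = 0.08,
                                        OES_25 = 0.15, TE_25 = 0.10,
                                        vector_25 = 0.05, iesRNA = 0.30),
                       n_srna_reads = 10000L,
                       iesrna_length_range = c(26L, 31L),
                       n_te = 5L, te_length = 3000L,
                       n_oes = 5L, oes_length = 5000L,
                       vector_length = 2000L) {
  cfg <- as.list(environment())
  probs <- c(cfg$retention_ev, cfg$retention_kd_strong, cfg$retention_kd_weak,
             cfg$contamination_fraction, cfg$strong_fraction,
             cfg$ies_length_classes$weight, cfg$srna_mixture)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (abs(sum(cfg$srna_mixture) - 1) > 1e-9) stop("srna_mixture must sum to 1")
  if (abs(sum(cfg$ies_length_classes$weight) - 1) > 1e-9) {
    stop("ies_length_classes weights must sum to 1")
  }
  if (any(cfg$ies_length_classes$min > cfg$ies_length_classes$max) ||
      any(cfg$ies_length_classes$min < 5L)) {
    stop("IES length classes must have 5 <= min <= max")
  }
  sub <- with(cfg$ies_length_classes, sum(weight[max < 147L]))
  if (any(cfg$ies_length_classes$min < 147L & cfg$ies_length_classes$max >= 147L)) {
    stop("an IES length class may not straddle the nucleosome size (147 bp)")
  }
  if (abs(sub - cfg$frac_subnucleosomal) > 1e-9) {
    stop("weights of sub-nucleosomal classes (", sub,
         ") disagree with frac_subnucleosomal (", cfg$frac_subnucleosomal, ")")
  }
  maxfrag <- max(cfg$dna_fragment_length_range[2], cfg$nuc_fragment_length_range[2])
  if (cfg$nuc_fragment_length_range[1] < 1L ||
      cfg$nuc_fragment_length_range[2] > cfg$contig_length) {
    stop("nuc_fragment_length_range must lie within [1, contig_length]")
  }
  if (maxfrag > cfg$min_spacing) {
    stop("max fragment length (", maxfrag, ") must not exceed min_spacing (",
         cfg$min_spacing, ")")
  }
  if (any(c(cfg$occupancy_ev, cfg$occupancy_kd_strong, cfg$occupancy_kd_weak) < 0)) {
    stop("occupancy multipliers must be >= 0")
  }
  structure(cfg, class = c("SimulationConfig", "list"))
}

# Deterministic per-stage seed derived from the master seed and a stage name.
derive_seed <- function(seed, stage) {
  m <- 2147483647
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) %% m * 48271 + h * 8191) %% m)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a synthetic MAC / MAC+IES genome pair with ground truth
#'
#' IES lengths are drawn from the configured length classes, insertion points
#' are uniform with the configured minimum spacing, IES sequences begin and
#' end with "TA", and per-IES ground truth (strong/weak class, per-condition
#' retention probability and occupancy multiplier) is recorded.
#'
#' @param config a [sim_config()].
#' @return list with elements `genome` (a [genome_pair()]; auxiliary TE, OES
#'   and vector references in `$aux`) and `truth` (per-IES data.frame with
#'   columns `ies_id`, `length`, `strong`, `retention_EV_control`,
#'   `retention_KD`, `occupancy_EV_control`, `occupancy_KD`).
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(derive_seed(config$seed, "genome"))
  L <- config$contig_length
  sp <- config$min_spacing
  ctg_names <- sprintf("contig_%02d", seq_len(config$n_contigs))
  # allocate IESs over contigs as evenly as possible
  k <- rep(config$n_ies %/% config$n_contigs, config$n_contigs)
  extra <- config$n_ies %% config$n_contigs
  if (extra > 0L) k[seq_len(extra)] <- k[seq_len(extra)] + 1L
  slack <- L - 2L * sp - (pmax(k, 1L) - 1L) * sp
  if (any(k > 0L & slack < 0L)) {
    stop("n_ies too large for contig_length under the spacing constraint")
  }

  mac <- character(config$n_contigs)
  rows <- vector("list", config$n_contigs)
  ies_counter <- 0L
  for (ci in seq_len(config$n_contigs)) {
    seq_c <- .random_dna(L)
    kc <- k[ci]
    if (kc > 0L) {
      u <- sort(stats::runif(kc, 0, slack[ci]))
      ins <- as.integer(sp + floor(u) + (seq_len(kc) - 1L) * sp)
      # TA immediately after each insertion point (flanking convention)
      for (t in ins) substr(seq_c, t + 1L, t + 2L) <- "TA"
      cls <- sample.int(nrow(config$ies_length_classes), kc, replace = TRUE,
                        prob = config$ies_length_classes$weight)
      lo <- config$ies_length_classes$min[cls]
      hi <- config$ies_length_classes$max[cls]
      len <- lo + as.integer(floor(stats::runif(kc) * (hi - lo + 1L)))
      seqs <- vapply(len, function(l) paste0("TA", .random_dna(l - 4L), "TA"),
                     character(1))
      start <- ins + c(0L, cumsum(len[-kc]))
      rows[[ci]] <- data.frame(
        ies_id = sprintf("ies_%04d", ies_counter + seq_len(kc)),
        contig_id = ctg_names[ci], mac_insertion_point = ins,
        length = len, start = start, end = start + len,
        sequence = seqs, stringsAsFactors = FALSE)
      ies_counter <- ies_counter + kc
    } else {
      rows[[ci]] <- NULL
    }
    mac[ci] <- seq_c
  }
  ies <- do.call(rbind, rows)
  if (is.null(ies)) {
    ies <- data.frame(ies_id = character(), contig_id = character(),
                      mac_insertion_point = integer(), length = integer(),
                      start = integer(), end = integer(), sequence = character(),
                      stringsAsFactors = FALSE)
  }

  mac_ies <- mac
  for (ci in seq_len(config$n_contigs)) {
    sub <- ies[ies$contig_id == ctg_names[ci], ]
    if (nrow(sub) == 0L) next
    cuts <- c(0L, sub$mac_insertion_point, L)   # MDS block boundaries (0-based)
    pieces <- substring(mac[ci], cuts[-length(cuts)] + 1L, cuts[-1L])
    assembled <- character(2L * nrow(sub) + 1L)
    assembled[c(TRUE, FALSE)] <- pieces
    assembled[c(FALSE, TRUE)] <- sub$sequence
    mac_ies[ci] <- paste(assembled, collapse = "")
  }

  aux <- list(
    TE = Biostrings::DNAStringSet(stats::setNames(
      vapply(seq_len(config$n_te), function(i) .random_dna(config$te_length),
             character(1)),
      sprintf("TE_%02d", seq_len(config$n_te)))),
    OES = Biostrings::DNAStringSet(stats::setNames(
      vapply(seq_len(config$n_oes), function(i) .random_dna(config$oes_length),
             character(1)),
      sprintf("OES_%02d", seq_len(config$n_oes)))),
    vector = Biostrings::DNAStringSet(stats::setNames(
      .random_dna(config$vector_length), "vector_L4440")))

  gp <- genome_pair(
    Biostrings::DNAStringSet(stats::setNames(mac, ctg_names)),
    Biostrings::DNAStringSet(stats::setNames(mac_ies, ctg_names)),
    ies, aux = aux)

  n <- nrow(ies)
  strong <- stats::runif(n) < config$strong_fraction
  ret_kd <- ifelse(strong,
                   stats::runif(n, config$retention_kd_strong[1],
                                config$retention_kd_strong[2]),
                   stats::runif(n, config$retention_kd_weak[1],
                                config$retention_kd_weak[2]))
  truth <- data.frame(
    ies_id = ies$ies_id, length = ies$length, strong = strong,
    retention_EV_control = rep(config$retention_ev, n),
    retention_KD = ret_kd,
    occupancy_EV_control = rep(config$occupancy_ev, n),
    occupancy_KD = ifelse(strong, config$occupancy_kd_strong,
                          config$occupancy_kd_weak),
    stringsAsFactors = FALSE)
  list(genome = gp, truth = truth)
}

# Shared fragment sampler.
#
# Generative model (per fragment, independent draws):
#   1. outer distance l ~ Uniform{len_range};
#   2. template: maternal-MAC contaminant with prob c (every IES absent),
#      otherwise developing-MAC (IES i present with prob p_i, resampled per
#      fragment: the template-pool abstraction);
#   3. start position uniform over the positions existing on that template,
#      with the weight of every start whose fragment would cover IES i
#      multiplied by m_i (nucleosomal occupancy; 1 for DNA-seq).
# Realised as a mixture over disjoint start categories -- plain MDS
# background, "IES i present" (weight q_i * K_i(l) * m_i with
# q_i = (1-c) p_i and K_i(l) = len_i + l - 1 covering starts), and
# "IES i excised junction" (weight (1-q_i) * (l-1)) -- which is exact
# whenever q_i is 0 or 1 and a close approximation otherwise (see the
# methods vignette).
.sample_fragments <- function(genome, q, m, n, len_range, seed, lib_id,
                              condition_label) {
  set.seed(seed)
  ies <- genome$ies
  n_ies <- nrow(ies)
  ctgs <- names(genome$mac_ies)
  Lfull <- Biostrings::width(genome$mac_ies)
  names(Lfull) <- ctgs
  lens <- len_range[1] + floor(stats::runif(n) * (len_range[2] - len_range[1] + 1))
  lens <- as.integer(lens)

  out_ref <- character(n); out_start <- integer(n)
  out_sys <- integer(n)     # 1 = MAC+IES stream, 2 = MAC stream, 3 = both
  out_origin <- character(n)

  ctg_of_ies <- ies$contig_id
  for (l in sort(unique(lens))) {
    idx <- which(lens == l)
    nl <- length(idx)
    K <- if (n_ies) ies$length + l - 1L else integer(0)
    S_tot <- sum(Lfull - l + 1)
    S0 <- S_tot - sum(K)
    if (S0 <= 0) stop("IESs too dense: no IES-free start positions remain")
    w <- c(S0, q * K * m, (1 - q) * (l - 1L))
    cat_draw <- sample.int(2L * n_ies + 1L, nl, replace = TRUE, prob = w)
    # background: uniform non-covering start on MAC+IES
    bg <- idx[cat_draw == 1L]
    if (length(bg)) {
      nb <- length(bg)
      ref_i <- sample.int(length(ctgs), nb, replace = TRUE,
                          prob = Lfull - l + 1)
      s <- integer(nb)
      pending <- seq_len(nb)
      guard <- 0L
      while (length(pending) && guard < 1000L) {
        guard <- guard + 1L
        cand <- as.integer(floor(stats::runif(length(pending)) *
                                   (Lfull[ref_i[pending]] - l + 1)))
        covering <- rep(FALSE, length(pending))
        if (n_ies) {
          for (ci in seq_along(ctgs)) {
            sel <- which(genome$ies$contig_id == ctgs[ci])
            if (!length(sel)) next
            on_c <- which(ref_i[pending] == ci)
            if (!length(on_c)) next
            st <- ies$start[sel]; en <- ies$end[sel]
            j <- findInterval(cand[on_c] + l, c(rbind(st + 1L, en + l)))
            covering[on_c] <- j %% 2L == 1L
          }
        }
        s[pending[!covering]] <- cand[!covering]
        pending <- pending[covering]
      }
      out_ref[bg] <- ctgs[ref_i]
      out_start[bg] <- s
      out_sys[bg] <- 3L
      out_origin[bg] <- "background"
    }
    # IES present: covering start on MAC+IES
    pres <- idx[cat_draw >= 2L & cat_draw <= n_ies + 1L]
    if (length(pres)) {
      i <- cat_draw[match(pres, idx)] - 1L
      lo <- ies$start[i] - l + 1L
      hi <- ies$end[i] - 1L
      out_start[pres] <- as.integer(lo + floor(stats::runif(length(pres)) *
                                                 (hi - lo + 1)))
      out_ref[pres] <- ctg_of_ies[i]
      out_sys[pres] <- 1L
      out_origin[pres] <- "ies_present"
    }
    # junction: start on MAC crossing the excision point
    junc <- idx[cat_draw > n_ies + 1L]
    if (length(junc)) {
      i <- cat_draw[match(junc, idx)] - n_ies - 1L
      t <- ies$mac_insertion_point[i]
      out_start[junc] <- as.integer(t - l + 1L +
                                      floor(stats::runif(length(junc)) * (l - 1)))
      out_ref[junc] <- ctg_of_ies[i]
      out_sys[junc] <- 2L
      out_origin[junc] <- "junction"
    }
  }

  frag <- data.frame(
    read_id = sprintf("%s_%07d", lib_id, seq_len(n)),
    reference_id = out_ref, start = out_start, end = out_start + lens,
    outer_distance = lens, properly_paired = TRUE,
    condition_label = condition_label, origin = out_origin,
    stringsAsFactors = FALSE)

  # MAC+IES stream: background (lifted coordinates are the draw coordinates)
  # and IES-present fragments. MAC stream: background (lifted back) and
  # junction fragments.
  macies <- frag[out_sys %in% c(1L, 3L), , drop = FALSE]
  mac <- frag[out_sys %in% c(2L, 3L), , drop = FALSE]
  bgr <- mac$origin == "background"
  if (any(bgr)) {
    for (ctg in unique(mac$reference_id[bgr])) {
      i <- which(bgr & mac$reference_id == ctg)
      mac$start[i] <- macies_to_mac(genome, ctg, mac$start[i])
    }
    mac$end[bgr] <- mac$start[bgr] + mac$outer_distance[bgr]
  }
  rownames(macies) <- NULL; rownames(mac) <- NULL
  list(mac_ies = macies, mac = mac, n_requested = n,
       n_rejected = 0L)
}

.retention_column <- function(truth, condition_label) {
  col <- paste0("retention_", condition_label)
  if (!col %in% names(truth)) {
    stop("no retention column for condition ", condition_label)
  }
  truth[[col]]
}

.occupancy_column <- function(truth, condition_label) {
  col <- paste0("occupancy_", condition_label)
  if (!col %in% names(truth)) {
    stop("no occupancy column for condition ", condition_label)
  }
  truth[[col]]
}

#' Simulate a paired-end DNA-seq fragment library
#'
#' Fragments are drawn from a pool of developing-MAC templates (each IES
#' present with its per-condition retention probability, resampled per
#' fragment) mixed with IES-free maternal-MAC contaminants. Fragments
#' touching a present IES are emitted on the MAC+IES stream; junction
#' fragments from excised templates are emitted on the MAC stream; fragments
#' touching no IES appear on both, so that each stream is exactly what an
#' aligner would report against that reference.
#'
#' @param genome,truth output of [build_genome()].
#' @param config a [sim_config()].
#' @param condition_label `"EV_control"` or `"KD"`; selects the retention
#'   column of `truth`.
#' @param retain_all if `TRUE`, every IES is present in every developing
#'   template (emulates co-silencing of the excision machinery, as done for
#'   nucleosome profiling libraries).
#' @param n library size; defaults to `config$n_dna_fragments`.
#' @param seed integer; defaults to a seed derived from `config$seed`, the
#'   condition and the library type.
#' @return list with fragment data.frames `mac_ies` and `mac` (columns as in
#'   [read_alignments()], plus `origin`), and bookkeeping counts.
#' @export
simulate_dna_fragments <- function(genome, truth, config, condition_label,
                                   retain_all = FALSE,
                                   n = config$n_dna_fragments,
                                   seed = NULL) {
  if (sum(Biostrings::width(genome$mac)) == 0L) stop("empty genome")
  p <- if (retain_all) rep(1, nrow(truth)) else
    .retention_column(truth, condition_label)
  q <- (1 - config$contamination_fraction) * p
  if (is.null(seed)) {
    seed <- derive_seed(config$seed, paste0("dna_", condition_label,
                                            if (retain_all) "_retained" else ""))
  }
  .sample_fragments(genome, q = q, m = rep(1, nrow(truth)), n = n,
                    len_range = config$dna_fragment_length_range, seed = seed,
                    lib_id = paste0("dna_", condition_label),
                    condition_label = condition_label)
}

#' Simulate a nucleosomal (MNase-style) fragment library
#'
#' Like [simulate_dna_fragments()], but fragment lengths are drawn from the
#' mononucleosomal range and the sampling weight of every start position
#' whose fragment covers IES i is multiplied by that IES's occupancy
#' multiplier for the condition. By default every IES is present
#' (`retain_all = TRUE`), emulating the co-silenced excision machinery used
#' for nucleosome profiling.
#'
#' @inheritParams simulate_dna_fragments
#' @param occupancy optional numeric vector overriding the per-IES occupancy
#'   multipliers from `truth`.
#' @export
simulate_nucleosomal_fragments <- function(genome, truth, config,
                                           condition_label,
                                           retain_all = TRUE,
                                           occupancy = NULL,
                                           n = config$n_nuc_fragments,
                                           seed = NULL) {
  if (sum(Biostrings::width(genome$mac)) == 0L) stop("empty genome")
  m <- if (is.null(occupancy)) .occupancy_column(truth, condition_label) else
    rep_len(occupancy, nrow(truth))
  if (nrow(truth) > 0L && all(m == 0)) {
    stop("all occupancy multipliers are zero")
  }
  p <- if (retain_all) rep(1, nrow(truth)) else
    .retention_column(truth, condition_label)
  q <- (1 - config$contamination_fraction) * p
  if (is.null(seed)) {
    seed <- derive_seed(config$seed, paste0("nuc_", condition_label))
  }
  .sample_fragments(genome, q = q, m = m, n = n,
                    len_range = config$nuc_fragment_length_range, seed = seed,
                    lib_id = paste0("nuc_", condition_label),
                    condition_label = condition_label)
}

#' Simulate a small-RNA read set
#'
#' 25-nt reads are exact substrings of their source compartment (MDS = MAC
#' contigs, IES = IES sequences, OES / TE / vector = auxiliary references);
#' iesRNA-class reads (26-31 nt by default) are drawn exclusively from IES
#' sequences. Half of the reads are emitted as reverse complements.
#'
#' @param genome a [build_genome()] genome (needs `$aux` references).
#' @param config a [sim_config()].
#' @param mixture optional named mixture overriding `config$srna_mixture`.
#' @param n number of reads; defaults to `config$n_srna_reads`.
#' @param seed integer seed; derived from `config$seed` when `NULL`.
#' @return data.frame with columns `read_id`, `sequence`, `length` and the
#'   ground-truth `compartment`.
#' @export
simulate_srna_reads <- function(genome, config, mixture = NULL, n = NULL,
                                seed = NULL) {
  mx <- if (is.null(mixture)) config$srna_mixture else mixture
  if (abs(sum(mx) - 1) > 1e-9) stop("srna mixture must sum to 1")
  if (is.null(n)) n <- config$n_srna_reads
  if (is.null(seed)) seed <- derive_seed(config$seed, "srna")
  set.seed(seed)
  sources <- list(
    MDS_25 = as.character(genome$mac),
    IES_25 = genome$ies$sequence,
    OES_25 = as.character(genome$aux$OES),
    TE_25 = as.character(genome$aux$TE),
    vector_25 = as.character(genome$aux$vector),
    iesRNA = genome$ies$sequence)
  comp_of <- c(MDS_25 = "MDS", IES_25 = "IES", OES_25 = "OES", TE_25 = "TE",
               vector_25 = "vector", iesRNA = "IES")
  counts <- stats::rmultinom(1, n, mx[names(mx)])[, 1]
  out <- vector("list", length(counts))
  for (gi in seq_along(counts)) {
    cls <- names(mx)[gi]
    k <- counts[gi]
    if (k == 0L) { next }
    pool <- sources[[cls]]
    if (is.null(pool) || length(pool) == 0L) {
      stop("no source sequences for sRNA class ", cls)
    }
    lens <- if (cls == "iesRNA") {
      as.integer(config$iesrna_length_range[1] +
                   floor(stats::runif(k) * (config$iesrna_length_range[2] -
                                              config$iesrna_length_range[1] + 1)))
    } else rep(25L, k)
    if (max(lens) > max(nchar(pool))) {
      stop("requested sRNA length ", max(lens),
           " exceeds the longest source sequence for class ", cls)
    }
    src_len <- nchar(pool)
    seqs <- character(k)
    for (li in unique(lens)) {
      ii <- which(lens == li)
      elig <- which(src_len >= li)
      wts <- src_len[elig] - li + 1
      pick <- elig[sample.int(length(elig), length(ii), replace = TRUE,
                              prob = wts)]
      st <- 1L + as.integer(floor(stats::runif(length(ii)) *
                                    (src_len[pick] - li + 1)))
      seqs[ii] <- substring(pool[pick], st, st + li - 1L)
    }
    rc <- stats::runif(k) < 0.5
    if (any(rc)) {
      seqs[rc] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[rc])))
    }
    out[[gi]] <- data.frame(sequence = seqs, length = lens,
                            compartment = comp_of[[cls]],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[sample.int(nrow(res)), , drop = FALSE]   # shuffle classes
  res <- data.frame(read_id = sprintf("srna_%06d", seq_len(nrow(res))), res,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Write small-RNA reads as FASTA
#' @param reads data.frame from [simulate_srna_reads()].
#' @param path output path.
#' @export
write_srna_fasta <- function(reads, path) {
  write_fasta(stats::setNames(reads$sequence, reads$read_id), path)
}
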