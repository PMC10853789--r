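#' Generate a random circular genome
#'
#' I.i.d. bases with the given probabilities; deterministic given the seed.
#'
#' @param L Genome length (>= 1).
#' @param base_probs Named probabilities for A/C/G/T (must sum to 1).
#' @param seed Integer seed.
#' @param name Sequence name.
#' @return A `circular_genome`.
#' @export
sim_genome <- function(L, base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       seed = 1L, name = "sim_chrM") {
  stopifnot(L >= 1L)
  if (length(base_probs) != 4L || any(base_probs < 0) ||
      abs(sum(base_probs) - 1) > 1e-8) {
    stop("base_probs must be 4 non-negative values summing to 1")
  }
  bp <- base_probs[c("A", "C", "G", "T")]
  if (anyNA(bp)) stop("base_probs must be named A/C/G/T")
  seq <- withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = bp),
          collapse = "")
  })
  circular_genome(seq, name = name)
}

#' Generate a mitochondrial-style annotation layout
#'
#' Places `n_cds` non-overlapping plus-strand CDS regions with lengths drawn
#' uniformly in `size_range`, leaving the zone around the origin free for a
#' control region, an OriH region and a 7S-DNA region laid out with the
#' proportions of the human mitochondrial control region (control region
#' wrapping the origin, OriH and the 7S span inside it). Deterministic given
#' the seed.
#'
#' @param genome A `circular_genome` (needs `L >= 2000` for the
#'   control-region features).
#' @param n_cds Number of CDS regions.
#' @param size_range Length 2 vector `(min, max)` of CDS sizes.
#' @param seed Integer seed.
#' @return An `annotation_set`.
#' @export
sim_annotation <- function(genome, n_cds = 12L, size_range = c(300L, 1800L),
                           seed = 1L) {
  L <- genome$length
  stopifnot(n_cds >= 1L, size_range[1L] >= 1L,
            size_range[1L] <= size_range[2L])
  if (L < 2000L) stop("genome too short for a mitochondrial-style layout")
  # control-region block around the origin, human-proportioned
  cr_start <- L - 545L; cr_end <- 576L
  orih <- c(110L, 441L)
  seven <- c(L - 463L, 191L)
  coding_lo <- cr_end + 25L
  coding_hi <- cr_start - 25L
  avail <- coding_hi - coding_lo + 1L
  if (n_cds * size_range[1L] + n_cds > avail) {
    stop("infeasible packing: CDSs do not fit")
  }
  layout <- withr::with_seed(seed, {
    # draw sizes until the set fits the coding zone (deterministic given seed)
    for (try in 1:100) {
      lens <- sample(seq.int(size_range[1L], size_range[2L]), n_cds,
                     replace = TRUE)
      slack <- avail - sum(lens)
      if (slack >= n_cds) break
    }
    if (slack < n_cds) stop("infeasible packing: CDSs do not fit")
    # split the slack into n_cds + 1 non-negative gaps
    cuts <- sort(sample.int(slack + 1L, n_cds, replace = TRUE) - 1L)
    gaps <- diff(c(0L, cuts, slack))
    starts <- coding_lo + cumsum(gaps[seq_len(n_cds)]) +
      c(0L, cumsum(lens[-n_cds]))
    list(lens = lens, starts = starts)
  })
  annotation_set(
    name = c(sprintf("CDS%02d", seq_len(n_cds)), "control_region", "OriH",
             "seven_S"),
    start = c(layout$starts, cr_start, orih[1L], seven[1L]),
    end = c(layout$starts + layout$lens - 1L, cr_end, orih[2L], seven[2L]),
    strand = c(rep("+", n_cds), "both", "both", "both"),
    feature_type = c(rep("CDS", n_cds), "control_region", "OriH", "seven_S"),
    genome_length = L
  )
}

#' Simulate an rNMP library with controllable structure, plus a truth table
#'
#' Emulates the post-alignment product of a ribose-seq-style experiment:
#' stranded single-nucleotide rNMP records on a circular genome with (i) a
#' global light/heavy strand bias, (ii) per-base composition bias, (iii)
#' planted rNMP-enriched zones, (iv) planted single-nucleotide hotspots and
#' (v) base-mismatch noise emulating sequencing error.
#'
#' Sampling model: each record draws its strand from
#' `Bernoulli(light_fraction)` and its position from a categorical
#' distribution whose per-position weight is the composition weight of the
#' reference base on that strand, times the zone multiplier if the slot lies
#' in a planted zone, times `1 + cds_size_effect * len(CDS) / max_len` for
#' light-strand positions inside a CDS. The rNMP identity is the
#' strand-correct reference base; with probability `mismatch_rate` the
#' observed base is flipped to a random different base (flips are logged in
#' the truth table, and are exactly what [filter_mismatches()] removes).
#' Planted hotspots are topped up after sampling so their counts are minima.
#'
#' @param genome A `circular_genome`.
#' @param annotation Optional `annotation_set` (needed for `cds_size_effect`).
#' @param n_rnmps Number of sampled records.
#' @param light_fraction Probability that a record is on the light strand.
#' @param composition_weights Named non-negative weights for A/C/G/T (the
#'   rNMP identity in the DNA alphabet; T weight governs rU).
#' @param rez_spec List of lists with `start`, `end`, `strand` ("+", "-" or
#'   "both") and `multiplier >= 0`: planted enriched (or depleted) zones.
#' @param hotspot_spec List of lists with `pos`, `strand`, `min_count`:
#'   planted hotspots topped up to at least `min_count` records.
#' @param mismatch_rate Probability of flipping a record's observed base.
#' @param cds_size_effect Non-negative coupling of light-strand CDS weight to
#'   CDS length (0 disables).
#' @param seed Integer seed.
#' @param library_id,cell_category,genotype,fragmentation Library metadata.
#' @return List with `library` (an `rnmp_library`) and `truth` (list with
#'   per-slot `weights`, `hotspots`, `rez`, and `mismatches`: one row per
#'   flipped record with `pos`, `strand`, `true_base`, `observed_base`).
#' @export
sim_library <- function(genome, annotation = NULL, n_rnmps = 50000L,
                        light_fraction = 0.75,
                        composition_weights = c(A = 1, C = 1.5, G = 1, T = 0.5),
                        rez_spec = list(), hotspot_spec = list(),
                        mismatch_rate = 0, cds_size_effect = 0,
                        seed = 1L, library_id = "simlib",
                        cell_category = "sim", genotype = "RNH2A_WT",
                        fragmentation = "fragmentase") {
  L <- genome$length
  stopifnot(light_fraction >= 0, light_fraction <= 1,
            mismatch_rate >= 0, mismatch_rate <= 1, cds_size_effect >= 0)
  cw <- composition_weights[c("A", "C", "G", "T")]
  if (anyNA(cw) || any(cw < 0) || sum(cw) == 0) {
    stop("composition_weights must be named non-negative A/C/G/T weights")
  }
  min_total <- sum(vapply(hotspot_spec, function(h) h$min_count, numeric(1L)))
  if (n_rnmps < min_total) {
    stop("n_rnmps smaller than the sum of hotspot minimum counts")
  }
  base_plus <- genome$chars
  base_minus <- unname(COMPLEMENT[base_plus])
  w <- list("+" = unname(cw[base_plus]), "-" = unname(cw[base_minus]))
  for (z in rez_spec) {
    if (z$multiplier < 0) stop("zone multiplier must be >= 0")
    pos <- region_positions(z$start, z$end, L)
    for (s in if (identical(z$strand, "both")) c("+", "-") else z$strand) {
      w[[s]][pos] <- w[[s]][pos] * z$multiplier
    }
  }
  if (cds_size_effect > 0 && !is.null(annotation)) {
    cds <- annotation[annotation$feature_type == "CDS" &
                        annotation$strand == "+", , drop = FALSE]
    if (nrow(cds) > 0L) {
      max_len <- max(cds$length)
      for (i in seq_len(nrow(cds))) {
        pos <- region_positions(cds$start[i], cds$end[i], L)
        w[["+"]][pos] <- w[["+"]][pos] *
          (1 + cds_size_effect * cds$length[i] / max_len)
      }
    }
  }
  if (sum(w[["+"]]) == 0 && light_fraction > 0) stop("all light-strand weights zero")
  if (sum(w[["-"]]) == 0 && light_fraction < 1) stop("all heavy-strand weights zero")
  sim <- withr::with_seed(seed, {
    n_light <- stats::rbinom(1L, n_rnmps, light_fraction)
    pos_l <- if (n_light > 0L) {
      sample.int(L, n_light, replace = TRUE, prob = w[["+"]])
    } else integer(0)
    pos_h <- if (n_rnmps - n_light > 0L) {
      sample.int(L, n_rnmps - n_light, replace = TRUE, prob = w[["-"]])
    } else integer(0)
    rec <- data.frame(
      pos = c(pos_l, pos_h),
      strand = rep(c("+", "-"), c(length(pos_l), length(pos_h))),
      stringsAsFactors = FALSE
    )
    rec$base <- ifelse(rec$strand == "+", base_plus[rec$pos],
                       base_minus[rec$pos])
    # top up planted hotspots to their minimum counts
    for (h in hotspot_spec) {
      have <- sum(rec$pos == h$pos & rec$strand == h$strand)
      if (have < h$min_count) {
        add <- h$min_count - have
        b <- if (h$strand == "+") base_plus[h$pos] else base_minus[h$pos]
        rec <- rbind(rec, data.frame(pos = rep(h$pos, add),
                                     strand = rep(h$strand, add),
                                     base = rep(b, add),
                                     stringsAsFactors = FALSE))
      }
    }
    rec$true_base <- rec$base
    flip <- stats::runif(nrow(rec)) < mismatch_rate
    if (any(flip)) {
      rec$base[flip] <- vapply(rec$true_base[flip], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1L))
    }
    list(rec = rec, flip = flip)
  })
  rec <- sim$rec
  truth <- list(
    weights = w,
    hotspots = if (length(hotspot_spec)) {
      do.call(rbind, lapply(hotspot_spec, as.data.frame))
    } else data.frame(pos = integer(0), strand = character(0),
                      min_count = integer(0)),
    rez = if (length(rez_spec)) {
      do.call(rbind, lapply(rez_spec, as.data.frame))
    } else data.frame(start = integer(0), end = integer(0),
                      strand = character(0), multiplier = numeric(0)),
    mismatches = data.frame(pos = rec$pos[sim$flip],
                            strand = rec$strand[sim$flip],
                            true_base = rec$true_base[sim$flip],
                            observed_base = rec$base[sim$flip],
                            stringsAsFactors = FALSE)
  )
  lib <- rnmp_library(rec[c("pos", "strand", "base")], library_id,
                      cell_category, genotype, fragmentation)
  list(library = lib, truth = truth)
}

#' Simulate a uniformly random rNMP library (size-study control)
#'
#' Records are uniform over all `2 * L` (position, strand) slots with the
#' reference base as identity and no mismatch noise — the random control used
#' to validate gene-size correlation analyses (canonical sizes 10,000,
#' 100,000 and 1,000,000 records).
#'
#' @param genome A `circular_genome`.
#' @param n Number of records (>= 0).
#' @param seed Integer seed.
#' @param library_id,cell_category Library metadata.
#' @return An `rnmp_library`.
#' @export
sim_random_library <- function(genome, n, seed = 1L,
                               library_id = sprintf("random_%d", n),
                               cell_category = "random_control") {
  stopifnot(n >= 0L)
  L <- genome$length
  rec <- withr::with_seed(seed, {
    slot <- sample.int(2L * L, n, replace = TRUE)
    pos <- (slot - 1L) %% L + 1L
    strand <- ifelse(slot > L, "-", "+")
    data.frame(pos = pos, strand = strand, stringsAsFactors = FALSE)
  })
  rec$base <- ifelse(rec$strand == "+", genome$chars[rec$pos],
                     unname(COMPLEMENT[genome$chars[rec$pos]]))
  rnmp_library(rec, library_id, cell_category,
               genotype = "other", fragmentation = "unknown")
}

#' Simulate a per-base sequencing depth track
#'
#' Depth `base_depth * multiplier` inside the region and `base_depth`
#' outside, plus Gaussian noise truncated at zero. Deterministic given the
#' seed. Emulates the depth input of 7S-DNA abundance profiling.
#'
#' @param genome A `circular_genome`.
#' @param region One-row region (may wrap the origin).
#' @param multiplier Depth multiplier inside the region (>= 0).
#' @param base_depth Baseline depth (> 0).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Numeric vector of length `L`.
#' @export
sim_depth_track <- function(genome, region, multiplier = 1, base_depth = 100,
                            noise_sd = 0, seed = 1L) {
  stopifnot(base_depth > 0, multiplier >= 0, noise_sd >= 0)
  L <- genome$length
  depth <- rep(base_depth, L)
  depth[region_positions(region$start, region$end, L)] <-
    base_depth * multiplier
  if (noise_sd > 0) {
    depth <- withr::with_seed(seed, pmax(depth + stats::rnorm(L, 0, noise_sd), 0))
  }
  depth
}

#' De Bruijn sequence genome over the DNA alphabet
#'
#' Builds a circular sequence of length `4^k` containing every k-mer exactly
#' once (an Eulerian circuit over the (k-1)-mer graph). Useful as a
#' uniform-context genome: every dinucleotide and trinucleotide background
#' count is constant, so background-normalized context frequencies of a
#' context-uniform library are exactly 0.25 (dinucleotide) and 0.0625
#' (trinucleotide).
#'
#' @param k K-mer order (>= 1).
#' @param name Sequence name.
#' @return A `circular_genome` of length `4^k`.
#' @export
debruijn_genome <- function(k = 3L, name = sprintf("debruijn_k%d", k)) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  bases <- c("A", "C", "G", "T")
  if (k == 1L) return(circular_genome("ACGT", name = name))
  nodes <- all_kmers(k - 1L)
  # Hierholzer's algorithm on the de Bruijn graph: nodes are (k-1)-mers,
  # each node has out-edges labelled A/C/G/T
  next_edge <- stats::setNames(rep(1L, length(nodes)), nodes)
  stack <- nodes[1L]
  circuit <- character(0)
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    if (next_edge[v] <= 4L) {
      b <- bases[next_edge[v]]
      next_edge[v] <- next_edge[v] + 1L
      stack <- c(stack, paste0(substr(v, 2L, k - 1L), b))
    } else {
      circuit <- c(circuit, v)
      stack <- stack[-length(stack)]
    }
  }
  # edge labels along the reversed circuit give the sequence
  circuit <- rev(circuit)
  labels <- vapply(circuit[-1L], function(v) substr(v, k - 1L, k - 1L),
                   character(1L))
  circular_genome(paste(labels, collapse = ""), name = name)
}
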