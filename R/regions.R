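count_in_region <- function(records, start, end, strand = NULL) {
  keep <- in_region(records$pos, start, end)
  if (!is.null(strand)) keep <- keep & records$strand == strand
  sum(keep)
}

#' Per-gene rNMP frequency table
#'
#' For every annotated feature of the requested type, reports the rNMP count,
#' PPB and EF on both strand roles. The non-template role is the strand the
#' feature is annotated on (the sense strand, matching the mRNA); the
#' template role is its complement. The dC and dG counts of the non-template
#' strand sequence are included for composition-correlation analyses.
#'
#' @param library An `rnmp_library`.
#' @param annotation An `annotation_set`.
#' @param genome A `circular_genome`.
#' @param feature_type "CDS" (default), "rRNA" or "tRNA".
#' @return Data frame with one row per (gene, strand role): columns `gene`,
#'   `length`, `gene_strand`, `role`, `r_g`, `ppb`, `ef`, `dc_nontemplate`,
#'   `dg_nontemplate`.
#' @export
gene_ppb_table <- function(library, annotation, genome,
                           feature_type = c("CDS", "rRNA", "tRNA")) {
  feature_type <- match.arg(feature_type)
  genes <- annotation[annotation$feature_type == feature_type, , drop = FALSE]
  if (nrow(genes) == 0L) stop("no features of type ", feature_type)
  rt <- n_rnmps(library)
  if (rt == 0L) stop("empty library")
  L <- genome$length
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (!g$strand %in% c("+", "-")) {
      stop("gene strand must be '+' or '-' for strand-role analysis: ", g$name)
    }
    sense_seq <- paste(genome$chars[region_positions(g$start, g$end, L)],
                       collapse = "")
    if (g$strand == "-") sense_seq <- revcomp(sense_seq)
    dc <- sum(strsplit(sense_seq, "", fixed = TRUE)[[1L]] == "C")
    dg <- sum(strsplit(sense_seq, "", fixed = TRUE)[[1L]] == "G")
    one_role <- function(role) {
      strand <- if (role == "non_template") g$strand
                else setdiff(c("+", "-"), g$strand)
      r_g <- count_in_region(library$records, g$start, g$end, strand)
      data.frame(gene = g$name, length = g$length, gene_strand = g$strand,
                 role = role, r_g = r_g,
                 ppb = ppb(r_g, rt, g$length),
                 ef = enrichment_factor(r_g, rt, g$length, 2 * L),
                 dc_nontemplate = dc, dg_nontemplate = dg,
                 stringsAsFactors = FALSE)
    }
    rbind(one_role("non_template"), one_role("template"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation of gene size (and base content) with rNMP frequency
#'
#' Spearman correlation of gene length versus PPB restricted to one strand
#' role, plus the corresponding correlations against the dC and dG counts of
#' the non-template strand.
#'
#' @param table Output of [gene_ppb_table()].
#' @param role "non_template" (default) or "template".
#' @return List with `rho_size`, `p_size`, `rho_dc`, `p_dc`, `rho_dg`,
#'   `p_dg`, and `n_genes`.
#' @export
size_correlation <- function(table, role = c("non_template", "template")) {
  role <- match.arg(role)
  sub <- table[table$role == role, , drop = FALSE]
  if (nrow(sub) < 3L) stop("need >= 3 genes")
  size <- spearman_cor(sub$length, sub$ppb)
  dc <- spearman_cor(sub$dc_nontemplate, sub$ppb)
  dg <- spearman_cor(sub$dg_nontemplate, sub$ppb)
  list(rho_size = size$rho, p_size = size$p_value,
       rho_dc = dc$rho, p_dc = dc$p_value,
       rho_dg = dg$rho, p_dg = dg$p_value,
       n_genes = nrow(sub))
}

#' Strand split of rNMPs inside one region
#'
#' Percentage of the records falling inside the (possibly wrapped) region
#' that lie on the light and heavy strands, e.g. for the OriH region or the
#' whole control region.
#'
#' @param library An `rnmp_library`.
#' @param region One-row region (data frame or list with `start`, `end`).
#' @return Named numeric vector `c(light = , heavy = )` summing to 100.
#' @export
region_strand_percentages <- function(library, region) {
  r <- library$records
  keep <- in_region(r$pos, region$start, region$end)
  n <- sum(keep)
  if (n == 0L) stop("empty region: no rNMPs inside")
  light <- sum(keep & r$strand == "+")
  c(light = 100 * light / n, heavy = 100 * (n - light) / n)
}

runs_to_intervals <- function(positions, above) {
  # maximal runs of TRUE along the ordered (possibly wrapped) position walk
  if (!any(above)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  rl <- rle(above)
  ends_idx <- cumsum(rl$lengths)
  starts_idx <- ends_idx - rl$lengths + 1L
  keep <- rl$values
  data.frame(start = positions[starts_idx[keep]],
             end = positions[ends_idx[keep]])
}

#' Smoothed rNMP profile and peak calls for the control region
#'
#' Computes the circular moving-average PPB track on each strand, restricts
#' it to the (possibly origin-wrapping) region, and calls peaks as maximal
#' runs where the smoothed PPB exceeds `peak_factor` times the genome-wide
#' per-base mean PPB (`1 / (2 * L)`). The run-based peak rule is a
#' formalization of what is usually judged by eye on control-region profiles;
#' the factor is configurable.
#'
#' @param library An `rnmp_library`.
#' @param genome A `circular_genome`.
#' @param region One-row region covering the control region (may wrap).
#' @param window Odd moving-average window (default 51 nt).
#' @param peak_factor Multiple of the genome mean PPB a run must exceed
#'   (default 1.5).
#' @param bins Optional `bin_grid`; when given, each peak lists the ids of
#'   overlapping same-strand bins.
#' @return List with `tracks` (data frame `pos`, `strand`, `smoothed_ppb`
#'   along the region) and `peaks` (data frame `strand`, `start`, `end`,
#'   `length`, optionally `bins`); attribute `threshold` holds the cutoff.
#' @export
control_region_profile <- function(library, genome, region, window = 51L,
                                   peak_factor = 1.5, bins = NULL) {
  L <- genome$length
  pos <- region_positions(region$start, region$end, L)
  threshold <- peak_factor / (2 * L)
  tracks <- list(); peaks <- list()
  for (strand in c("+", "-")) {
    sm <- moving_average_ppb(library, genome, strand, window)
    tracks[[strand]] <- data.frame(pos = pos, strand = strand,
                                   smoothed_ppb = sm[pos],
                                   stringsAsFactors = FALSE)
    iv <- runs_to_intervals(pos, sm[pos] > threshold)
    if (nrow(iv) > 0L) {
      iv$strand <- strand
      peaks[[strand]] <- iv
    }
  }
  peaks <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(start = integer(0), end = integer(0), strand = character(0))
  rownames(peaks) <- NULL
  if (nrow(peaks) > 0L) {
    peaks$length <- region_length(peaks$start, peaks$end, L)
    if (!is.null(bins)) {
      peaks$bins <- vapply(seq_len(nrow(peaks)), function(i) {
        same <- bins[bins$strand == peaks$strand[i], , drop = FALSE]
        hit <- vapply(seq_len(nrow(same)), function(j) {
          any(in_region(region_positions(peaks$start[i], peaks$end[i], L),
                        same$start[j], same$end[j]))
        }, logical(1L))
        paste(same$bin[hit], collapse = ",")
      }, character(1L))
    }
  }
  out <- list(tracks = do.call(rbind, tracks),
              peaks = peaks[, c("strand", "start", "end",
                                setdiff(names(peaks),
                                        c("strand", "start", "end"))),
                            drop = FALSE])
  rownames(out$tracks) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' Relative abundance of the 7S DNA region from a depth track
#'
#' Mean sequencing depth inside the (possibly wrapped) region divided by the
#' genome-wide mean depth. A ratio above 1 indicates that the region is
#' over-represented among sequenced molecules, as expected when many genomes
#' carry the three-stranded D-loop.
#'
#' @param depth Numeric per-base depth vector over positions `1..L`.
#' @param region One-row region (e.g. the annotated 7S DNA span).
#' @return Numeric ratio.
#' @export
seven_s_abundance <- function(depth, region) {
  L <- length(depth)
  stopifnot(all(depth >= 0))
  gm <- mean(depth)
  if (gm <= 0) stop("zero genome-wide mean depth")
  mean(depth[region_positions(region$start, region$end, L)]) / gm
}

#' Read a per-base depth track (TSV with columns pos, depth)
#'
#' @param path Path to the TSV file.
#' @param L Genome length; every position `1..L` must be present.
#' @return Numeric vector of length `L`.
#' @export
read_depth_track <- function(path, L) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  if (!all(c("pos", "depth") %in% names(dt))) {
    stop("depth track must have columns 'pos' and 'depth'")
  }
  out <- rep(NA_real_, L)
  out[dt$pos] <- dt$depth
  if (anyNA(out)) stop("depth track does not cover every position 1..L")
  if (any(out < 0)) stop("negative depth")
  out
}

#' Write a per-base depth track as TSV
#'
#' @param depth Numeric vector of per-base depth.
#' @param path Output path.
#' @export
write_depth_track <- function(depth, path) {
  data.table::fwrite(data.table::data.table(pos = seq_along(depth),
                                            depth = depth),
                     path, sep = "\t")
  invisible(path)
}
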