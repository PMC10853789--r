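slot_counts <- function(library) {
  r <- library$records
  agg <- stats::aggregate(list(count = rep(1L, nrow(r))),
                          by = list(pos = r$pos, strand = r$strand), FUN = sum)
  agg[order(agg$pos, agg$strand), , drop = FALSE]
}

#' Single-nucleotide rNMP hotspots common to all libraries
#'
#' A hotspot is a (position, strand) slot carrying at least one rNMP in every
#' library of the set. The table reports per-library counts and
#' single-nucleotide enrichment factors (`len_G = 1`, `len_basis = 2 * L`),
#' plus the median EF across libraries used for ranking.
#'
#' @param libraries Non-empty list of non-empty `rnmp_library` objects.
#' @param genome A `circular_genome`.
#' @return Data frame with columns `pos`, `strand`, `base` (reference base on
#'   the slot's strand), `count_<id>` and `ef_<id>` per library, and
#'   `median_ef`.
#' @export
common_hotspots <- function(libraries, genome) {
  stopifnot(length(libraries) >= 1L)
  if (any(vapply(libraries, n_rnmps, integer(1L)) == 0L)) {
    stop("empty library")
  }
  L <- genome$length
  keys <- lapply(libraries, function(lib) {
    with(lib$records, unique(paste(pos, strand)))
  })
  common <- Reduce(intersect, keys)
  if (length(common) == 0L) {
    return(data.frame(pos = integer(0), strand = character(0),
                      base = character(0), median_ef = numeric(0)))
  }
  parts <- strsplit(common, " ", fixed = TRUE)
  out <- data.frame(pos = as.integer(vapply(parts, `[`, "", 1L)),
                    strand = vapply(parts, `[`, "", 2L),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$base <- reference_base_on_strand(genome, out$pos, out$strand)
  efs <- matrix(0, nrow(out), length(libraries))
  for (j in seq_along(libraries)) {
    lib <- libraries[[j]]
    key <- paste(lib$records$pos, lib$records$strand)
    cnt <- table(key)[paste(out$pos, out$strand)]
    cnt <- as.integer(cnt)
    out[[paste0("count_", lib$library_id)]] <- cnt
    efs[, j] <- enrichment_factor(cnt, n_rnmps(lib), 1L, 2 * L)
    out[[paste0("ef_", lib$library_id)]] <- efs[, j]
  }
  out$median_ef <- apply(efs, 1L, stats::median)
  out
}

#' Rank hotspots by median enrichment factor
#'
#' Sorted by median single-nucleotide EF descending; ties broken by
#' ascending position, then light before heavy strand. When `categories` is
#' given, per-category mean EF columns are appended (mean of the `ef_*`
#' columns of that category's libraries).
#'
#' @param table Hotspot table from [common_hotspots()].
#' @param k Number of top rows to return (default 20).
#' @param categories Optional named character vector mapping library id to
#'   cell category.
#' @return The top `min(k, nrow)` rows, with a `rank` column.
#' @export
rank_hotspots <- function(table, k = 20L, categories = NULL) {
  if (nrow(table) == 0L) return(table)
  stopifnot(k >= 1L)
  ord <- order(-table$median_ef, table$pos, match(table$strand, c("+", "-")))
  out <- table[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(categories)) {
    ef_cols <- grep("^ef_", names(out), value = TRUE)
    ids <- sub("^ef_", "", ef_cols)
    for (ct in unique(categories[ids])) {
      cols <- ef_cols[categories[ids] == ct]
      out[[paste0("mean_ef_", ct)]] <-
        rowMeans(out[, cols, drop = FALSE])
    }
  }
  out <- utils::head(out, k)
  out$rank <- seq_len(nrow(out))
  out
}

#' High-frequency rNMP sites (top 1% most abundant slots)
#'
#' Among the slots carrying at least one rNMP in the library, selects the
#' `ceiling(top_frac * n_covered)` slots with the highest counts; slots tied
#' with the cutoff count are all included, which makes the selection
#' deterministic and invariant to duplicating every record.
#'
#' @param library A non-empty `rnmp_library`.
#' @param top_frac Fraction of covered slots to select (default 0.01).
#' @return Data frame with columns `pos`, `strand`, `count`.
#' @export
high_frequency_sites <- function(library, top_frac = 0.01) {
  if (n_rnmps(library) == 0L) stop("empty library")
  sc <- slot_counts(library)
  n_sel <- ceiling(top_frac * nrow(sc))
  cutoff <- sort(sc$count, decreasing = TRUE)[n_sel]
  out <- sc[sc$count >= cutoff, , drop = FALSE]
  out <- out[order(-out$count, out$pos, match(out$strand, c("+", "-"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Position frequency matrix of the sequence context around rNMP sites
#'
#' Extracts the strand-aware `±flank` window around every site (minus-strand
#' windows reverse-complemented so all read 5'->3' with the rNMP at the
#' centre) and tabulates per-column base probabilities. The centre column is
#' the rNMP identity distribution. Output is consumable by sequence-logo
#' tools.
#'
#' @param sites Data frame with columns `pos` and `strand`.
#' @param genome A `circular_genome`.
#' @param flank Bases on each side (default 3, i.e. 7-mer windows).
#' @return 4 x (2*flank+1) numeric matrix, rows A/C/G/T, columns
#'   `-flank..+flank`; every column sums to 1.
#' @export
context_pfm <- function(sites, genome, flank = 3L) {
  stopifnot(nrow(sites) >= 1L)
  wins <- extract_window(genome, sites$pos, sites$strand, flank = flank)
  m <- do.call(rbind, strsplit(wins, "", fixed = TRUE))
  width <- 2L * flank + 1L
  pfm <- vapply(seq_len(width), function(j) {
    tab <- table(factor(m[, j], levels = c("A", "C", "G", "T")))
    as.numeric(tab) / nrow(m)
  }, numeric(4L))
  rownames(pfm) <- c("A", "C", "G", "T")
  colnames(pfm) <- as.character(seq.int(-flank, flank))
  pfm
}
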