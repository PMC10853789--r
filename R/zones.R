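#' Tile both strands of a circular genome into fixed-size bins
#'
#' Per strand, consecutive bins `[1, bin_size]`, `[bin_size + 1, 2 *
#' bin_size]`, ... anchored at position 1, with the short remainder as the
#' last bin. For the 16,569-nt human mitochondrial genome with the default
#' 200-nt bins this yields 83 bins per strand (last bin 169 nt), 166 in
#' total. Bins on the light (plus) strand are named `L01..`, heavy-strand
#' bins `H01..`.
#'
#' @param L Genome length.
#' @param bin_size Bin width in nt (default 200).
#' @return Data frame of class `bin_grid` with columns `bin`, `strand`,
#'   `start`, `end`, `length`; attributes `L` and `bin_size`.
#' @export
make_bins <- function(L, bin_size = 200L) {
  L <- as.integer(L); bin_size <- as.integer(bin_size)
  if (bin_size < 1L || bin_size > L) stop("bin_size must be in [1, L]")
  starts <- seq.int(1L, L, by = bin_size)
  ends <- pmin(starts + bin_size - 1L, L)
  n <- length(starts)
  fmt <- paste0("%s%0", max(2L, nchar(n)), "d")
  one <- function(strand, tag) {
    data.frame(bin = sprintf(fmt, tag, seq_len(n)), strand = strand,
               start = starts, end = ends, length = ends - starts + 1L,
               stringsAsFactors = FALSE)
  }
  grid <- rbind(one("+", "L"), one("-", "H"))
  structure(grid, L = L, bin_size = bin_size,
            class = c("bin_grid", "data.frame"))
}

bin_counts <- function(library, grid) {
  L <- attr(grid, "L"); bs <- attr(grid, "bin_size")
  n <- ceiling(L / bs)
  r <- library$records
  idx <- (r$pos - 1L) %/% bs + 1L
  c(tabulate(idx[r$strand == "+"], nbins = n),
    tabulate(idx[r$strand == "-"], nbins = n))
}

#' Per-bin rNMP enrichment factors for one library
#'
#' EF per bin via [enrichment_factor()] with the two-strand length basis
#' (`len_basis = 2 * L`), so the bin-length-weighted mean EF of the full grid
#' is exactly 1 for any library.
#'
#' @param library An `rnmp_library`.
#' @param grid A `bin_grid`.
#' @return The grid with added columns `count` and `ef`.
#' @export
bin_enrichment <- function(library, grid) {
  rt <- n_rnmps(library)
  if (rt == 0L) stop("empty library")
  out <- grid
  out$count <- bin_counts(library, grid)
  out$ef <- enrichment_factor(out$count, rt, out$length, 2 * attr(grid, "L"))
  out
}

#' EF matrix (bins x libraries) for a set of libraries
#'
#' @param libraries List of `rnmp_library` objects.
#' @param grid A `bin_grid`.
#' @return Numeric matrix, one row per bin (rownames = bin ids), one column
#'   per library (colnames = library ids).
#' @export
bin_ef_matrix <- function(libraries, grid) {
  cols <- lapply(libraries, function(lib) bin_enrichment(lib, grid)$ef)
  m <- do.call(cbind, cols)
  rownames(m) <- grid$bin
  colnames(m) <- vapply(libraries, `[[`, "", "library_id")
  m
}

#' Flag rNMP-enriched zones (REZs)
#'
#' A bin is an enriched zone in a library iff its EF strictly exceeds the
#' threshold (default 1, i.e. above genome-average density).
#'
#' @param ef Numeric vector or matrix of EF values.
#' @param threshold Enrichment threshold (strict inequality).
#' @return Logical object of the same shape.
#' @export
detect_rez <- function(ef, threshold = 1) ef > threshold

#' Common REZs across cell categories and libraries
#'
#' A bin is a common REZ iff (a) in every cell category the mean EF across
#' that category's libraries exceeds the threshold, and (b) at least
#' `library_fraction` of all libraries flag the bin as enriched. The
#' per-category rule is configurable to "any enriched library per category".
#'
#' @param ef_matrix EF matrix from [bin_ef_matrix()] (bins x libraries).
#' @param categories Character vector assigning each column to a category.
#' @param library_fraction Minimum supporting fraction of all libraries
#'   (compared with `>=`; default 0.8).
#' @param threshold EF enrichment threshold (default 1).
#' @param category_rule "mean_ef" (default) or "any_library".
#' @return Data frame per bin: `bin`, `lib_fraction`, `all_categories`,
#'   `common`.
#' @export
common_rez <- function(ef_matrix, categories, library_fraction = 0.8,
                       threshold = 1, category_rule = c("mean_ef", "any_library")) {
  category_rule <- match.arg(category_rule)
  stopifnot(length(categories) == ncol(ef_matrix))
  if (any(!nzchar(categories)) || any(is.na(categories))) {
    stop("every library must be assigned to a non-empty category")
  }
  enriched <- detect_rez(ef_matrix, threshold)
  lib_fraction <- rowMeans(enriched)
  cats <- unique(categories)
  per_cat <- vapply(cats, function(ct) {
    sub <- ef_matrix[, categories == ct, drop = FALSE]
    if (category_rule == "mean_ef") rowMeans(sub) > threshold
    else rowSums(detect_rez(sub, threshold)) >= 1L
  }, logical(nrow(ef_matrix)))
  per_cat <- matrix(per_cat, nrow = nrow(ef_matrix))
  all_categories <- rowSums(per_cat) == length(cats)
  data.frame(bin = rownames(ef_matrix),
             lib_fraction = lib_fraction,
             all_categories = all_categories,
             common = all_categories & lib_fraction >= library_fraction,
             stringsAsFactors = FALSE)
}

#' Background-coverage enrichment factor per bin
#'
#' Per-bin mean sequencing depth divided by the genome-wide mean depth; used
#' to check that rNMP-enriched zones are not fragmentation/coverage
#' artifacts. Depth is unstranded, so the two strand copies of a positional
#' bin receive the same value.
#'
#' @param depth Numeric vector of per-base depth over positions `1..L`.
#' @param grid A `bin_grid` with matching `L`.
#' @return The grid with an added `ef` column.
#' @export
coverage_bin_ef <- function(depth, grid) {
  L <- attr(grid, "L")
  stopifnot(length(depth) == L, all(depth >= 0))
  gm <- mean(depth)
  if (gm <= 0) stop("zero mean depth")
  out <- grid
  out$ef <- vapply(seq_len(nrow(grid)), function(i) {
    mean(depth[grid$start[i]:grid$end[i]]) / gm
  }, numeric(1L))
  out
}
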