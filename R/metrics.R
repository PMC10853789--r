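#' rNMP embedment probability per base (PPB)
#'
#' `PPB = R_G / (Length(G) * R_total)`: the probability that a given captured
#' rNMP of the library sits on any one nucleotide of region G. Comparable
#' across regions of different size and across libraries of different depth.
#'
#' @param r_g rNMP count inside the region (vectorized).
#' @param r_total Total rNMP count of the library.
#' @param len_g Region length in nt.
#' @return Numeric PPB value(s) in `[0, 1/len_g]`.
#' @export
ppb <- function(r_g, r_total, len_g) {
  if (any(r_total <= 0)) stop("empty library (R_total == 0)")
  stopifnot(all(len_g >= 1), all(r_g >= 0), all(r_g <= r_total))
  r_g / (len_g * r_total)
}

#' rNMP enrichment factor (EF)
#'
#' `EF = (R_G / R_total) * (len_basis / Length(G))`: the rNMP density of a
#' region relative to the genome-wide average density. `len_basis` is the
#' total number of positions over which `R_total` is counted — `2 * L` when
#' both strands are analysed, `L` for a single-strand analysis — which makes
#' EF a pure density ratio whose length-weighted mean over any partition of
#' the counted positions is exactly 1, and makes `EF > 1` the natural
#' enrichment criterion.
#'
#' @inheritParams ppb
#' @param len_basis Total positions over which `r_total` is counted.
#' @return Numeric EF value(s), >= 0.
#' @export
enrichment_factor <- function(r_g, r_total, len_g, len_basis) {
  if (any(r_total <= 0)) stop("empty library (R_total == 0)")
  stopifnot(all(len_g >= 1), all(len_basis >= len_g))
  (r_g / r_total) * (len_basis / len_g)
}

# per-base rNMP counts of one strand as a length-L integer vector
strand_count_track <- function(library, L, strand) {
  pos <- library$records$pos[library$records$strand == strand]
  tabulate(pos, nbins = L)
}

#' Moving average of the per-base PPB along one strand
#'
#' The per-base PPB track (`len_G = 1`) is smoothed with a centred circular
#' moving average; the default 51-nt window is the standard choice for
#' control-region profiling. Circular wrap means the window never truncates
#' at the origin — essential because the control region spans it.
#'
#' @param library An `rnmp_library`.
#' @param genome A `circular_genome`.
#' @param strand "+" (light) or "-" (heavy).
#' @param window Odd window size in nt.
#' @return Numeric vector of length L: smoothed PPB at each position.
#' @export
moving_average_ppb <- function(library, genome, strand = "+", window = 51L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  stopifnot(window >= 1L, window < genome$length)
  rt <- n_rnmps(library)
  if (rt == 0L) stop("empty library (R_total == 0)")
  track <- strand_count_track(library, genome$length, strand) / rt
  as.numeric(stats::filter(track, rep(1 / window, window),
                           method = "convolution", sides = 2,
                           circular = TRUE))
}

#' Percentage of rNMPs on the light and heavy strands
#'
#' @param library An `rnmp_library` (plus strand = light).
#' @return Named numeric vector `c(light = , heavy = )` summing to 100.
#' @export
strand_percentages <- function(library) {
  n <- n_rnmps(library)
  if (n == 0L) stop("empty library")
  light <- sum(library$records$strand == "+")
  c(light = 100 * light / n, heavy = 100 * (n - light) / n)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. The p-value is exact (full
#' enumeration of the U distribution) when `min(n, m) <= 8` and the combined
#' sample has no ties; otherwise the normal approximation with tie and
#' continuity correction is used. This is the workhorse test for strand-bias
#' and pattern-preference comparisons (significance level 0.05 throughout).
#'
#' @param x,y Numeric samples (both non-empty).
#' @param alternative "two_sided", "greater" or "less" (x relative to y).
#' @return List of class `mwu_test` with `statistic` (U of `x`), `p_value`,
#'   `alternative` and `method` ("exact" or "normal_approx").
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[alternative]
  if (length(unique(c(x, y))) == 1L) {
    # fully tied samples: U is at its null mean and no evidence either way
    return(structure(list(statistic = length(x) * length(y) / 2, p_value = 1,
                          alternative = alternative, method = "normal_approx"),
                     class = "mwu_test"))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && min(length(x), length(y)) <= 8L
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt, exact = use_exact,
                       correct = TRUE)
  )
  structure(list(statistic = unname(res$statistic), p_value = res$p.value,
                 alternative = alternative,
                 method = if (use_exact) "exact" else "normal_approx"),
            class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, p = %.4g (%s, %s)\n",
              x$statistic, x$p_value, x$alternative, x$method))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with the p-value from the t
#' approximation on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return List with `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    stop("constant input: rank correlation undefined")
  }
  res <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(res$estimate), p_value = res$p.value)
}
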