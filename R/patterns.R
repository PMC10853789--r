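RNMP_LABELS <- c(A = "rA", C = "rC", G = "rG", T = "rU")

scope_strands <- function(scope = c("both", "light", "heavy")) {
  scope <- match.arg(scope)
  switch(scope, light = "+", heavy = "-", both = c("+", "-"))
}

scope_bg_strand <- function(scope) {
  switch(scope, light = "+", heavy = "-", both = "both")
}

#' Background-normalized rNMP composition
#'
#' Per base `b`, the raw frequency is the rNMP count of identity `b` in the
#' requested strand scope divided by the background count of `b` in the
#' reference genome on the same scope; the four frequencies are then
#' renormalized to sum to 1. A library whose rNMP counts are proportional to
#' the background therefore scores 0.25 everywhere.
#'
#' @param library An `rnmp_library`.
#' @param genome A `circular_genome`.
#' @param scope "both", "light" (plus strand) or "heavy" (minus strand).
#' @return Named numeric 4-vector (`rA`, `rC`, `rG`, `rU`) summing to 1.
#' @export
rnmp_composition <- function(library, genome, scope = c("both", "light", "heavy")) {
  scope <- match.arg(scope)
  r <- library$records[library$records$strand %in% scope_strands(scope), ]
  if (nrow(r) == 0L) stop("no rNMPs in scope '", scope, "'")
  counts <- table(factor(r$base, levels = c("A", "C", "G", "T")))
  bg <- count_background(genome, scope_bg_strand(scope), k = 1L)
  if (any(counts > 0 & bg == 0)) {
    stop("rNMP observed for a base with zero background count")
  }
  f <- ifelse(bg > 0, as.numeric(counts) / bg, 0)
  out <- f / sum(f)
  names(out) <- unname(RNMP_LABELS)
  out
}

# neighbour context of each record, read 5'->3' on the record's strand
record_contexts <- function(library, genome, mode) {
  flank <- 2L
  wins <- extract_window(genome, library$records$pos, library$records$strand,
                         flank = flank)
  switch(mode,
         NR = substr(wins, flank, flank),             # 5' neighbour
         RN = substr(wins, flank + 2L, flank + 2L),   # 3' neighbour
         NNR = substr(wins, flank - 1L, flank))       # two 5' neighbours
}

#' Background-normalized dinucleotide / trinucleotide rNMP context frequencies
#'
#' For each record the upstream (`NR`), downstream (`RN`) or two-upstream
#' (`NNR`) reference neighbours are read 5'->3' on the record's strand with
#' circular wrap; the raw count of every context x rNMP pattern is divided by
#' the circular background count of the corresponding k-mer on the same
#' strand scope, then normalized within each rNMP column so the column sums
#' to 1. Patterns with zero background count are reported as 0 and flagged in
#' the `zero_background` attribute so matrix shapes stay stable across
#' libraries.
#'
#' @param library An `rnmp_library`.
#' @param genome A `circular_genome`.
#' @param mode "NR" (upstream dNMP + rNMP), "RN" (rNMP + downstream dNMP) or
#'   "NNR" (two upstream dNMPs + rNMP).
#' @param scope "both", "light" or "heavy".
#' @return Numeric matrix, one row per context (4 for NR/RN, 16 for NNR) and
#'   one column per rNMP type (`rA`, `rC`, `rG`, `rU`); columns sum to 1
#'   unless all raw frequencies in the column are zero.
#' @export
pattern_frequencies <- function(library, genome, mode = c("NR", "RN", "NNR"),
                                scope = c("both", "light", "heavy")) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  keep <- library$records$strand %in% scope_strands(scope)
  lib <- library
  lib$records <- library$records[keep, , drop = FALSE]
  if (nrow(lib$records) == 0L) stop("no rNMPs in scope '", scope, "'")
  ctx <- record_contexts(lib, genome, mode)
  contexts <- all_kmers(if (mode == "NNR") 2L else 1L)
  bases <- c("A", "C", "G", "T")
  raw <- table(factor(ctx, levels = contexts),
               factor(lib$records$base, levels = bases))
  k <- if (mode == "NNR") 3L else 2L
  bg_k <- count_background(genome, scope_bg_strand(scope), k = k)
  # background k-mer for each (context, rNMP) cell, in pattern orientation
  kmer_of <- if (mode == "RN") {
    function(ct, b) paste0(b, ct)
  } else {
    function(ct, b) paste0(ct, b)
  }
  bg <- outer(contexts, bases, function(ct, b) bg_k[kmer_of(ct, b)])
  if (any(raw > 0 & bg == 0)) {
    stop("rNMP context observed for a pattern with zero background count")
  }
  f <- ifelse(bg > 0, as.matrix(raw) / bg, 0)
  colsum <- colSums(f)
  norm <- sweep(f, 2L, ifelse(colsum > 0, colsum, 1), "/")
  dimnames(norm) <- list(contexts, unname(RNMP_LABELS))
  attr(norm, "zero_background") <- bg == 0
  attr(norm, "mode") <- mode
  attr(norm, "scope") <- scope
  norm
}

#' Test a context pattern's preference against its null expectation
#'
#' Compares the per-library normalized frequencies of one pattern against the
#' no-preference expectation (0.25 for dinucleotide, 0.0625 for trinucleotide
#' patterns). The default reading executes a Mann-Whitney U test between the
#' sample and a constant pseudo-sample of the expectation with midrank ties;
#' a one-sample Wilcoxon signed-rank test is available as an alternative
#' formalization of the same comparison.
#'
#' @param freqs Numeric vector of per-library normalized frequencies for one
#'   pattern (needs >= 3 libraries).
#' @param expectation Null value: 0.25 (NR/RN) or 0.0625 (NNR).
#' @param alternative "greater" (preference, default), "less" or "two_sided".
#' @param method "mwu_constant" (default) or "signed_rank".
#' @return An `mwu_test`-style result list with `statistic`, `p_value`,
#'   `alternative`, `method`.
#' @export
pattern_preference_test <- function(freqs, expectation = 0.25,
                                    alternative = c("greater", "less", "two_sided"),
                                    method = c("mwu_constant", "signed_rank")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (length(freqs) < 3L) stop("need >= 3 libraries")
  if (method == "mwu_constant") {
    return(mann_whitney_u(freqs, rep(expectation, length(freqs)),
                          alternative = alternative))
  }
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[alternative]
  res <- suppressWarnings(
    stats::wilcox.test(freqs, mu = expectation, alternative = alt,
                       exact = FALSE, correct = TRUE)
  )
  structure(list(statistic = unname(res$statistic), p_value = res$p.value,
                 alternative = alternative, method = "signed_rank"),
            class = "mwu_test")
}

#' Decompose the strand bias into per-rNMP-type contributions
#'
#' Each rNMP type's embedment rate on a strand is its count divided by the
#' background count of that base on the strand. For the library's preferred
#' strand (the one carrying the larger share of records), the rate difference
#' versus the other strand is computed per type; types with a positive
#' difference share the contribution proportionally (`contribution_pct`), and
#' the final contribution rescales by the overall embedment-percentage
#' difference `delta = share_preferred - share_other` (kept as a fraction),
#' so final contributions sum to `delta` when all differences are positive.
#'
#' @param library An `rnmp_library` with records on both strands.
#' @param genome A `circular_genome`.
#' @return List with `preferred_strand` ("light"/"heavy"), `delta`,
#'   `symmetric` flag, and `table`: one row per rNMP type with columns
#'   `rnmp`, `rate_preferred`, `rate_other`, `diff`, `contribution_pct`,
#'   `contribution`.
#' @export
strand_bias_contribution <- function(library, genome) {
  r <- library$records
  n <- nrow(r)
  if (n == 0L) stop("empty library")
  n_light <- sum(r$strand == "+")
  if (n_light == 0L || n_light == n) {
    stop("records required on both strands")
  }
  share <- c(light = n_light / n, heavy = (n - n_light) / n)
  preferred <- names(which.max(share))
  other <- setdiff(c("light", "heavy"), preferred)
  rate <- function(scope) {
    strand <- scope_strands(scope)
    counts <- table(factor(r$base[r$strand == strand],
                           levels = c("A", "C", "G", "T")))
    bg <- count_background(genome, scope_bg_strand(scope), k = 1L)
    ifelse(bg > 0, as.numeric(counts) / bg, 0)
  }
  rate_pref <- rate(preferred)
  rate_other <- rate(other)
  d <- rate_pref - rate_other
  pos <- pmax(d, 0)
  delta <- unname(share[preferred] - share[other])
  symmetric <- sum(pos) == 0
  pct <- if (symmetric) rep(0, 4L) else pos / sum(pos)
  list(preferred_strand = preferred, delta = delta, symmetric = symmetric,
       table = data.frame(rnmp = unname(RNMP_LABELS),
                          rate_preferred = rate_pref, rate_other = rate_other,
                          diff = d, contribution_pct = pct,
                          contribution = pct * delta,
                          stringsAsFactors = FALSE))
}
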