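# Independent oracles and fixture builders used across the suite.

# Exact Mann-Whitney p-value by full enumeration of label assignments.
# U convention matches the rank-sum statistic of x (number of (x, y) pairs
# with x > y); two-sided doubles the smaller tail as in the classical test.
mwu_enum_p <- function(x, y, alternative) {
  z <- c(x, y)
  n <- length(x); m <- length(y)
  u_of <- function(idx) {
    xs <- z[idx]; ys <- z[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  us <- apply(utils::combn(n + m, n), 2L, u_of)
  u_obs <- u_of(seq_len(n))
  switch(alternative,
         less = mean(us <= u_obs),
         greater = mean(us >= u_obs),
         two_sided = {
           p <- if (u_obs > n * m / 2) 2 * mean(us >= u_obs)
                else 2 * mean(us <= u_obs)
           min(p, 1)
         })
}

# Brute-force common-slot intersection over libraries: every (pos, strand)
# slot of the genome is checked against every library by direct counting.
brute_force_common_slots <- function(libraries, L) {
  out <- character(0)
  for (pos in seq_len(L)) {
    for (strand in c("+", "-")) {
      ok <- all(vapply(libraries, function(lib) {
        sum(lib$records$pos == pos & lib$records$strand == strand) >= 1L
      }, logical(1L)))
      if (ok) out <- c(out, paste(pos, strand))
    }
  }
  out
}

# A library with one record per (position, strand) slot carrying the
# reference base: its context counts equal the background k-mer counts.
all_slots_library <- function(genome, strands = c("+", "-")) {
  L <- genome$length
  recs <- do.call(rbind, lapply(strands, function(s) {
    base <- if (s == "+") genome$chars else chartr("ACGT", "TGCA", genome$chars)
    data.frame(pos = seq_len(L), strand = s, base = base,
               stringsAsFactors = FALSE)
  }))
  rnmp_library(recs, library_id = "all_slots")
}

# Small deterministic library from explicit vectors.
make_library <- function(pos, strand, base, id = "toy", category = "toy") {
  rnmp_library(data.frame(pos = pos, strand = strand, base = base,
                          stringsAsFactors = FALSE),
               library_id = id, cell_category = category)
}

# Fixed 12-interval CDS layout on a mitochondrial-scale genome, shared by
# the size-correlation tests.
fixture_genome_annotation <- function(seed = 11L) {
  genome <- sim_genome(16569L, seed = seed)
  list(genome = genome, annotation = sim_annotation(genome, seed = seed))
}
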