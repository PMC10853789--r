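test_that("rnmp_composition normalizes by background base counts", {
  # plus-strand background A:30, C:20, G:25, T:25; light rA = 6, rC = 4
  # -> raw frequencies 0.2 and 0.2, renormalized to (0.5, 0.5, 0, 0)
  seq <- paste(rep(c("A", "C", "G", "T"), c(30L, 20L, 25L, 25L)),
               collapse = "")
  g <- circular_genome(seq)
  lib <- make_library(c(1:6, 31:34), rep("+", 10L),
                      rep(c("A", "C"), c(6L, 4L)))
  comp <- rnmp_composition(lib, g, scope = "light")
  expect_equal(unname(comp), c(0.5, 0.5, 0, 0))
  expect_equal(sum(comp), 1)

  # counts proportional to background -> uniform 0.25
  unif <- all_slots_library(g)
  expect_equal(unname(rnmp_composition(unif, g, "both")), rep(0.25, 4L))
})

test_that("pattern_frequencies reads neighbours 5'->3' on the record strand", {
  g <- circular_genome("ACGTACGT")
  lib <- make_library(2L, "+", "C")  # upstream neighbour is A at pos 1
  nr <- pattern_frequencies(lib, g, "NR", "light")
  expect_equal(unname(nr[, "rC"]), c(1, 0, 0, 0))
  expect_equal(sum(nr[, "rC"]), 1)

  # downstream neighbour of the same record is G
  rn <- pattern_frequencies(lib, g, "RN", "light")
  expect_equal(unname(rn[, "rC"]), c(0, 0, 1, 0))

  # minus-strand record: neighbours read on the reverse complement
  lib2 <- make_library(2L, "-", "G")  # minus 5' neighbour = complement of pos 3
  nr2 <- pattern_frequencies(lib2, g, "NR", "heavy")
  expect_equal(unname(nr2["C", "rG"]), 1)
})

test_that("uniform-context libraries give exactly 0.25 / 0.0625 everywhere", {
  g <- debruijn_genome(3L)
  lib <- all_slots_library(g)
  nr <- pattern_frequencies(lib, g, "NR", "both")
  expect_equal(as.vector(nr), rep(0.25, 16L), tolerance = 1e-15)
  nnr <- pattern_frequencies(lib, g, "NNR", "both")
  expect_equal(as.vector(nnr), rep(0.0625, 64L), tolerance = 1e-15)
  rn <- pattern_frequencies(lib, g, "RN", "both")
  expect_equal(as.vector(rn), rep(0.25, 16L), tolerance = 1e-15)
})

test_that("every rNMP column of a pattern matrix sums to 1", {
  g <- sim_genome(3000L, seed = 1L)
  lib <- sim_library(g, n_rnmps = 5000L, seed = 2L)$library
  for (mode in c("NR", "RN", "NNR")) {
    for (scope in c("both", "light", "heavy")) {
      m <- pattern_frequencies(lib, g, mode, scope)
      expect_equal(unname(colSums(m)), rep(1, 4L),
                   label = paste(mode, scope))
    }
  }
})

test_that("composition is invariant under genome complement + strand swap", {
  g <- sim_genome(1000L, seed = 3L)
  lib <- sim_library(g, n_rnmps = 2000L, seed = 4L)$library
  g_comp <- circular_genome(chartr("ACGT", "TGCA", g$seq))
  lib_swap <- lib
  lib_swap$records$strand <- ifelse(lib$records$strand == "+", "-", "+")
  expect_equal(rnmp_composition(lib, g, "both"),
               rnmp_composition(lib_swap, g_comp, "both"))
})

test_that("pattern_preference_test rejects planted preferences", {
  res <- pattern_preference_test(rep(0.5, 6L), expectation = 0.25,
                                 alternative = "greater")
  expect_lt(res$p_value, 0.05)
  flat <- pattern_preference_test(rep(0.25, 6L), expectation = 0.25,
                                  alternative = "two_sided")
  expect_equal(flat$p_value, 1)
  sr <- pattern_preference_test(c(0.5, 0.52, 0.48, 0.55, 0.5, 0.51), 0.25,
                                "greater", method = "signed_rank")
  expect_lt(sr$p_value, 0.05)
  expect_error(pattern_preference_test(c(0.5, 0.5), 0.25), "3 libraries")
})

test_that("a planted CrC preference is recovered and significant", {
  g <- sim_genome(4000L, seed = 5L)
  # rC records drawn from plus-strand C positions with upstream-C weight x4
  c_pos <- which(g$chars == "C")
  upstream_c <- g$chars[wrap_position(g$length, c_pos - 1L)] == "C"
  w <- ifelse(upstream_c, 4, 1)
  freqs <- vapply(1:6, function(i) {
    pos <- withr::with_seed(100L + i, {
      sample(c_pos, 800L, replace = TRUE, prob = w)
    })
    lib <- make_library(pos, rep("+", 800L), rep("C", 800L))
    pattern_frequencies(lib, g, "NR", "light")["C", "rC"]
  }, numeric(1L))
  expect_true(all(freqs > 0.25))
  expect_lt(pattern_preference_test(freqs, 0.25, "greater")$p_value, 0.05)
})

test_that("strand_bias_contribution decomposes the strand excess", {
  # genome with 100 of each base on the plus strand
  g <- circular_genome(paste(rep("ACGT", 100L), collapse = ""))
  build <- function(light_counts, heavy_counts) {
    bases <- c("A", "C", "G", "T")
    pos_of <- function(b) which(g$chars == b)
    recs <- list()
    for (i in 1:4) {
      if (light_counts[i] > 0) {
        recs[[length(recs) + 1L]] <- data.frame(
          pos = pos_of(bases[i])[seq_len(light_counts[i])], strand = "+",
          base = bases[i], stringsAsFactors = FALSE)
      }
      if (heavy_counts[i] > 0) {
        comp <- c(A = "T", C = "G", G = "C", T = "A")[bases[i]]
        recs[[length(recs) + 1L]] <- data.frame(
          pos = pos_of(comp)[seq_len(heavy_counts[i])], strand = "-",
          base = bases[i], stringsAsFactors = FALSE)
      }
    }
    rnmp_library(do.call(rbind, recs), "contrib")
  }
  # light (3,4,1,2), heavy (2,2,2,2): diffs (1,2,-1,0)/100, delta = 1/9
  sb <- strand_bias_contribution(build(c(3L, 4L, 1L, 2L), rep(2L, 4L)), g)
  expect_identical(sb$preferred_strand, "light")
  expect_equal(sb$delta, 1 / 9)
  expect_equal(sb$table$contribution_pct, c(1 / 3, 2 / 3, 0, 0))
  expect_equal(sb$table$contribution, c(1 / 27, 2 / 27, 0, 0))
  expect_equal(sum(sb$table$contribution_pct), 1)

  # all-positive diffs: contributions sum to delta
  sb2 <- strand_bias_contribution(build(rep(2L, 4L), rep(1L, 4L)), g)
  expect_equal(sum(sb2$table$contribution), sb2$delta)

  # strand-symmetric library: flagged, zero contributions, delta = 0
  sb3 <- strand_bias_contribution(build(rep(2L, 4L), rep(2L, 4L)), g)
  expect_true(sb3$symmetric)
  expect_equal(sb3$delta, 0)
  expect_equal(sb3$table$contribution, rep(0, 4L))
})
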