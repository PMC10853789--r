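test_that("wrap_position agrees with a brute-force rotation table", {
  L <- 100L
  # oracle: explicit rotation table built by walking the circle
  table_pos <- rep(seq_len(L), times = 5L)
  offset <- 2L * L  # table_pos[i + 2L] corresponds to position i
  for (pos in seq.int(-2L * L + 1L, 2L * L)) {
    expect_identical(wrap_position(L, pos), table_pos[pos + offset])
  }
  expect_identical(wrap_position(100L, 1L), 1L)
  expect_identical(wrap_position(100L, 105L), 5L)
  expect_identical(wrap_position(100L, 0L), 100L)
  # periodicity
  pos <- c(-7L, 3L, 42L, 99L)
  expect_identical(wrap_position(L, pos), wrap_position(L, pos + 3L * L))
})

test_that("extract_window handles circular wrap and strand orientation", {
  g <- circular_genome("ACGT")
  expect_identical(extract_window(g, 1, "+", 1), "TAC")
  expect_identical(extract_window(g, 2, "-", 1), "CGT")  # revcomp of ACG
  expect_identical(extract_window(g, 3, "+", 0), "G")
  expect_error(extract_window(g, 1, "+", 4), "flank")
  # plus and minus windows at the same centre are reverse complements
  g2 <- sim_genome(200L, seed = 3L)
  centers <- c(1L, 7L, 100L, 200L)
  plus <- extract_window(g2, centers, "+", 5L)
  minus <- extract_window(g2, centers, "-", 5L)
  revcomp_oracle <- function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1L]])), collapse = "")
  }
  expect_identical(minus, vapply(plus, revcomp_oracle, "", USE.NAMES = FALSE))
})

test_that("count_background counts circular k-mers with strand symmetry", {
  g <- circular_genome("AACG")
  expect_identical(count_background(g, "+", 1),
                   c(A = 2L, C = 1L, G = 1L, T = 0L))
  expect_identical(count_background(g, "-", 1),
                   c(A = 0L, C = 1L, G = 1L, T = 2L))
  g2 <- sim_genome(500L, seed = 9L)
  for (k in 1:3) {
    plus <- count_background(g2, "+", k)
    minus <- count_background(g2, "-", k)
    expect_identical(sum(plus), 500L)
    expect_identical(sum(minus), 500L)
    expect_identical(sum(count_background(g2, "both", k)), 1000L)
  }
  # complement symmetry at k = 1
  p1 <- count_background(g2, "+", 1); m1 <- count_background(g2, "-", 1)
  expect_identical(unname(p1[c("A", "C", "G", "T")]),
                   unname(m1[c("T", "G", "C", "A")]))
})

test_that("FASTA reading enforces a single clean record", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">seq1", "acgt"), f)
  g <- read_genome_fasta(f)
  expect_identical(g$seq, "ACGT")
  expect_identical(g$length, 4L)

  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), f2)
  expect_error(read_genome_fasta(f2), "exactly one sequence")

  f3 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACNT"), f3)
  expect_error(read_genome_fasta(f3), "position 3")
})

test_that("genome FASTA write/read round trips bit-exactly", {
  g <- sim_genome(777L, seed = 5L, name = "toy")
  f <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g, f)
  g2 <- read_genome_fasta(f)
  expect_identical(g2$seq, g$seq)
  expect_identical(g2$name, g$name)
})

test_that("BED annotation converts coordinates and merges wrap pairs", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrM\t0\t100\tGENE1\t.\t+",
               "chrM\t16023\t16569\tDLOOP\t.\t+",
               "chrM\t0\t576\tDLOOP\t.\t+"), f)
  ann <- read_annotation(f, 16569L)
  g1 <- ann[ann$name == "GENE1", ]
  expect_identical(c(g1$start, g1$end), c(1L, 100L))
  expect_identical(g1$strand, "+")
  dl <- ann[ann$name == "DLOOP", ]
  expect_identical(c(dl$start, dl$end), c(16024L, 576L))
  expect_identical(dl$length, 16569L - 16024L + 1L + 576L)

  f2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrM\t0\t100\tX", f2)  # too few columns
  expect_error(read_annotation(f2, 16569L), "line 1")
  f3 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrM\t50\t17000\tX\t.\t+", f3)
  expect_error(read_annotation(f3, 16569L), "line 1")
})

test_that("GTF annotation passes 1-based coordinates through", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste(c("chrM", "test", "CDS", "3307", "4262", ".", "+", ".",
                     'gene_id "ND1"; gene_name "MT-ND1";'),
                   collapse = "\t"), f)
  ann <- read_annotation(f, 16569L)
  cds <- ann[ann$feature_type == "CDS", ]
  expect_identical(nrow(cds), 1L)
  expect_identical(c(cds$start, cds$end), c(3307L, 4262L))
  expect_identical(cds$strand, "+")
  expect_identical(cds$name, "MT-ND1")
})

test_that("annotation BED write/read round trips all fields", {
  ann <- annotation_set(
    name = c("ND1", "t1", "CR"),
    start = c(300L, 900L, 950L), end = c(800L, 940L, 100L),
    strand = c("+", "-", "both"),
    feature_type = c("CDS", "tRNA", "control_region"),
    genome_length = 1000L)
  f <- withr::local_tempfile(fileext = ".bed")
  write_annotation_bed(ann, f, chrom = "toy")
  ann2 <- read_annotation(f, 1000L)
  ann2 <- ann2[match(ann$name, ann2$name), ]
  for (col in c("name", "start", "end", "strand", "feature_type", "length")) {
    expect_identical(unname(unlist(ann2[[col]])), unname(unlist(ann[[col]])),
                     label = col)
  }
})

test_that("region arithmetic honours origin wrap", {
  expect_identical(region_length(10L, 20L, 100L), 11L)
  expect_identical(region_length(95L, 5L, 100L), 11L)
  expect_identical(region_positions(98L, 2L, 100L), c(98L, 99L, 100L, 1L, 2L))
  expect_true(all(in_region(c(98L, 1L), 98L, 2L)))
  expect_false(in_region(50L, 98L, 2L))
})
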