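test_that("gene_ppb_table matches the PPB/EF formulas row by row", {
  g <- sim_genome(100L, seed = 1L)
  ann <- annotation_set("G1", 11L, 20L, "+", "CDS", 100L)
  # 5 light records inside the gene, 45 records elsewhere on the heavy strand
  lib <- make_library(c(11:15, rep(60L, 45L)),
                      rep(c("+", "-"), c(5L, 45L)),
                      c(g$chars[11:15],
                        rep(chartr("ACGT", "TGCA", g$chars[60L]), 45L)))
  tab <- gene_ppb_table(lib, ann, g, "CDS")
  nt <- tab[tab$role == "non_template", ]
  expect_equal(nt$ppb, 0.01)  # 5 / (10 * 50)
  expect_equal(nt$ppb, ppb(nt$r_g, 50L, nt$length))
  expect_equal(nt$ef, enrichment_factor(nt$r_g, 50L, nt$length, 200L))
  tmpl <- tab[tab$role == "template", ]
  expect_identical(tmpl$r_g, 0L)
  expect_equal(tmpl$ppb, 0)
  # dC/dG of the non-template (annotated) strand sequence
  sense <- g$chars[11:20]
  expect_identical(nt$dc_nontemplate, sum(sense == "C"))
  expect_identical(nt$dg_nontemplate, sum(sense == "G"))
  expect_error(gene_ppb_table(lib, ann, g, "tRNA"), "no features")

  # cross-implementation identity on a simulated mitochondrial-scale run
  fx <- fixture_genome_annotation()
  lib2 <- sim_library(fx$genome, fx$annotation, n_rnmps = 10000L,
                      seed = 2L)$library
  tab2 <- gene_ppb_table(lib2, fx$annotation, fx$genome, "CDS")
  expect_equal(tab2$ppb, ppb(tab2$r_g, 10000L, tab2$length))
  expect_true(sum(tab2$r_g[tab2$role == "non_template"]) <= 10000L)
})

test_that("size_correlation recovers coupling and stays null on uniform input", {
  fx <- fixture_genome_annotation()
  # length-coupled light-strand embedment: strong positive correlation
  lib <- sim_library(fx$genome, fx$annotation, n_rnmps = 100000L,
                     light_fraction = 0.5,
                     composition_weights = c(A = 1, C = 1, G = 1, T = 1),
                     cds_size_effect = 1, seed = 3L)$library
  sc <- size_correlation(gene_ppb_table(lib, fx$annotation, fx$genome, "CDS"))
  expect_gte(sc$rho_size, 0.6)
  expect_identical(sc$n_genes, 12L)

  # uniform random libraries: mean rho near 0 over seeded replicates
  rhos <- vapply(1:20, function(i) {
    ulib <- sim_random_library(fx$genome, 10000L, seed = 200L + i)
    size_correlation(gene_ppb_table(ulib, fx$annotation, fx$genome,
                                    "CDS"))$rho_size
  }, numeric(1L))
  expect_lt(abs(mean(rhos)), 0.1)

  # rank invariance: permuting gene rows leaves rho unchanged
  tab <- gene_ppb_table(lib, fx$annotation, fx$genome, "CDS")
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(size_correlation(perm)$rho_size, sc$rho_size)
})

test_that("region_strand_percentages splits records inside a region", {
  lib <- make_library(c(120:127, 200L, 210L, 500L),
                      c(rep("+", 8L), "-", "-", "+"), rep("A", 11L))
  orih <- list(start = 110L, end = 441L)
  expect_equal(region_strand_percentages(lib, orih),
               c(light = 80, heavy = 20))
  whole <- list(start = 1L, end = 16569L)
  expect_equal(region_strand_percentages(lib, whole),
               strand_percentages(lib))
  one_sided <- make_library(115:119, rep("+", 5L), rep("A", 5L))
  expect_equal(region_strand_percentages(one_sided, orih),
               c(light = 100, heavy = 0))
  expect_error(region_strand_percentages(one_sided,
                                         list(start = 600L, end = 700L)),
               "empty region")
})

test_that("control_region_profile calls peaks only where planted", {
  fx <- fixture_genome_annotation()
  cr <- fx$annotation[fx$annotation$feature_type == "control_region", ][1L, ]
  grid <- make_bins(fx$genome$length)

  # uniform library: no peaks inside the control region
  ulib <- sim_random_library(fx$genome, 50000L, seed = 4L)
  pu <- control_region_profile(ulib, fx$genome, cr)
  expect_identical(nrow(pu$peaks), 0L)

  # planted zone inside the region -> peak overlapping the planted bin
  zone <- list(start = 16101L, end = 16300L, strand = "+", multiplier = 5)
  sim <- sim_library(fx$genome, n_rnmps = 50000L, light_fraction = 0.5,
                     composition_weights = c(A = 1, C = 1, G = 1, T = 1),
                     rez_spec = list(zone), seed = 5L)
  pp <- control_region_profile(sim$library, fx$genome, cr, bins = grid)
  expect_gt(nrow(pp$peaks), 0L)
  expect_true(all(pp$peaks$strand == "+"))
  planted_bins <- grid$bin[grid$strand == "+" &
                             grid$start <= 16300L & grid$end >= 16101L]
  expect_true(any(vapply(strsplit(pp$peaks$bins, ","), function(b) {
    any(b %in% planted_bins)
  }, logical(1L))))

  # scale invariance: duplicating every record leaves the peaks unchanged
  dup <- sim$library
  dup$records <- rbind(dup$records, dup$records)
  pd <- control_region_profile(dup, fx$genome, cr, bins = grid)
  expect_identical(pd$peaks[c("strand", "start", "end")],
                   pp$peaks[c("strand", "start", "end")])
  expect_error(control_region_profile(sim$library, fx$genome, cr,
                                      window = 50L), "odd")
})

test_that("seven_s_abundance is a scale-invariant depth ratio", {
  expect_equal(seven_s_abundance(rep(10, 1000L),
                                 list(start = 901L, end = 100L)), 1)
  d <- rep(10, 1000L)
  d[101:300] <- 20  # region of 200 nt doubled
  region <- list(start = 101L, end = 300L)
  expect_equal(seven_s_abundance(d, region), 20 / mean(d))
  expect_equal(seven_s_abundance(3 * d, region), seven_s_abundance(d, region))
  expect_error(seven_s_abundance(rep(0, 10L), list(start = 1L, end = 2L)),
               "zero genome-wide")
})

test_that("depth tracks round trip through TSV", {
  g <- sim_genome(500L, seed = 6L)
  d <- sim_depth_track(g, list(start = 451L, end = 50L), multiplier = 3,
                       base_depth = 20, noise_sd = 2, seed = 7L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_depth_track(d, f)
  expect_equal(read_depth_track(f, 500L), d)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pos\tdepth", "1\t5"), f2)
  expect_error(read_depth_track(f2, 10L), "cover")
})
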