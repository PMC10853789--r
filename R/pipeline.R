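write_tsv <- function(df, path) {
  data.table::fwrite(data.table::as.data.table(df), path, sep = "\t")
  invisible(path)
}

default_params <- function() {
  list(bin_size = 200L, window = 51L, top_frac = 0.01, k = 20L,
       library_fraction = 0.8, peak_factor = 1.5, alpha = 0.05,
       enzymes = list(), seed = 1L)
}

#' Run the full rNMP analysis pipeline from a configuration
#'
#' Executes ingest (with circular-origin recovery, mismatch and
#' restriction-site filtering), strand-bias summaries, 200-nt bin EF / REZ
#' calling with common-REZ voting, hotspot detection and ranking,
#' composition / context-pattern matrices, strand-bias contribution, the
#' gene-level PPB and size-correlation stage, and (when the annotation and
#' depth tracks provide them) control-region profiling and 7S-DNA abundance.
#' All results are written as TSV/BED files plus a machine-readable run
#' manifest; outputs are identical for identical (inputs, config, seed).
#'
#' @param config Path to a YAML file or an equivalent named list with fields
#'   `genome` (FASTA path), `annotation` (BED/GTF path, optional),
#'   `libraries` (list of lists: `path`, `library_id`, `cell_category`,
#'   `genotype`, `fragmentation`), optional `depth_tracks` (named list of TSV
#'   paths), and optional `params` overriding the defaults (`bin_size`,
#'   `window`, `top_frac`, `k`, `library_fraction`, `peak_factor`, `alpha`,
#'   `enzymes`, `seed`).
#' @param output_dir Output directory (created if absent).
#' @param overwrite Overwrite existing outputs? Errors otherwise.
#' @return Invisibly, a list with the main result objects.
#' @export
run_pipeline <- function(config, output_dir, overwrite = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("missing input: ", config)
    config <- yaml::read_yaml(config)
  }
  params <- utils::modifyList(default_params(), config$params %||% list())
  for (f in c(config$genome, config$annotation,
              unlist(config$depth_tracks, use.names = FALSE),
              vapply(config$libraries, `[[`, "", "path"))) {
    if (!is.null(f) && !file.exists(f)) stop("missing input: ", f)
  }
  if (dir.exists(output_dir) &&
      length(list.files(output_dir, pattern = "\\.(tsv|bed|json|log)$")) > 0L &&
      !overwrite) {
    stop("output directory already contains results; use overwrite = TRUE")
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), ...))
  }

  note("stage ingest")
  genome <- read_genome_fasta(config$genome)
  L <- genome$length
  annotation <- if (!is.null(config$annotation)) {
    read_annotation(config$annotation, L)
  } else NULL
  filter_report <- list()
  libraries <- lapply(config$libraries, function(cfg) {
    lib <- read_rnmp_bed(cfg$path, cfg$library_id %||% basename(cfg$path),
                         cfg$cell_category %||% "unknown",
                         cfg$genotype %||% "other",
                         cfg$fragmentation %||% "unknown")
    lib <- recover_circular(lib, L)
    n0 <- n_rnmps(lib)
    fm <- filter_mismatches(lib, genome)
    fr <- filter_re_sites(fm$library, genome, params$enzymes)
    filter_report[[length(filter_report) + 1L]] <<- data.frame(
      library_id = lib$library_id, input = n0,
      removed_mismatch = fm$removed, removed_re_site = fr$removed,
      kept = n_rnmps(fr$library), stringsAsFactors = FALSE)
    fr$library
  })
  write_tsv(do.call(rbind, filter_report),
            file.path(output_dir, "filter_report.tsv"))
  categories <- vapply(libraries, `[[`, "", "cell_category")

  note("stage strand_bias")
  sp <- t(vapply(libraries, strand_percentages, numeric(2L)))
  strand_tab <- data.frame(
    library_id = vapply(libraries, `[[`, "", "library_id"),
    category = categories, light_pct = sp[, "light"], heavy_pct = sp[, "heavy"],
    stringsAsFactors = FALSE)
  strand_tab$mwu_p <- NA_real_
  for (ct in unique(categories)) {
    idx <- categories == ct
    if (sum(idx) >= 3L) {
      strand_tab$mwu_p[idx] <- mann_whitney_u(
        strand_tab$light_pct[idx], strand_tab$heavy_pct[idx],
        alternative = "two_sided")$p_value
    }
  }
  write_tsv(strand_tab, file.path(output_dir, "strand_bias.tsv"))

  note("stage zones")
  grid <- make_bins(L, params$bin_size)
  efm <- bin_ef_matrix(libraries, grid)
  write_tsv(cbind(grid[c("bin", "strand", "start", "end", "length")],
                  as.data.frame(efm)),
            file.path(output_dir, "bin_ef_matrix.tsv"))
  rez <- common_rez(efm, categories, params$library_fraction)
  rez_out <- cbind(grid[c("bin", "strand", "start", "end")], rez[-1L])
  write_tsv(rez_out, file.path(output_dir, "rez_summary.tsv"))
  cm <- rez_out[rez_out$common, , drop = FALSE]
  if (nrow(cm) > 0L) {
    utils::write.table(
      data.frame(genome$name, cm$start - 1L, cm$end, cm$bin,
                 round(cm$lib_fraction, 3), cm$strand),
      file.path(output_dir, "common_rez.bed"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }

  note("stage hotspots")
  hs <- common_hotspots(libraries, genome)
  ranked <- rank_hotspots(hs, params$k,
                          stats::setNames(categories,
                                          colnames(efm)))
  write_tsv(ranked, file.path(output_dir, "top_hotspots.tsv"))
  hf_pfm <- lapply(libraries, function(lib) {
    context_pfm(high_frequency_sites(lib, params$top_frac), genome)
  })
  pfm_tab <- do.call(rbind, lapply(seq_along(hf_pfm), function(i) {
    m <- hf_pfm[[i]]
    data.frame(library_id = libraries[[i]]$library_id,
               base = rownames(m), as.data.frame(m, check.names = FALSE),
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  write_tsv(pfm_tab, file.path(output_dir, "high_frequency_context_pfm.tsv"))

  note("stage patterns")
  for (scope in c("both", "light", "heavy")) {
    comp <- t(vapply(libraries, rnmp_composition, numeric(4L),
                     genome = genome, scope = scope))
    write_tsv(data.frame(library_id = strand_tab$library_id, comp,
                         check.names = FALSE),
              file.path(output_dir, sprintf("composition_%s.tsv", scope)))
    for (mode in c("NR", "RN", "NNR")) {
      mats <- lapply(libraries, pattern_frequencies, genome = genome,
                     mode = mode, scope = scope)
      long <- do.call(rbind, lapply(seq_along(mats), function(i) {
        m <- mats[[i]]
        data.frame(library_id = libraries[[i]]$library_id,
                   context = rownames(m), as.data.frame(unclass(m)),
                   stringsAsFactors = FALSE)
      }))
      write_tsv(long, file.path(output_dir,
                                sprintf("pattern_%s_%s.tsv", mode, scope)))
    }
  }
  contrib <- do.call(rbind, lapply(libraries, function(lib) {
    ct <- tryCatch(strand_bias_contribution(lib, genome),
                   error = function(e) NULL)
    if (is.null(ct)) return(NULL)
    cbind(library_id = lib$library_id, preferred = ct$preferred_strand,
          delta = ct$delta, ct$table)
  }))
  if (!is.null(contrib)) {
    write_tsv(contrib, file.path(output_dir, "strand_bias_contribution.tsv"))
  }

  gene_tabs <- NULL
  if (!is.null(annotation) && any(annotation$feature_type == "CDS")) {
    note("stage regions")
    gene_tabs <- do.call(rbind, lapply(libraries, function(lib) {
      cbind(library_id = lib$library_id,
            gene_ppb_table(lib, annotation, genome, "CDS"))
    }))
    write_tsv(gene_tabs, file.path(output_dir, "gene_ppb.tsv"))
    size_cor <- do.call(rbind, lapply(libraries, function(lib) {
      tab <- gene_ppb_table(lib, annotation, genome, "CDS")
      sc <- tryCatch(size_correlation(tab, "non_template"),
                     error = function(e) NULL)
      if (is.null(sc)) return(NULL)
      data.frame(library_id = lib$library_id, sc, stringsAsFactors = FALSE)
    }))
    if (!is.null(size_cor)) {
      write_tsv(size_cor, file.path(output_dir, "size_correlation.tsv"))
    }
  }
  cr <- annotation[annotation$feature_type == "control_region", , drop = FALSE]
  if (!is.null(annotation) && nrow(cr) == 1L) {
    profiles <- do.call(rbind, lapply(libraries, function(lib) {
      pr <- control_region_profile(lib, genome, cr[1L, ], params$window,
                                   params$peak_factor, bins = grid)
      if (nrow(pr$peaks) == 0L) return(NULL)
      cbind(library_id = lib$library_id, pr$peaks)
    }))
    if (!is.null(profiles)) {
      write_tsv(profiles, file.path(output_dir, "control_region_peaks.tsv"))
    }
    orih <- annotation[annotation$feature_type == "OriH", , drop = FALSE]
    reg_rows <- list()
    for (i in seq_along(libraries)) {
      for (rg in list(if (nrow(orih) == 1L) orih[1L, ], cr[1L, ])) {
        if (is.null(rg)) next
        pct <- tryCatch(region_strand_percentages(libraries[[i]], rg),
                        error = function(e) NULL)
        if (is.null(pct)) next
        reg_rows[[length(reg_rows) + 1L]] <- data.frame(
          library_id = libraries[[i]]$library_id, region = rg$name,
          light_pct = pct["light"], heavy_pct = pct["heavy"],
          stringsAsFactors = FALSE)
      }
    }
    if (length(reg_rows)) {
      write_tsv(do.call(rbind, reg_rows),
                file.path(output_dir, "region_strand_bias.tsv"))
    }
  }
  if (!is.null(config$depth_tracks) && !is.null(annotation)) {
    seven <- annotation[annotation$feature_type == "seven_S", , drop = FALSE]
    if (nrow(seven) == 1L) {
      ratios <- vapply(config$depth_tracks, function(p) {
        seven_s_abundance(read_depth_track(p, L), seven[1L, ])
      }, numeric(1L))
      write_tsv(data.frame(track = names(config$depth_tracks),
                           seven_s_ratio = unname(ratios)),
                file.path(output_dir, "seven_s_abundance.tsv"))
    }
  }

  manifest <- list(
    package = "mitornmp",
    version = as.character(utils::packageVersion("mitornmp")),
    genome = config$genome, genome_length = L,
    annotation = config$annotation,
    libraries = vapply(config$libraries, `[[`, "", "path"),
    params = params[setdiff(names(params), "enzymes")],
    n_enzymes = length(params$enzymes))
  writeLines(yaml::as.yaml(manifest), file.path(output_dir, "manifest.yaml"))
  writeLines(log_lines, file.path(output_dir, "run.log"))
  invisible(list(genome = genome, annotation = annotation,
                 libraries = libraries, strand_bias = strand_tab,
                 ef_matrix = efm, rez = rez_out, hotspots = ranked,
                 gene_ppb = gene_tabs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a self-contained synthetic demo dataset
#'
#' Generates a mitochondrial-scale circular genome, a CDS/control-region
#' annotation, a set of rNMP libraries with planted structure (strand bias,
#' composition bias, an enriched zone, hotspots, mismatch noise, CDS-size
#' coupling), a 7S-depth track and the truth tables, and writes them as
#' FASTA / BED / TSV under `out_dir` together with a ready-to-run pipeline
#' config. Everything is reproducible from the seed.
#'
#' @param out_dir Output directory.
#' @param n_libraries Number of libraries (default 6).
#' @param n_rnmps Records per library (default 50,000).
#' @param L Genome length (default 16,569 nt).
#' @param seed Integer seed.
#' @return The path of the written pipeline config (invisibly).
#' @export
write_demo_dataset <- function(out_dir, n_libraries = 6L, n_rnmps = 50000L,
                               L = 16569L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- sim_genome(L, seed = seed)
  annotation <- sim_annotation(genome, seed = seed)
  write_genome_fasta(genome, file.path(out_dir, "genome.fa"))
  write_annotation_bed(annotation, file.path(out_dir, "annotation.bed"),
                       chrom = genome$name)
  rez_spec <- list(list(start = 2001L, end = 2200L, strand = "+",
                        multiplier = 5),
                   # a second zone inside the control region so the demo
                   # exercises the peak-calling stage
                   list(start = L - 400L, end = L - 201L, strand = "+",
                        multiplier = 5))
  hotspot_spec <- list(list(pos = 5000L, strand = "+", min_count = 25L))
  lib_cfgs <- list()
  for (i in seq_len(n_libraries)) {
    sim <- sim_library(genome, annotation, n_rnmps = n_rnmps,
                       rez_spec = rez_spec, hotspot_spec = hotspot_spec,
                       mismatch_rate = 0.01, cds_size_effect = 1,
                       seed = seed * 1000L + i,
                       library_id = sprintf("demo%02d", i),
                       cell_category = if (i <= ceiling(n_libraries / 2))
                         "cellA" else "cellB")
    path <- file.path(out_dir, sprintf("demo%02d.bed", i))
    write_rnmp_bed(sim$library, path, chrom = genome$name)
    write_tsv(sim$truth$mismatches,
              file.path(out_dir, sprintf("demo%02d_truth_mismatches.tsv", i)))
    lib_cfgs[[i]] <- list(path = path, library_id = sim$library$library_id,
                          cell_category = sim$library$cell_category,
                          genotype = "RNH2A_WT", fragmentation = "fragmentase")
  }
  seven <- annotation[annotation$feature_type == "seven_S", ][1L, ]
  depth <- sim_depth_track(genome, seven, multiplier = 2, base_depth = 100,
                           noise_sd = 5, seed = seed)
  write_depth_track(depth, file.path(out_dir, "depth.tsv"))
  config <- list(genome = file.path(out_dir, "genome.fa"),
                 annotation = file.path(out_dir, "annotation.bed"),
                 libraries = lib_cfgs,
                 depth_tracks = list(demo = file.path(out_dir, "depth.tsv")),
                 params = list(seed = seed))
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}
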