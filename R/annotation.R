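#' @importFrom utils head tail
NULL

FEATURE_TYPES <- c("CDS", "tRNA", "rRNA", "control_region", "OriH", "OriL",
                   "CSB1", "CSB2", "CSB3", "D_loop", "seven_S", "HSP", "LSP",
                   "TAS", "bin", "custom")

#' Build an annotation set of (possibly wrapped) circular regions
#'
#' Regions are 1-based inclusive. `start > end` is legal and denotes a region
#' wrapping through the origin (e.g. the mitochondrial control region). The
#' region length is `end - start + 1`, or `L - start + 1 + end` when wrapped.
#'
#' @param name,start,end,strand,feature_type Parallel vectors describing the
#'   regions; `strand` in `+`/`-`/`both`, `feature_type` one of the documented
#'   mitochondrial feature types (see `mitornmp:::FEATURE_TYPES`).
#' @param genome_length Genome length the coordinates refer to.
#' @return A data frame of class `annotation_set` with attribute
#'   `genome_length`.
#' @export
annotation_set <- function(name, start, end, strand, feature_type,
                           genome_length) {
  L <- as.integer(genome_length)
  df <- data.frame(name = as.character(name), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   feature_type = as.character(feature_type),
                   stringsAsFactors = FALSE)
  if (any(df$start < 1L | df$start > L | df$end < 1L | df$end > L)) {
    stop("region coordinates outside [1, L]")
  }
  if (!all(df$strand %in% c("+", "-", "both"))) stop("invalid strand")
  if (!all(df$feature_type %in% FEATURE_TYPES)) {
    stop("unknown feature_type: ",
         paste(setdiff(df$feature_type, FEATURE_TYPES), collapse = ", "))
  }
  dup <- duplicated(df[c("feature_type", "name")])
  if (any(dup)) stop("duplicated region name within a feature_type: ",
                     paste(unique(df$name[dup]), collapse = ", "))
  df$length <- region_length(df$start, df$end, L)
  structure(df, genome_length = L,
            class = c("annotation_set", "data.frame"))
}

#' Length of a circular region
#'
#' @param start,end 1-based inclusive bounds; `start > end` wraps the origin.
#' @param L Genome length.
#' @return Integer vector of region lengths (always >= 1).
#' @export
region_length <- function(start, end, L) {
  ifelse(start <= end, end - start + 1L, L - start + 1L + end)
}

#' Positions covered by a circular region, in 5'->3' plus-strand order
#'
#' @inheritParams region_length
#' @return Integer vector of genome positions.
#' @export
region_positions <- function(start, end, L) {
  if (start <= end) seq.int(start, end) else c(seq.int(start, L), seq.int(1L, end))
}

#' Is a position inside a (possibly wrapped) region?
#'
#' @param pos Integer vector of positions.
#' @inheritParams region_length
#' @return Logical vector.
#' @export
in_region <- function(pos, start, end) {
  if (start <= end) pos >= start & pos <= end else pos >= start | pos <= end
}

infer_feature_type <- function(name) {
  vapply(name, function(nm) {
    pre <- sub(":.*$", "", nm)
    hit <- FEATURE_TYPES[toupper(FEATURE_TYPES) == toupper(pre)]
    if (length(hit) == 1L) hit else "custom"
  }, character(1L), USE.NAMES = FALSE)
}

strip_feature_prefix <- function(name, feature_type) {
  has <- grepl(":", name, fixed = TRUE) & feature_type != "custom"
  name[has] <- sub("^[^:]*:", "", name[has])
  name
}

read_annotation_bed <- function(path, L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1L))
  if (any(n < 6L)) {
    stop(sprintf("malformed BED line %d: expected 6 tab-separated fields",
                 which(n < 6L)[1L]))
  }
  start0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- is.na(start0) | is.na(end0) | start0 < 0L | end0 > L | start0 >= end0
  if (any(bad)) {
    stop(sprintf("malformed BED line %d: invalid coordinates for genome of %d nt",
                 which(bad)[1L], L))
  }
  strands <- vapply(fields, `[`, "", 6L)
  strands[strands == "."] <- "both"
  df <- data.frame(
    name = vapply(fields, `[`, "", 4L),
    start = start0 + 1L, end = end0,
    strand = strands,
    stringsAsFactors = FALSE
  )
  # wrap dialect: a region spanning the origin is written as two lines with a
  # shared name, one ending at L and one starting at 0; merge them on load
  merged <- df[0L, ]
  for (nm in unique(df$name)) {
    part <- df[df$name == nm, , drop = FALSE]
    if (nrow(part) == 2L && any(part$end == L) && any(part$start == 1L) &&
        length(unique(part$strand)) == 1L) {
      a <- part[part$end == L, ]
      b <- part[part$start == 1L, ]
      part <- a
      part$end <- b$end
    } else if (nrow(part) > 1L) {
      stop("duplicated BED region name without a valid wrap pair: ", nm)
    }
    merged <- rbind(merged, part)
  }
  ft <- infer_feature_type(merged$name)
  annotation_set(strip_feature_prefix(merged$name, ft), merged$start,
                 merged$end, merged$strand, ft, genome_length = L)
}

read_annotation_gtf <- function(path, L) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  biotype <- if ("gene_biotype" %in% names(md)) as.character(md$gene_biotype)
             else rep(NA_character_, length(gr))
  ft <- ifelse(type == "CDS", "CDS",
        ifelse(grepl("tRNA", type) | grepl("tRNA", biotype), "tRNA",
        ifelse(grepl("rRNA", type) | grepl("rRNA", biotype), "rRNA", "custom")))
  keep <- ft != "custom" | type %in% c("gene", "exon")
  gr <- gr[keep]; md <- S4Vectors::mcols(gr); ft <- ft[keep]
  nm <- if ("gene_name" %in% names(md) && !all(is.na(md$gene_name))) {
    as.character(md$gene_name)
  } else if ("gene_id" %in% names(md)) {
    as.character(md$gene_id)
  } else paste0("feature", seq_along(gr))
  nm[is.na(nm)] <- paste0("feature", which(is.na(nm)))
  st <- BiocGenerics::start(gr); en <- BiocGenerics::end(gr)
  if (any(st < 1L | en > L)) stop("GTF coordinates outside [1, L]")
  # unique names within a feature type (a gene may have several CDS lines)
  key <- paste(ft, nm, st, en)
  keep2 <- !duplicated(key)
  nm <- nm[keep2]; st <- st[keep2]; en <- en[keep2]; ft <- ft[keep2]
  gr <- gr[keep2]
  dup <- duplicated(paste(ft, nm))
  nm[dup] <- paste0(nm[dup], "_", seq_len(sum(dup)))
  annotation_set(nm, st, en, as.character(BiocGenerics::strand(gr)), ft,
                 genome_length = L)
}

#' Read gene/feature annotation (BED6 or GTF) for a circular genome
#'
#' BED input (0-based half-open) is converted to 1-based inclusive
#' coordinates; regions spanning the origin may be encoded as two BED lines
#' sharing a name (one ending at `L`, one starting at 0) and are merged into a
#' single wrapped region on load. The feature type is inferred from the BED
#' name (or its prefix before a `:`), matched case-insensitively against the
#' known mitochondrial feature types; anything else becomes `custom`. GTF
#' input (1-based inclusive) is passed through, with `CDS` lines kept as CDS
#' and tRNA/rRNA genes classified from the feature type or `gene_biotype`.
#'
#' @param path Path to the annotation file.
#' @param genome_length Length of the circular genome.
#' @param format "bed", "gtf", or "auto" (by file extension).
#' @return An `annotation_set`.
#' @export
read_annotation <- function(path, genome_length,
                            format = c("auto", "bed", "gtf")) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf"
              else "bed"
  }
  L <- as.integer(genome_length)
  switch(format,
         bed = read_annotation_bed(path, L),
         gtf = read_annotation_gtf(path, L))
}

#' Write an annotation set as BED6
#'
#' Wrapped regions are split back into the two-line dialect used by
#' [read_annotation()].
#'
#' @param annotation An `annotation_set`.
#' @param path Output path.
#' @param chrom Chromosome name for column 1.
#' @export
write_annotation_bed <- function(annotation, path, chrom = "chrM") {
  L <- attr(annotation, "genome_length")
  rows <- list()
  for (i in seq_len(nrow(annotation))) {
    r <- annotation[i, ]
    strand <- if (r$strand == "both") "." else r$strand
    # name encodes the feature type so BED round trips preserve it
    nm <- if (r$feature_type == "custom") r$name
          else paste0(r$feature_type, ":", r$name)
    if (r$start <= r$end) {
      rows[[length(rows) + 1L]] <-
        c(chrom, r$start - 1L, r$end, nm, ".", strand)
    } else {
      rows[[length(rows) + 1L]] <- c(chrom, r$start - 1L, L, nm, ".", strand)
      rows[[length(rows) + 1L]] <- c(chrom, 0L, r$end, nm, ".", strand)
    }
  }
  mat <- do.call(rbind, rows)
  utils::write.table(mat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
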