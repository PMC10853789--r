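#' rNMP library object
#'
#' One sequencing library's stranded single-nucleotide rNMP records plus
#' metadata. Each record is one captured rNMP; duplicate records at a
#' position are distinct events and all kept (per-position abundance matters
#' for hotspot and top-1% analyses). rU is stored as "T" so that every record
#' can be compared against the DNA reference alphabet; report writers render
#' it as rU.
#'
#' @param records Data frame with columns `pos` (1-based), `strand`
#'   ("+"/"-") and `base` (A/C/G/T; "U" accepted and stored as "T").
#' @param library_id Library identifier.
#' @param cell_category Cell category label used for REZ voting.
#' @param genotype RNase H2 genotype label ("RNH2A_WT", "RNH2A_KO", "other").
#' @param fragmentation Fragmentation method label.
#' @return An object of class `rnmp_library`.
#' @export
rnmp_library <- function(records, library_id, cell_category = "unknown",
                         genotype = "other", fragmentation = "unknown") {
  stopifnot(is.data.frame(records),
            all(c("pos", "strand", "base") %in% names(records)))
  if (!nzchar(library_id) || !nzchar(cell_category)) {
    stop("library metadata fields must be non-empty")
  }
  records <- data.frame(pos = as.integer(records$pos),
                        strand = as.character(records$strand),
                        base = toupper(as.character(records$base)),
                        stringsAsFactors = FALSE)
  records$base[records$base == "U"] <- "T"
  if (!all(records$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(records$base %in% c("A", "C", "G", "T"))) {
    stop("base must be one of A/C/G/T/U")
  }
  structure(list(library_id = library_id, cell_category = cell_category,
                 genotype = genotype, fragmentation = fragmentation,
                 records = records),
            class = "rnmp_library")
}

#' @export
print.rnmp_library <- function(x, ...) {
  cat(sprintf("<rnmp_library> %s (%s, %s, %s): %d rNMPs (%d light / %d heavy)\n",
              x$library_id, x$cell_category, x$genotype, x$fragmentation,
              nrow(x$records), sum(x$records$strand == "+"),
              sum(x$records$strand == "-")))
  invisible(x)
}

#' Total rNMP count of a library
#' @param library An `rnmp_library`.
#' @return Integer count.
#' @export
n_rnmps <- function(library) nrow(library$records)

#' Read an rNMP coordinate BED6 file
#'
#' One line per captured rNMP: single-nucleotide interval (`chromEnd -
#' chromStart == 1`), observed base in the name column (U accepted as rU and
#' stored as T), strand in column 6. Coordinates convert from BED 0-based
#' half-open to 1-based.
#'
#' @param path Path to BED6 file.
#' @inheritParams rnmp_library
#' @return An `rnmp_library`.
#' @export
read_rnmp_bed <- function(path, library_id = basename(path),
                          cell_category = "unknown", genotype = "other",
                          fragmentation = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 4, 6)))
  if (ncol(dt) < 6L) stop("expected BED6 (6 tab-separated columns)")
  width <- dt[[3L]] - dt[[2L]]
  if (any(width != 1L)) {
    stop(sprintf("line %d: not single-nucleotide (width %d)",
                 which(width != 1L)[1L], width[which(width != 1L)[1L]]))
  }
  rnmp_library(data.frame(pos = dt[[3L]], strand = dt[[6L]], base = dt[[4L]],
                          stringsAsFactors = FALSE),
               library_id = library_id, cell_category = cell_category,
               genotype = genotype, fragmentation = fragmentation)
}

#' Write an rNMP library as BED6
#'
#' @param library An `rnmp_library`.
#' @param path Output path.
#' @param chrom Chromosome name for column 1.
#' @export
write_rnmp_bed <- function(library, path, chrom = "chrM") {
  r <- library$records
  dt <- data.table::data.table(chrom = chrom, start = r$pos - 1L, end = r$pos,
                               name = r$base, score = ".", strand = r$strand)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Recover rNMP coordinates onto the circular genome
#'
#' Records aligned against a linearized (or rotated) representation of a
#' circular genome can carry positions outside `[1, L]`; every position is
#' mapped through [wrap_position()]. Idempotent; record multiplicity is
#' preserved.
#'
#' @param library An `rnmp_library`.
#' @param L Genome length.
#' @return The library with all positions in `[1, L]`.
#' @export
recover_circular <- function(library, L) {
  library$records$pos <- wrap_position(L, library$records$pos)
  library
}

reference_base_on_strand <- function(genome, pos, strand) {
  b <- genome$chars[pos]
  minus <- strand == "-"
  b[minus] <- unname(COMPLEMENT[b[minus]])
  b
}

#' Remove rNMP records that mismatch the reference
#'
#' A record is kept iff its observed base equals the reference base read on
#' the record's strand (minus-strand records are compared against the
#' complement of the plus-strand base). Mismatching records are most likely
#' sequencing errors.
#'
#' @param library An `rnmp_library` with recovered coordinates.
#' @param genome A `circular_genome`.
#' @return List with `library` (filtered) and `removed` (count dropped).
#' @export
filter_mismatches <- function(library, genome) {
  r <- library$records
  keep <- r$base == reference_base_on_strand(genome, r$pos, r$strand)
  library$records <- r[keep, , drop = FALSE]
  rownames(library$records) <- NULL
  list(library = library, removed = sum(!keep))
}

# slots (pos, strand) adjacent to every cut of one enzyme, both orientations
re_cut_slots <- function(genome, motif, top_cut, bottom_cut) {
  L <- genome$length
  m <- nchar(motif)
  if (m > L) stop("motif longer than the genome")
  scan <- function(pat) {
    doubled <- paste0(genome$seq, substr(genome$seq, 1L, m - 1L))
    hits <- Biostrings::matchPattern(pat, Biostrings::DNAString(doubled))
    starts <- BiocGenerics::start(hits)
    starts[starts <= L]
  }
  slots <- list()
  for (q in scan(motif)) {           # site read on the plus strand
    slots[[length(slots) + 1L]] <-
      data.frame(pos = c(wrap_position(L, q + top_cut - 1L),
                         wrap_position(L, q + m - bottom_cut)),
                 strand = c("+", "-"), stringsAsFactors = FALSE)
  }
  rc <- revcomp(motif)
  for (q in scan(rc)) {              # site read on the minus strand
    slots[[length(slots) + 1L]] <-
      data.frame(pos = c(wrap_position(L, q + m - top_cut),
                         wrap_position(L, q + bottom_cut - 1L)),
                 strand = c("-", "+"), stringsAsFactors = FALSE)
  }
  if (length(slots) == 0L) {
    return(data.frame(pos = integer(0), strand = character(0)))
  }
  unique(do.call(rbind, slots))
}

#' Remove rNMP calls at restriction-enzyme fragment ends
#'
#' Library fragmentation with restriction enzymes produces fragment-end
#' artifacts that masquerade as rNMP calls. Both strands of the circular
#' genome are scanned for each recognition motif; for every cut the single
#' terminal nucleotide 5' of the cut on each strand is a removal slot, and
#' every record whose (position, strand) equals a removal slot is dropped.
#' Cut offsets count bases of the motif 5'->3' on each strand (a blunt cutter
#' with motif length 6 cutting in the middle has `top_cut = bottom_cut = 3`).
#'
#' @param library An `rnmp_library`.
#' @param genome A `circular_genome`.
#' @param enzymes List of lists with fields `motif`, `top_cut`, `bottom_cut`.
#' @return List with `library` (filtered) and `removed` (count dropped).
#' @export
filter_re_sites <- function(library, genome, enzymes) {
  if (length(enzymes) == 0L) return(list(library = library, removed = 0L))
  slots <- unique(do.call(rbind, lapply(enzymes, function(e) {
    re_cut_slots(genome, toupper(e$motif), e$top_cut, e$bottom_cut)
  })))
  r <- library$records
  key <- paste(r$pos, r$strand)
  drop <- key %in% paste(slots$pos, slots$strand)
  library$records <- r[!drop, , drop = FALSE]
  rownames(library$records) <- NULL
  list(library = library, removed = sum(drop))
}
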