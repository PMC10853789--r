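#' Circular genome object
#'
#' Holds a single circular DNA sequence with 1-based coordinates. The stored
#' sequence is the plus strand read 5'->3'; for mitochondrial genomes this is
#' conventionally the light strand (GRCh38 chrM annotates 12 of the 13 coding
#' sequences on "+"). Only the four unambiguous bases are accepted: ambiguous
#' characters would silently corrupt the background k-mer counts used for
#' context normalization, so they are rejected outright.
#'
#' @param sequence Character scalar over A/C/G/T (case-insensitive).
#' @param name Sequence name (e.g. "chrM").
#' @return An object of class `circular_genome` with fields `name`, `length`,
#'   `seq` (uppercase string) and `chars` (per-position character vector).
#' @export
circular_genome <- function(sequence, name = "chrM") {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  seq <- toupper(sequence)
  if (nchar(seq) < 1L) stop("genome must contain at least one base")
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L) {
    stop(sprintf("non-ACGT character '%s' at position %d",
                 substr(seq, bad, bad), as.integer(bad)))
  }
  structure(
    list(name = name, length = nchar(seq), seq = seq,
         chars = strsplit(seq, "", fixed = TRUE)[[1L]]),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d nt (circular)\n", x$name, x$length))
  invisible(x)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# reverse complement of a character vector of sequences
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                                 collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}

#' Map an arbitrary integer position onto the circular genome
#'
#' Positions are 1-based; position `L + 1` wraps to 1 and position 0 wraps to
#' `L`. Total on all integers, periodic with period `L`. Used to recover rNMP
#' coordinates that fall off either end of a linearized circular reference.
#'
#' @param L Genome length (nt).
#' @param pos Integer vector of positions (may be outside `[1, L]`).
#' @return Integer vector in `[1, L]`.
#' @export
wrap_position <- function(L, pos) {
  stopifnot(L >= 1L)
  as.integer((as.numeric(pos) - 1) %% L + 1)
}

#' Extract the sequence window around a position, strand-aware
#'
#' Returns the `2*flank + 1`-mer centred on `center`, read 5'->3' on the
#' requested strand: plus-strand windows are the reference subsequence with
#' circular wrap, minus-strand windows are its reverse complement so the base
#' at the middle is the (complemented) base at `center` on the minus strand.
#' Vectorized over `center` and `strand`.
#'
#' @param genome A `circular_genome`.
#' @param center Position(s) in `[1, L]`.
#' @param strand "+" or "-" (recycled).
#' @param flank Number of bases on each side; must satisfy `flank < L`.
#' @return Character vector of windows.
#' @export
extract_window <- function(genome, center, strand = "+", flank = 3L) {
  stopifnot(inherits(genome, "circular_genome"), flank >= 0L)
  L <- genome$length
  if (flank >= L) stop("flank must be smaller than the genome length")
  center <- as.integer(center)
  if (any(center < 1L | center > L)) stop("center outside [1, L]")
  strand <- rep_len(strand, length(center))
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  idx <- outer(center, seq.int(-flank, flank), "+")
  m <- matrix(genome$chars[wrap_position(L, idx)], nrow = length(center))
  win <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  minus <- strand == "-"
  if (any(minus)) win[minus] <- revcomp(win[minus])
  win
}

all_kmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  if (k == 1L) return(bases)
  grid <- do.call(expand.grid,
                  c(rep(list(bases), k), list(stringsAsFactors = FALSE)))
  # vary the last base fastest so the order is alphabetical
  sort(do.call(paste0, grid))
}

count_kmers_circular <- function(seq, k) {
  L <- nchar(seq)
  doubled <- paste0(seq, substr(seq, 1L, k - 1L))
  km <- substring(doubled, seq_len(L), seq_len(L) + k - 1L)
  out <- integer(4L^k)
  names(out) <- all_kmers(k)
  tab <- table(km)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Background k-mer counts of the circular genome
#'
#' Counts every circular occurrence of each k-mer on the requested strand(s);
#' origin-spanning k-mers are included, so counts always sum to `L` per
#' strand. Minus-strand counting is performed on the (circular) reverse
#' complement. These counts are the denominator for composition and
#' context-frequency normalization.
#'
#' @param genome A `circular_genome`.
#' @param strand "+", "-" or "both".
#' @param k k-mer size (1, 2 or 3).
#' @return Named integer vector over all `4^k` k-mers (alphabetical order).
#' @export
count_background <- function(genome, strand = c("both", "+", "-"), k = 1L) {
  stopifnot(inherits(genome, "circular_genome"))
  strand <- match.arg(strand)
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= 3L, k <= genome$length)
  plus <- count_kmers_circular(genome$seq, k)
  if (strand == "+") return(plus)
  minus <- count_kmers_circular(revcomp(genome$seq), k)
  if (strand == "-") return(minus)
  plus + minus
}

#' Read a single-record FASTA file as a circular genome
#'
#' @param path Path to a FASTA file with exactly one record.
#' @param name Optional override for the sequence name.
#' @return A `circular_genome`.
#' @export
read_genome_fasta <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) {
    stop(sprintf("expected exactly one sequence, found %d", length(set)))
  }
  nm <- if (is.null(name)) sub("\\s.*$", "", names(set)[1L]) else name
  circular_genome(as.character(set[[1L]]), name = nm)
}

#' Write a circular genome to FASTA
#'
#' @param genome A `circular_genome`.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "circular_genome"))
  set <- Biostrings::DNAStringSet(genome$seq)
  names(set) <- genome$name
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
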