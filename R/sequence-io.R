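#' @useDynLib motifmix, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Base alphabet used throughout: integer codes 1..5 for A, C, G, T, N.
BASE_LETTERS <- c("A", "C", "G", "T", "N")
# complement of each code (N stays N)
BASE_COMP <- c(4L, 3L, 2L, 1L, 5L)

#' Encode a DNA string as integer base codes
#'
#' Letters are case-folded to upper case; any IUPAC code other than
#' A/C/G/T becomes N. Codes are 1=A, 2=C, 3=G, 4=T, 5=N.
#'
#' @param x a single character string, or a character vector of single
#'   letters.
#' @return integer vector of base codes.
#' @export
encode_bases <- function(x) {
  if (length(x) == 1L && nchar(x[1L]) > 1L) x <- strsplit(x, "", fixed = TRUE)[[1L]]
  up <- toupper(x)
  code <- match(up, BASE_LETTERS)
  code[is.na(code)] <- 5L
  code
}

#' Decode integer base codes back to letters
#'
#' @param code integer vector of codes in 1..5.
#' @param collapse if `TRUE` (default) return a single string.
#' @return character string or vector of letters.
#' @export
decode_bases <- function(code, collapse = TRUE) {
  letters <- BASE_LETTERS[code]
  if (collapse) paste(letters, collapse = "") else letters
}

new_encoded_sequence <- function(id, bases, masked) {
  stopifnot(length(bases) >= 1L, length(masked) == length(bases),
            all(bases %in% 1:5))
  structure(
    list(id = id, bases = as.integer(bases), length = length(bases),
         masked = as.logical(masked), masked_count = sum(masked)),
    class = "encoded_sequence"
  )
}

#' @export
print.encoded_sequence <- function(x, ...) {
  cat(sprintf("<%s> %d bp, %d masked\n", x$id, x$length, x$masked_count))
  invisible(x)
}

#' Construct a sequence set
#'
#' An ordered collection of encoded sequences with unique identifiers;
#' the container every other function in the package consumes.
#'
#' @param sequences list of objects created by the FASTA reader (or
#'   internally); each holds `id`, integer `bases`, `length`,
#'   `masked` flags and `masked_count`.
#' @return object of class `sequence_set` with elements `sequences` and `n`.
#' @export
sequence_set <- function(sequences) {
  ids <- vapply(sequences, function(s) s$id, character(1))
  if (anyDuplicated(ids))
    stop("sequence ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(sequences = sequences, n = length(sequences)),
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  lens <- seq_lengths(x)
  cat(sprintf("sequence_set: %d sequences, lengths %d-%d bp\n",
              x$n, min(lens), max(lens)))
  invisible(x)
}

#' @export
length.sequence_set <- function(x) x$n

seq_lengths <- function(set) vapply(set$sequences, function(s) s$length, integer(1))
seq_ids <- function(set) vapply(set$sequences, function(s) s$id, character(1))

#' Read a FASTA file of ChIP-bound regions
#'
#' Letters are case-folded to upper case. Lowercase letters in the source
#' are treated as repeat-masked (the soft-masking convention used by
#' genome browsers) and counted in `masked_count`; they are used as
#' ordinary bases afterwards. Any IUPAC ambiguity code other than
#' A/C/G/T is mapped to N and counted as masked, as are literal Ns.
#'
#' @param path path to a FASTA file (multi-record, wrapped or unwrapped).
#' @return a [sequence_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("no sequences in ", path)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA: sequence data before any header at line ", first)
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = FALSE,
                             forceDNAtolower = FALSE, set.attributes = FALSE)
  if (length(recs) == 0L) stop("no sequences in ", path)
  sequences <- vector("list", length(recs))
  nm <- names(recs)
  for (i in seq_along(recs)) {
    raw <- recs[[i]]
    if (length(raw) == 0L) stop("empty record '", nm[i], "' in ", path)
    lower <- raw != toupper(raw)
    code <- encode_bases(raw)
    masked <- lower | code == 5L
    sequences[[i]] <- new_encoded_sequence(nm[i], code, masked)
  }
  sequence_set(sequences)
}

#' Write a sequence set to FASTA
#'
#' Masked positions are written in lower case (N positions as `N`), so a
#' write/read round trip reproduces the set exactly, including masking.
#'
#' @param set a [sequence_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(set, path) {
  seqs <- lapply(set$sequences, function(s) {
    letters <- BASE_LETTERS[s$bases]
    soft <- s$masked & s$bases != 5L
    letters[soft] <- tolower(letters[soft])
    letters
  })
  seqinr::write.fasta(seqs, names = seq_ids(set), file.out = path,
                      nbchar = 70)
  invisible(path)
}

#' Drop heavily repeat-masked or short sequences
#'
#' Keeps sequences with at most `max_masked` masked bases (lowercase or N
#' in the source) and length at least `min_length`, preserving input
#' order. The defaults drop 200 bp ChIP windows in which more than 150 bp
#' are repeat-masked, and sequences too short to host a site of the
#' widest motif considered by the default fit.
#'
#' @param set a [sequence_set()].
#' @param max_masked maximum number of masked bases tolerated (bp).
#' @param min_length minimum sequence length retained (bp); choose at
#'   least the maximum motif width so every sequence admits a site of
#'   every mode.
#' @return the filtered [sequence_set()].
#' @export
filter_repeats <- function(set, max_masked = 150L, min_length = 40L) {
  stopifnot(max_masked >= 0L, min_length >= 1L)
  keep <- vapply(set$sequences,
                 function(s) s$masked_count <= max_masked && s$length >= min_length,
                 logical(1))
  removed <- sum(!keep)
  if (removed > 0L)
    message("filter_repeats: removed ", removed, " of ", set$n, " sequences")
  if (!any(keep)) stop("all sequences filtered out")
  sequence_set(set$sequences[keep])
}
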