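#' Sequence sets
#'
#' A \code{SequenceSet} is a light container for named sequences with a
#' declared alphabet. It is the carrier for probe sequences and EST/transcript
#' collections throughout the package.
#'
#' @param id character vector of unique record identifiers.
#' @param description character vector of free-text descriptions (may be "").
#' @param sequence character vector of sequences.
#' @param alphabet "nucleotide" or "protein"; every residue must belong to the
#'   IUPAC alphabet (ambiguity codes and gaps allowed).
#'
#' @return An object of class \code{SequenceSet}: a data frame with columns
#'   \code{id}, \code{description}, \code{sequence} and an \code{alphabet}
#'   attribute.
#' @export
SequenceSet <- function(id, description = "", sequence, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  description <- rep_len(as.character(description), length(id))
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(sequence))) stop("empty sequence(s) for id(s): ",
                                   paste(id[!nzchar(sequence)], collapse = ", "))
  ok <- grepl(alphabet_regex(alphabet), sequence)
  if (any(!ok)) {
    stop("sequence(s) contain residues outside the ", alphabet, " alphabet: ",
         paste(id[!ok], collapse = ", "))
  }
  out <- data.frame(id = id, description = description, sequence = sequence,
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  class(out) <- c("SequenceSet", "data.frame")
  out
}

alphabet_regex <- function(alphabet) {
  # IUPAC codes; '*' allowed for protein stops, '-' for gaps
  if (alphabet == "nucleotide") "^[ACGTUNRYSWKMBDHV-]+$" else "^[ACDEFGHIKLMNPQRSTVWYBXZJUO*-]+$"
}

#' Read a FASTA file into a SequenceSet
#'
#' Parsing is delegated to \code{Biostrings::readBStringSet}; the result is
#' validated against the declared alphabet and duplicate ids are an error.
#' Record order is preserved and sequence whitespace stripped.
#'
#' @param path path to a FASTA file.
#' @param alphabet "nucleotide" or "protein".
#' @return A \code{\link{SequenceSet}}.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("no FASTA records in: ", path)
  hdr <- names(ss)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  SequenceSet(id, desc, as.character(ss), alphabet)
}

#' Write a SequenceSet to FASTA
#'
#' @param x a \code{\link{SequenceSet}}.
#' @param path output path.
#' @param width line width for wrapping.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "SequenceSet"))
  hdr <- ifelse(nzchar(x$description), paste(x$id, x$description), x$id)
  ss <- Biostrings::BStringSet(x$sequence)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' @export
print.SequenceSet <- function(x, ...) {
  cat("SequenceSet of", nrow(x), attr(x, "alphabet"), "sequences\n")
  invisible(x)
}
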