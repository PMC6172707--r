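#' Read a FASTA file
#'
#' Thin wrapper around \code{Biostrings::readBStringSet} that enforces the
#' package's FASTA contract: unique record ids, non-empty sequences, and
#' uppercase residues (lowercase input is normalized with a warning). Record
#' names keep the full header line (id + description); CRLF and LF files are
#' parsed identically.
#'
#' @param path FASTA file path.
#' @param alphabet `"dna"`, `"aa"`, or `"auto"` (guess from residues).
#' @return A `DNAStringSet` or `AAStringSet` named by full header.
#' @export
read_fasta <- function(path, alphabet = c("auto", "dna", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop_input("FASTA file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop_input("duplicate FASTA ids: ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(x) == 0L))
    stop_input("empty sequence for id: ", ids[Biostrings::width(x) == 0L][1])
  chr <- as.character(x)
  up <- toupper(chr)
  if (!identical(chr, up)) {
    warning("lowercase residues normalized to uppercase")
    chr <- up
  }
  if (alphabet == "auto") {
    alphabet <- if (all(grepl("^[ACGTNU]*$", chr))) "dna" else "aa"
  }
  out <- if (alphabet == "dna") Biostrings::DNAStringSet(chr)
         else Biostrings::AAStringSet(chr)
  names(out) <- names(x)
  out
}

#' Write sequences to FASTA
#'
#' @param x A named `XStringSet` (or named character vector) of sequences.
#' @param path Output file path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  if (is.null(names(x)) || any(names(x) == ""))
    stop_input("all records must be named")
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop_input("duplicate FASTA ids: ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(x) == 0L))
    stop_input("refusing to write empty sequence: ",
               ids[Biostrings::width(x) == 0L][1])
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}
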