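#' In-silico proteolytic digestion
#'
#' Digest an amino-acid sequence with LysC or trypsin. LysC cleaves
#' C-terminal to every lysine, \emph{including} lysine-proline (K|P) bonds;
#' because K|P bonds are incompletely cleaved in practice, the digest also
#' emits, for each K|P site, the peptide form that retains that bond, up to
#' \code{max_miscleavage} retained K|P bonds per peptide. Trypsin mode uses
#' the standard rule (cleave after K or R, but not before P) with up to
#' \code{max_miscleavage} general missed cleavages, and is provided for
#' cross-method comparison of junction-peptide yields.
#'
#' @param sequence Single amino-acid string over the 20-letter alphabet
#'   (`X` and `*` tolerated; digestion never cuts at them).
#' @param enzyme `"lysc"` (default) or `"trypsin"`.
#' @param max_miscleavage Maximum retained K|P bonds (LysC) or missed
#'   cleavages (trypsin) per emitted peptide.
#' @return A data.frame with columns `peptide`, `start`, `end` (1-based
#'   residue coordinates in `sequence`), `n_miscleavage` and `miscleaved`.
#' @examples
#' digest_peptides("MAKPLSK", "lysc", 0)$peptide   # "MAK" "PLSK"
#' digest_peptides("MAKPLSK", "lysc", 1)$peptide   # adds "MAKPLSK"
#' @export
digest_peptides <- function(sequence, enzyme = c("lysc", "trypsin"),
                            max_miscleavage = 1L) {
  enzyme <- match.arg(enzyme)
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop_input("sequence must be a single string")
  assert_scalar_number(max_miscleavage, "max_miscleavage", lower = 0)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  ok <- aa %in% c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")
  if (!all(ok))
    stop_input("illegal residue '", aa[which(!ok)[1]], "' at position ",
               which(!ok)[1])
  n <- length(aa)
  if (n == 0L)
    return(data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), n_miscleavage = integer(0),
                      miscleaved = logical(0)))

  # cut sites: index i means a cut between residue i and i+1
  if (enzyme == "lysc") {
    cuts <- which(aa[-n] == "K")
  } else {
    cuts <- which(aa[-n] %in% c("K", "R") & aa[-1][seq_len(n - 1L)] != "P")
  }
  bounds <- c(0L, cuts, n)
  seg_start <- bounds[-length(bounds)] + 1L
  seg_end <- bounds[-1]
  m <- length(seg_start)

  # which inter-segment boundaries may be retained as a miscleavage
  if (enzyme == "lysc") {
    retainable <- vapply(seq_len(m - 1L), function(i)
      aa[seg_end[i]] == "K" && aa[seg_start[i + 1L]] == "P", logical(1))
  } else {
    retainable <- rep(TRUE, max(m - 1L, 0L))
  }

  out <- vector("list", m)
  for (i in seq_len(m)) {
    js <- i
    j <- i
    while (j < m && (j - i) < max_miscleavage && retainable[j]) {
      j <- j + 1L
      js <- c(js, j)
    }
    out[[i]] <- data.frame(
      start = seg_start[i], end = seg_end[js],
      n_miscleavage = seq_along(js) - 1L)
  }
  out <- do.call(rbind, out)
  out$peptide <- substring(sequence, out$start, out$end)
  out$miscleaved <- out$n_miscleavage > 0L
  rownames(out) <- NULL
  out[, c("peptide", "start", "end", "n_miscleavage", "miscleaved")]
}
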