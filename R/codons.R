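# Stop-codon screening for COI amplicons.
#
# Nuclear mitochondrial pseudogenes (NUMTs) frequently carry frameshifts and
# premature stop codons; a genuine COI fragment translates without stops in
# at least one reading frame. The invertebrate mitochondrial code (NCBI
# translation table 5) has only two stop codons, TAA and TAG.

.stop_codons <- list(
  invertebrate_mito = c("TAA", "TAG"),       # table 5
  vertebrate_mito   = c("TAA", "TAG", "AGA", "AGG"),  # table 2
  standard          = c("TAA", "TAG", "TGA") # table 1
)

frame_codons <- function(seq, offset) {
  n <- nchar(seq)
  starts <- seq.int(1L + offset, n - 2L, by = 3L)
  if (length(starts) == 0L) return(character())
  substring(seq, starts, starts + 2L)
}

# TRUE if the frame starting at `offset` (0, 1, 2) contains no stop codon.
# Codons containing N are treated as non-stop (cannot be called).
frame_stop_free <- function(seq, offset, stops) {
  cod <- frame_codons(seq, offset)
  !any(cod %in% stops)
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(seq, NULL), function(s) paste(rev(s), collapse = ""), ""))
}

#' Screen OTUs for in-frame stop codons
#'
#' An OTU is kept if at least one of its three forward reading frames (and,
#' optionally, the three reverse-complement frames) translates without a stop
#' codon under the chosen genetic code. OTUs with stops in every examined
#' frame are presumed pseudogenes (NUMTs) and removed.
#'
#' @param annotations an [otu_annotations()] data.frame (or any data.frame
#'   with `otu_id` and `sequence` columns).
#' @param code genetic code: `"invertebrate_mito"` (NCBI table 5, default),
#'   `"vertebrate_mito"` or `"standard"`.
#' @param check_reverse also accept a stop-free reverse-complement frame?
#'   Off by default: amplicon orientation is fixed by the primers.
#' @return list with `kept` and `removed` character vectors of OTU ids.
#' @export
screen_stop_codons <- function(annotations, code = "invertebrate_mito",
                               check_reverse = FALSE) {
  stops <- .stop_codons[[match.arg(code, names(.stop_codons))]]
  seqs <- toupper(annotations$sequence)
  if (any(!nzchar(seqs))) stop("empty sequences in annotations")
  odd <- grepl("[^ACGTN]", seqs)
  if (any(odd)) {
    warning("non-nucleotide characters (treated as N): ",
            paste(annotations$otu_id[odd], collapse = ", "))
    seqs[odd] <- gsub("[^ACGTN]", "N", seqs[odd])
  }
  ok <- vapply(seqs, function(s) {
    keep <- any(vapply(0:2, function(o) frame_stop_free(s, o, stops), logical(1)))
    if (!keep && check_reverse) {
      rc <- revcomp(s)
      keep <- any(vapply(0:2, function(o) frame_stop_free(rc, o, stops), logical(1)))
    }
    keep
  }, logical(1), USE.NAMES = FALSE)
  list(kept = annotations$otu_id[ok], removed = annotations$otu_id[!ok])
}
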