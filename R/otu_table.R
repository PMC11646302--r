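#' OTU read-count table with replicate pairing and negative-control flags
#'
#' The central container flowing through the curation stages. Rows are OTUs,
#' columns are sequencing libraries. Each library is either one member of a
#' technical-replicate pair (two libraries per biological sample) or a
#' negative control.
#'
#' @param counts non-negative integer matrix, OTUs in rows, libraries in
#'   columns; both dimensions must be named.
#' @param replicate_pairs data.frame with columns `sample_id`, `lib_a`,
#'   `lib_b` mapping each biological sample to its two replicate libraries.
#'   May have zero rows (e.g. after replicate merging).
#' @param negative_ids character vector of library ids that are negative
#'   controls.
#' @return an object of class `otu_table`.
#' @export
otu_table <- function(counts, replicate_pairs = NULL, negative_ids = character()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have OTU row names and library column names")
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and free of NA")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  if (is.null(replicate_pairs))
    replicate_pairs <- data.frame(sample_id = character(), lib_a = character(),
                                  lib_b = character(), stringsAsFactors = FALSE)
  need <- c("sample_id", "lib_a", "lib_b")
  if (!all(need %in% names(replicate_pairs)))
    stop("replicate_pairs needs columns sample_id, lib_a, lib_b")
  replicate_pairs <- replicate_pairs[, need]
  negative_ids <- as.character(negative_ids)

  paired <- c(replicate_pairs$lib_a, replicate_pairs$lib_b)
  if (any(replicate_pairs$lib_a == replicate_pairs$lib_b))
    stop("replicate pair members must be distinct libraries")
  all_assigned <- c(paired, negative_ids)
  libs <- colnames(counts)
  if (anyDuplicated(all_assigned))
    stop("a library may appear in at most one replicate pair or negative flag: ",
         paste(unique(all_assigned[duplicated(all_assigned)]), collapse = ", "))
  missing <- setdiff(all_assigned, libs)
  if (length(missing))
    stop("replicate/negative libraries absent from counts: ",
         paste(missing, collapse = ", "))
  unassigned <- setdiff(libs, all_assigned)
  if (length(unassigned) && nrow(replicate_pairs) > 0)
    stop("unpaired, non-negative libraries: ", paste(unassigned, collapse = ", "))

  structure(list(counts = counts,
                 replicate_pairs = replicate_pairs,
                 negative_ids = negative_ids),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d libraries (%d replicate pairs, %d negatives), %s reads\n",
              nrow(x$counts), ncol(x$counts), nrow(x$replicate_pairs),
              length(x$negative_ids), format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Total read count of an OTU table
#' @param x an `otu_table`
#' @return numeric scalar
#' @export
total_reads <- function(x) sum(as.numeric(x$counts))

otu_ids <- function(x) rownames(x$counts)
library_ids <- function(x) colnames(x$counts)
sample_library_ids <- function(x) setdiff(colnames(x$counts), x$negative_ids)
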