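#' Merge technical replicates by consensus sum
#'
#' Each biological sample was sequenced as two technical-replicate libraries.
#' Replicates are merged by summing the reads of an OTU, provided the OTU has
#' reads in *both* replicates; an OTU absent from one replicate is zeroed, so
#' a read must be seen twice to survive. Negative controls pass through
#' unmerged unless they themselves form a replicate pair, in which case the
#' same both-present rule applies.
#'
#' @param x an [otu_table()] in which every non-negative library belongs to a
#'   replicate pair.
#' @return an `otu_table` with one library per sample (named by `sample_id`)
#'   plus the untouched negative libraries.
#' @export
merge_replicates <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  rp <- x$replicate_pairs
  unassigned <- setdiff(colnames(x$counts), c(rp$lib_a, rp$lib_b, x$negative_ids))
  if (length(unassigned))
    stop("unpaired sample libraries (configuration error): ",
         paste(unassigned, collapse = ", "))
  if (nrow(rp) == 0) return(x)
  merged <- vapply(seq_len(nrow(rp)), function(i) {
    a <- x$counts[, rp$lib_a[i]]
    b <- x$counts[, rp$lib_b[i]]
    ifelse(a > 0L & b > 0L, a + b, 0L)
  }, integer(nrow(x$counts)))
  merged <- matrix(merged, nrow = nrow(x$counts),
                   dimnames = list(rownames(x$counts), rp$sample_id))
  neg <- x$counts[, x$negative_ids, drop = FALSE]
  otu_table(cbind(merged, neg), negative_ids = x$negative_ids)
}

#' Subtract the negative-control maximum from every sample
#'
#' Contamination control: for each OTU the maximum read count observed across
#' all negative-control libraries is subtracted from that OTU's count in every
#' sample, flooring at zero. Negative libraries are dropped from the output.
#'
#' @param x an `otu_table` (typically replicate-merged).
#' @return an `otu_table` without negative libraries.
#' @export
subtract_negatives <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  if (length(x$negative_ids) == 0) {
    warning("no negative-control libraries; subtraction is the identity")
    return(x)
  }
  neg <- x$counts[, x$negative_ids, drop = FALSE]
  m <- apply(neg, 1L, max)
  keep <- setdiff(colnames(x$counts), x$negative_ids)
  out <- pmax(x$counts[, keep, drop = FALSE] - m, 0L)
  rp <- x$replicate_pairs[x$replicate_pairs$lib_a %in% keep, , drop = FALSE]
  otu_table(out, replicate_pairs = rp, negative_ids = character())
}

#' Split the curated table into the named-species and insect datasets
#'
#' Two datasets are analysed downstream: (1) OTUs carrying a species-level
#' assignment and (2) OTUs assigned to class Insecta.
#'
#' @param x an `otu_table`.
#' @param annotations per-OTU annotation data.frame (see
#'   [otu_annotations()]); must cover every OTU in `x`.
#' @return list with `otu_table` elements `species` and `insects`.
#' @export
split_datasets <- function(x, annotations) {
  stopifnot(inherits(x, "otu_table"))
  ann <- match_annotations(x, annotations)
  named <- !is.na(ann$species) & nzchar(ann$species)
  insect <- !is.na(ann$class) & ann$class == "Insecta"
  if (!any(insect)) warning("no OTUs assigned to Insecta")
  subset_rows <- function(keep) {
    otu_table(x$counts[keep, , drop = FALSE],
              replicate_pairs = x$replicate_pairs,
              negative_ids = x$negative_ids)
  }
  list(species = subset_rows(named), insects = subset_rows(insect))
}

match_annotations <- function(x, annotations) {
  idx <- match(rownames(x$counts), annotations$otu_id)
  if (anyNA(idx))
    stop("OTUs without annotation: ",
         paste(rownames(x$counts)[is.na(idx)], collapse = ", "))
  annotations[idx, , drop = FALSE]
}

#' Species-name hygiene filter
#'
#' Keeps only clean Latin binomials: exactly two tokens separated by one
#' space, each consisting solely of letters. Names carrying digits,
#' punctuation, placeholder epithets ("sp.", "cf.") or BIN-style suffixes are
#' dropped, as these indicate incomplete reference records.
#'
#' @param names character vector of species names.
#' @param allow_hyphen keep hyphenated epithets (e.g. some valid compound
#'   epithets)? Default `FALSE`: the strict rule drops all punctuation.
#' @return list with character vectors `kept` and `dropped`.
#' @export
clean_species_names <- function(names, allow_hyphen = FALSE) {
  names <- as.character(names)
  token <- if (allow_hyphen) "\\p{L}+(-\\p{L}+)?" else "\\p{L}+"
  re <- sprintf("^%s %s$", token, token)
  ok <- !is.na(names) & grepl(re, names, perl = TRUE)
  list(kept = names[ok], dropped = names[!ok])
}

#' Merge OTUs sharing a species assignment
#'
#' All OTUs assigned to the same (hygiene-passing) species name are collapsed
#' by summing their per-sample reads. The number of OTUs contributing to each
#' species is recorded; it feeds the OTU-per-species ratios used for
#' dark-taxa estimation. OTUs whose reads were entirely removed by earlier
#' filtering do not count as contributing.
#'
#' @param x an `otu_table` restricted to named OTUs (dataset 1).
#' @param annotations per-OTU annotations covering `x`.
#' @param allow_hyphen passed to [clean_species_names()].
#' @return a `species_table`: list with `counts` (species x sample integer
#'   matrix), `otus_per_species` (named integer vector) and `taxonomy`
#'   (one row per species: class, order, family, genus).
#' @export
merge_by_species <- function(x, annotations, allow_hyphen = FALSE) {
  stopifnot(inherits(x, "otu_table"))
  ann <- match_annotations(x, annotations)
  named <- !is.na(ann$species) & nzchar(ann$species)
  kept_names <- clean_species_names(unique(ann$species[named]), allow_hyphen)$kept
  use <- named & ann$species %in% kept_names
  sp <- ann$species[use]
  cnt <- x$counts[use, , drop = FALSE]
  groups <- sort(unique(sp))
  counts <- t(vapply(groups, function(g) {
    as.integer(colSums(cnt[sp == g, , drop = FALSE]))
  }, integer(ncol(cnt))))
  colnames(counts) <- colnames(cnt)
  contributing <- rowSums(cnt) > 0
  ops <- vapply(groups, function(g) sum(sp == g & contributing), integer(1L))
  ops[ops == 0L] <- 1L  # species observed only through zeroed OTUs still map to >=1 OTU
  tax <- do.call(rbind, lapply(groups, function(g) {
    r <- which(sp == g)[1L]
    a <- ann[use, , drop = FALSE][r, ]
    data.frame(species = g, class = a$class, order = a$order,
               family = a$family, genus = a$genus, stringsAsFactors = FALSE)
  }))
  structure(list(counts = counts, otus_per_species = ops, taxonomy = tax),
            class = "species_table")
}

#' @export
print.species_table <- function(x, ...) {
  cat(sprintf("species_table: %d species x %d samples; %d contributing OTUs\n",
              nrow(x$counts), ncol(x$counts), sum(x$otus_per_species)))
  invisible(x)
}

#' Per-OTU taxonomy and sequence annotations
#'
#' Validates the annotation data.frame used throughout the pipeline. Species
#' names, when present, require a genus; sequences are over {A,C,G,T,N}.
#'
#' @param otu_id,sequence,class,order,family,genus,species equal-length
#'   character vectors (empty string = unassigned rank).
#' @return a data.frame of class `otu_annotations`.
#' @export
otu_annotations <- function(otu_id, sequence, class = "", order = "",
                            family = "", genus = "", species = "") {
  df <- data.frame(otu_id = as.character(otu_id),
                   sequence = toupper(as.character(sequence)),
                   class = class, order = order, family = family,
                   genus = genus, species = species,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$otu_id)) stop("duplicated otu_id in annotations")
  bad <- grepl("[^ACGTN]", df$sequence)
  if (any(bad))
    stop("sequences with non-ACGTN characters: ",
         paste(df$otu_id[bad], collapse = ", "))
  named <- nzchar(df$species)
  if (any(named & !nzchar(df$genus)))
    stop("species assignment without genus: ",
         paste(df$otu_id[named & !nzchar(df$genus)], collapse = ", "))
  class(df) <- c("otu_annotations", "data.frame")
  df
}
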