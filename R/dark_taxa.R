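# Plausible-species and dark-taxa estimation.
#
# OTU clustering over-splits some species (pseudogenes, intraspecific
# divergence), so raw unnamed-OTU counts overstate the number of additional
# species. The correction divides unnamed OTU counts per taxon by the mean
# number of OTUs observed per *validated* species of that taxon, yielding
# "plausible species". Comparing these against regional checklist and
# barcode-reference coverage splits them into species that merely lack a
# reference barcode versus potential dark taxa (undescribed/unrecorded).

#' Mean OTUs per validated species, by order or family
#'
#' @param st a `species_table` (carries `otus_per_species` and per-species
#'   taxonomy).
#' @param validated character vector of validated species names.
#' @param level `"order"` or `"family"`.
#' @return data.frame with `taxon`, `n_validated`, `n_otus`, `ratio`,
#'   `fallback` (TRUE when the taxon had no validated species and received
#'   the global mean ratio).
#' @export
otus_per_species_ratio <- function(st, validated, level = c("order", "family")) {
  level <- match.arg(level)
  stopifnot(inherits(st, "species_table"))
  tax <- st$taxonomy[[level]]
  sp <- st$taxonomy$species
  ok <- sp %in% validated
  taxa <- sort(unique(tax))
  global <- if (any(ok)) sum(st$otus_per_species[ok]) / sum(ok) else 1
  res <- lapply(taxa, function(tx) {
    sel <- ok & tax == tx
    n <- sum(sel)
    if (n > 0)
      data.frame(taxon = tx, n_validated = n,
                 n_otus = sum(st$otus_per_species[sel]),
                 ratio = sum(st$otus_per_species[sel]) / n,
                 fallback = FALSE, stringsAsFactors = FALSE)
    else
      data.frame(taxon = tx, n_validated = 0L, n_otus = 0L,
                 ratio = global, fallback = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Count unnamed OTUs per taxon
#'
#' Unnamed OTUs are those in the insect dataset without a species-level
#' assignment (after all filtering); only OTUs retaining reads are counted.
#'
#' @param insect_table the insect-dataset `otu_table`.
#' @param annotations OTU annotations covering the table.
#' @param level `"order"` or `"family"`.
#' @return named integer vector taxon -> unnamed OTU count.
#' @export
unnamed_otu_counts <- function(insect_table, annotations,
                               level = c("order", "family")) {
  level <- match.arg(level)
  ann <- match_annotations(insect_table, annotations)
  unnamed <- (!nzchar(ann$species) | is.na(ann$species)) &
    rowSums(insect_table$counts) > 0
  tab <- table(ann[[level]][unnamed])
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Plausible additional species behind unnamed OTUs
#'
#' Divides each taxon's unnamed OTU count by its mean OTUs-per-validated-
#' species ratio and rounds (half to even). Taxa on the exclusion list (by
#' default Orthoptera, whose abundant pseudogenes inflate the ratio and the
#' OTU counts) contribute zero and are reported separately.
#'
#' @param unnamed named integer vector taxon -> unnamed OTU count (see
#'   [unnamed_otu_counts()]).
#' @param ratios data.frame from [otus_per_species_ratio()] (or named numeric
#'   vector of ratios).
#' @param exclude character vector of taxa to exclude, default
#'   `"Orthoptera"`.
#' @return data.frame `taxon`, `n_unnamed_otus`, `ratio`, `plausible`,
#'   `excluded`.
#' @export
plausible_species <- function(unnamed, ratios, exclude = "Orthoptera") {
  if (is.data.frame(ratios)) {
    r <- ratios$ratio
    names(r) <- ratios$taxon
    ratios <- r
  }
  if (any(ratios <= 0, na.rm = TRUE)) stop("ratios must be positive")
  taxa <- names(unnamed)
  ratio <- ratios[taxa]
  missing_ratio <- is.na(ratio)
  if (any(missing_ratio)) {
    # taxa never seen among validated species fall back to the global mean
    ratio[missing_ratio] <- mean(ratios, na.rm = TRUE)
  }
  excluded <- taxa %in% exclude
  pl <- ifelse(excluded, 0L, as.integer(round(unnamed / ratio)))
  data.frame(taxon = taxa, n_unnamed_otus = as.integer(unnamed),
             ratio = as.numeric(ratio), plausible = pl, excluded = excluded,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Partition plausible species into missing-reference vs potential dark taxa
#'
#' Regionally known but unbarcoded species (`known - barcoded`) form the
#' capacity of the "missing reference" explanation; plausible species beyond
#' that capacity are potential dark taxa (unrecorded or undescribed).
#'
#' @param plausible integer vector of plausible-species counts per taxon.
#' @param known,barcoded per-taxon counts of species known from the region
#'   and of those with reference barcodes. Taxa with `barcoded > known` are
#'   clamped with a warning; taxa absent from the reference table (NA) get
#'   capacity 0.
#' @return data.frame with `missing_reference` and `potential_dark`
#'   (`plausible = missing_reference + potential_dark` per taxon).
#' @export
partition_dark <- function(plausible, known, barcoded) {
  known[is.na(known)] <- 0
  barcoded[is.na(barcoded)] <- 0
  if (any(barcoded > known)) {
    warning("barcoded > known for some taxa; clamping capacity at 0")
    barcoded <- pmin(barcoded, known)
  }
  capacity <- known - barcoded
  mr <- pmin(plausible, capacity)
  data.frame(missing_reference = as.integer(mr),
             potential_dark = as.integer(plausible - mr))
}

#' Grand total species estimate
#'
#' @param validated_count number of validated named species.
#' @param plausible_counts per-taxon plausible-species counts.
#' @return `validated_count + sum(plausible_counts)`.
#' @export
total_species <- function(validated_count, plausible_counts) {
  as.integer(validated_count + sum(plausible_counts))
}

#' Full per-taxon dark-taxa estimation
#'
#' Convenience driver combining [otus_per_species_ratio()],
#' [unnamed_otu_counts()], [plausible_species()] and [partition_dark()].
#'
#' @param st a `species_table`.
#' @param insect_table the insect-dataset `otu_table`.
#' @param annotations OTU annotations.
#' @param validated validated species names.
#' @param reference_counts data.frame `taxon`, `known_species`,
#'   `barcoded_species` (may omit taxa; missing taxa get capacity 0).
#' @param level `"order"` or `"family"`.
#' @param exclude excluded taxa, default `"Orthoptera"`.
#' @return data.frame of class `order_estimate`, one row per taxon, with OTU
#'   counts, ratios, plausible counts and the missing-reference/dark split.
#' @export
estimate_dark <- function(st, insect_table, annotations, validated,
                          reference_counts = NULL,
                          level = c("order", "family"),
                          exclude = "Orthoptera") {
  level <- match.arg(level)
  ratios <- otus_per_species_ratio(st, validated, level)
  unnamed <- unnamed_otu_counts(insect_table, annotations, level)
  taxa <- sort(union(ratios$taxon, names(unnamed)))
  un <- unnamed[taxa]
  un[is.na(un)] <- 0L
  names(un) <- taxa
  pl <- plausible_species(un, ratios, exclude)
  ann <- match_annotations(insect_table, annotations)
  live <- rowSums(insect_table$counts) > 0
  n_total <- vapply(taxa, function(tx) sum(ann[[level]] == tx & live), integer(1))
  known <- barc <- rep(NA_real_, length(taxa))
  if (!is.null(reference_counts)) {
    i <- match(taxa, reference_counts$taxon)
    known <- reference_counts$known_species[i]
    barc <- reference_counts$barcoded_species[i]
  }
  part <- partition_dark(pl$plausible, known, barc)
  ri <- match(taxa, ratios$taxon)
  out <- data.frame(taxon = taxa,
                    n_otus_total = n_total,
                    n_otus_named = n_total - as.integer(un),
                    n_validated_species = ifelse(is.na(ri), 0L, ratios$n_validated[ri]),
                    mean_otus_per_species = pl$ratio,
                    ratio_fallback = ifelse(is.na(ri), TRUE, ratios$fallback[ri]),
                    n_unnamed_otus = as.integer(un),
                    n_plausible = pl$plausible,
                    excluded = pl$excluded,
                    n_known_in_region = ifelse(is.na(known), 0L, as.integer(known)),
                    n_barcoded_in_region = ifelse(is.na(barc), 0L, as.integer(barc)),
                    n_missing_reference = part$missing_reference,
                    n_potential_dark = part$potential_dark,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("order_estimate", "data.frame")
  out
}
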