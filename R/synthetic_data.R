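# Seeded synthetic communities with the statistical structure the analysis
# assumes: duplicate libraries per sample, 12 negative controls per 96-well
# plate, cross-contamination reads in negatives, per-species OTU inflation
# with a pseudogene fraction, partial reference coverage, and occurrence
# records spatially clustered around occupied trap sites.

.insect_orders <- c("Diptera", "Hymenoptera", "Lepidoptera", "Coleoptera",
                    "Hemiptera", "Trichoptera", "Psocodea", "Neuroptera",
                    "Plecoptera", "Ephemeroptera", "Orthoptera", "Odonata",
                    "Dermaptera", "Blattodea", "Mecoptera", "Thysanoptera",
                    "Megaloptera", "Raphidioptera", "Zygentoma", "Mantodea")

.syllables <- c("ba", "ce", "di", "fo", "gu", "la", "me", "ni", "po", "ra",
                "su", "te", "vi", "xo", "ze")

# deterministic unique letters-only word from an integer index
syllable_word <- function(i, n_syll = 3L) {
  b <- length(.syllables)
  idx <- integer(n_syll)
  i <- i - 1L
  for (k in seq_len(n_syll)) {
    idx[k] <- i %% b + 1L
    i <- i %/% b
  }
  paste(.syllables[idx], collapse = "")
}

capitalize <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

.sense_codons_invmito <- {
  b <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all_codons, c("TAA", "TAG"))
}

# 205-base COI-like fragment: 68 sense codons (in frame 1) + 1 trailing base
random_coi_sequence <- function() {
  paste0(paste(sample(.sense_codons_invmito, 68, replace = TRUE), collapse = ""),
         sample(c("A", "C", "G", "T"), 1))
}

# overwrite a codon-aligned 12-base window with stops in all three forward
# frames, so the any-frame-stop-free keep rule removes the OTU for certain
make_pseudogene <- function(seq) {
  j <- sample(1:64, 1)                  # codon index; window spans 4 codons
  q <- 3L * (j - 1L) + 1L
  paste0(substr(seq, 1, q - 1L), "TAAATAAATAAA", substr(seq, q + 12L, nchar(seq)))
}

#' Specification of a synthetic metabarcoding study
#'
#' Defaults describe a desk-scale analogue of a nationwide Malaise-trap
#' programme: six diverse insect orders, duplicate libraries per sample,
#' 12 negatives per 96-library plate, lognormal read abundances, an OTU
#' inflation of 1.3 per species (within the 1.0-1.5 range typical of COI
#' clustering at 97%), and occurrence records scattered within 100 km of the
#' traps where a species truly occurs.
#'
#' @param n_orders number of insect orders (taken from a fixed list).
#' @param species_per_order species per order (scalar or length-`n_orders`).
#' @param otu_inflation_mean expected OTUs per true species (>= 1); drawn as
#'   `1 + Poisson(mean - 1)`.
#' @param pseudogene_rate fraction of the *extra* OTUs that are pseudogenes
#'   carrying in-frame stop codons.
#' @param reference_coverage fraction of species carrying a name in the
#'   reference database (i.e. assignable).
#' @param checklist_coverage fraction of named species present in the
#'   checklist.
#' @param expert_coverage fraction of named species on the expert-accepted
#'   list.
#' @param occurrence_density expected occurrence records per named species
#'   (Poisson).
#' @param occurrence_radius_km records fall uniformly within this distance of
#'   an occupied trap (default 100, half the validation radius, so truly
#'   present species pass the spatial check by construction).
#' @param n_traps,samples_per_trap sampling design; samples are split evenly
#'   between two study years.
#' @param occupancy probability a species is present in a given sample.
#' @param read_abundance lognormal meanlog/sdlog of per-(OTU, replicate) read
#'   counts, `c(mu, sigma)`.
#' @param contamination_reads_mean expected reads per OTU leaking into each
#'   negative control (Poisson).
#' @param replicate_dropout probability an occupied OTU is absent from one
#'   (randomly chosen) technical replicate.
#' @param seed integer seed; the full dataset is a deterministic function of
#'   the spec.
#' @return validated list of class `community_spec`.
#' @export
community_spec <- function(n_orders = 6, species_per_order = 60,
                           otu_inflation_mean = 1.3, pseudogene_rate = 0.1,
                           reference_coverage = 0.5, checklist_coverage = 0.9,
                           expert_coverage = 0.95, occurrence_density = 3,
                           occurrence_radius_km = 100, n_traps = 8,
                           samples_per_trap = 10, occupancy = 0.15,
                           read_abundance = c(mu = 5, sigma = 1.2),
                           contamination_reads_mean = 0.5,
                           replicate_dropout = 0.05, seed = 1) {
  n_orders <- check_count(n_orders, "n_orders")
  if (n_orders > length(.insect_orders))
    stop_field("n_orders", sprintf("at most %d", length(.insect_orders)))
  if (length(species_per_order) == 1L)
    species_per_order <- rep(species_per_order, n_orders)
  if (length(species_per_order) != n_orders)
    stop_field("species_per_order", "length must be 1 or n_orders")
  species_per_order <- vapply(species_per_order, check_count, integer(1),
                              field = "species_per_order")
  if (!is.numeric(otu_inflation_mean) || otu_inflation_mean < 1)
    stop_field("otu_inflation_mean", "must be >= 1")
  check_prob(pseudogene_rate, "pseudogene_rate")
  check_prob(reference_coverage, "reference_coverage")
  check_prob(checklist_coverage, "checklist_coverage")
  check_prob(expert_coverage, "expert_coverage")
  check_prob(occupancy, "occupancy")
  check_prob(replicate_dropout, "replicate_dropout")
  if (!is.numeric(occurrence_density) || occurrence_density < 0)
    stop_field("occurrence_density", "must be >= 0")
  if (!is.numeric(occurrence_radius_km) || occurrence_radius_km <= 0)
    stop_field("occurrence_radius_km", "must be > 0")
  n_traps <- check_count(n_traps, "n_traps")
  samples_per_trap <- check_count(samples_per_trap, "samples_per_trap")
  if (length(read_abundance) != 2 || any(!is.finite(read_abundance)) ||
      read_abundance[2] < 0)
    stop_field("read_abundance", "must be c(mu, sigma) with sigma >= 0")
  if (!is.numeric(contamination_reads_mean) || contamination_reads_mean < 0)
    stop_field("contamination_reads_mean", "must be >= 0")
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(n_orders = n_orders, species_per_order = species_per_order,
                 otu_inflation_mean = otu_inflation_mean,
                 pseudogene_rate = pseudogene_rate,
                 reference_coverage = reference_coverage,
                 checklist_coverage = checklist_coverage,
                 expert_coverage = expert_coverage,
                 occurrence_density = occurrence_density,
                 occurrence_radius_km = occurrence_radius_km,
                 n_traps = n_traps, samples_per_trap = samples_per_trap,
                 occupancy = occupancy,
                 read_abundance = stats::setNames(as.numeric(read_abundance),
                                                  c("mu", "sigma")),
                 contamination_reads_mean = contamination_reads_mean,
                 replicate_dropout = replicate_dropout, seed = seed),
            class = "community_spec")
}

#' Generate a ground-truthed synthetic dataset
#'
#' Deterministic for a fixed spec (including its seed). OTU sequences are
#' 205-base fragments, in frame 1 protein-coding under the invertebrate
#' mitochondrial code except for the pseudogene fraction; negative controls
#' carry only contamination reads; species occupy samples as independent
#' Bernoulli draws; occurrence records are scattered around occupied traps.
#'
#' @param spec a [community_spec()].
#' @return list with elements `table` ([otu_table()]), `annotations`,
#'   `samples`, `traps`, `occurrences`, `checklist`, `expert`,
#'   `reference_counts` and `truth` (the ground-truth bookkeeping used by
#'   tests).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(spec$seed, generate_dataset_impl(spec))
}

generate_dataset_impl <- function(spec) {
  orders <- .insect_orders[seq_len(spec$n_orders)]
  n_sp <- sum(spec$species_per_order)

  # --- species, families, genera, names -------------------------------------
  sp_order <- rep(orders, spec$species_per_order)
  fam_within <- unlist(lapply(spec$species_per_order, function(k)
    ceiling(seq_len(k) / 12)))  # ~12 species per family
  sp_family <- paste0(sub("a$", "", sp_order), "idae",
                      vapply(fam_within, function(i) syllable_word(i, 1), ""))
  genus_key <- paste(sp_family, (seq_len(n_sp) - 1L) %/% 4L)  # ~4 spp/genus
  genus_idx <- as.integer(factor(genus_key, levels = unique(genus_key)))
  sp_genus <- capitalize(vapply(genus_idx, syllable_word, "", n_syll = 3L))
  sp_epithet <- vapply(seq_len(n_sp) + 1000L, syllable_word, "", n_syll = 3L)
  sp_binomial <- paste(sp_genus, sp_epithet)
  named <- stats::runif(n_sp) < spec$reference_coverage
  species_id <- sprintf("SP%04d", seq_len(n_sp))

  # --- OTUs per species (inflation + pseudogenes) ---------------------------
  n_otus_per_sp <- 1L + stats::rpois(n_sp, spec$otu_inflation_mean - 1)
  otu_species <- rep(seq_len(n_sp), n_otus_per_sp)
  n_otu <- length(otu_species)
  otu_id <- sprintf("OTU_%05d", seq_len(n_otu))
  is_extra <- unlist(lapply(n_otus_per_sp, function(k) c(FALSE, rep(TRUE, k - 1L))))
  is_pseudo <- is_extra & stats::runif(n_otu) < spec$pseudogene_rate
  seqs <- vapply(seq_len(n_otu), function(i) random_coi_sequence(), "")
  seqs[is_pseudo] <- vapply(seqs[is_pseudo], make_pseudogene, "")

  annotations <- otu_annotations(
    otu_id = otu_id, sequence = seqs, class = "Insecta",
    order = sp_order[otu_species], family = sp_family[otu_species],
    genus = ifelse(named[otu_species], sp_genus[otu_species], ""),
    species = ifelse(named[otu_species], sp_binomial[otu_species], ""))

  # --- traps, samples, libraries --------------------------------------------
  traps <- data.frame(trap_id = sprintf("T%02d", seq_len(spec$n_traps)),
                      latitude = stats::runif(spec$n_traps, 47.5, 54.5),
                      longitude = stats::runif(spec$n_traps, 6.5, 14.5),
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste0(rep(traps$trap_id, each = spec$samples_per_trap), "_S",
                       sprintf("%02d", rep(seq_len(spec$samples_per_trap),
                                           spec$n_traps))),
    trap_id = rep(traps$trap_id, each = spec$samples_per_trap),
    year = 2019L + rep(seq_len(spec$samples_per_trap), spec$n_traps) %% 2L,
    stringsAsFactors = FALSE)
  n_samples <- nrow(samples)
  n_lib <- 2L * n_samples
  n_neg <- 12L * ceiling(n_lib / 84)  # 12 negatives per 96-library plate
  lib_a <- paste0(samples$sample_id, "_A")
  lib_b <- paste0(samples$sample_id, "_B")
  neg_ids <- sprintf("NEG%02d", seq_len(n_neg))

  # --- read counts -----------------------------------------------------------
  presence <- matrix(stats::runif(n_sp * n_samples) < spec$occupancy,
                     nrow = n_sp)
  mu <- spec$read_abundance[["mu"]]; sig <- spec$read_abundance[["sigma"]]
  draw_counts <- function() {
    m <- matrix(0L, n_otu, n_samples)
    occ <- presence[otu_species, , drop = FALSE]
    k <- sum(occ)
    m[occ] <- as.integer(round(stats::rlnorm(k, mu, sig)))
    m
  }
  A <- draw_counts(); B <- draw_counts()
  drop <- matrix(stats::runif(n_otu * n_samples) < spec$replicate_dropout,
                 n_otu, n_samples) & presence[otu_species, , drop = FALSE]
  which_rep <- matrix(stats::runif(n_otu * n_samples) < 0.5, n_otu, n_samples)
  A[drop & which_rep] <- 0L
  B[drop & !which_rep] <- 0L
  neg <- matrix(stats::rpois(n_otu * n_neg, spec$contamination_reads_mean),
                n_otu, n_neg)
  counts <- cbind(A, B, neg)
  dimnames(counts) <- list(otu_id, c(lib_a, lib_b, neg_ids))
  table <- otu_table(counts,
                     replicate_pairs = data.frame(sample_id = samples$sample_id,
                                                  lib_a = lib_a, lib_b = lib_b,
                                                  stringsAsFactors = FALSE),
                     negative_ids = neg_ids)

  # --- occurrence records around occupied traps -----------------------------
  trap_of_sample <- match(samples$trap_id, traps$trap_id)
  occ_rows <- list()
  for (s in which(named)) {
    n_rec <- stats::rpois(1, spec$occurrence_density)
    if (n_rec == 0) next
    occupied <- unique(trap_of_sample[presence[s, ]])
    if (length(occupied) == 0) occupied <- sample.int(nrow(traps), 1)
    ti <- occupied[sample.int(length(occupied), n_rec, replace = TRUE)]
    r <- spec$occurrence_radius_km * sqrt(stats::runif(n_rec))
    brg <- stats::runif(n_rec, 0, 360)
    pt <- destination_point(traps$latitude[ti], traps$longitude[ti], brg, r)
    occ_rows[[length(occ_rows) + 1L]] <-
      data.frame(species = sp_binomial[s], latitude = pt[, "lat"],
                 longitude = pt[, "lon"], stringsAsFactors = FALSE)
  }
  occurrences <- if (length(occ_rows)) do.call(rbind, occ_rows) else
    data.frame(species = character(), latitude = numeric(),
               longitude = numeric(), stringsAsFactors = FALSE)

  # --- checklist (with synonyms) and expert list ----------------------------
  in_checklist <- named & stats::runif(n_sp) < spec$checklist_coverage
  canonical <- sp_binomial[in_checklist]
  syn_src <- canonical[stats::runif(length(canonical)) < 0.1]
  synonyms <- character()
  if (length(syn_src)) {
    syn_names <- paste(capitalize(vapply(seq_along(syn_src) + 5000L,
                                         syllable_word, "", n_syll = 3L)),
                       vapply(seq_along(syn_src) + 6000L, syllable_word, "",
                              n_syll = 3L))
    synonyms <- stats::setNames(syn_src, syn_names)
  }
  checklist <- name_list(canonical, synonyms)
  expert <- name_list(sp_binomial[named & stats::runif(n_sp) < spec$expert_coverage])

  # --- per-order reference coverage -----------------------------------------
  reference_counts <- data.frame(
    taxon = orders,
    known_species = as.integer(tapply(rep(1L, n_sp), sp_order, sum)[orders]),
    barcoded_species = as.integer(tapply(as.integer(named), sp_order, sum)[orders]),
    stringsAsFactors = FALSE)

  truth <- list(
    true_species_total = n_sp,
    true_named_species = sum(named),
    true_dark_species = sum(!named),
    species_to_otus = split(otu_id, species_id[otu_species])[species_id],
    species_binomial = stats::setNames(ifelse(named, sp_binomial, NA_character_),
                                       species_id),
    species_order = stats::setNames(sp_order, species_id),
    pseudogene_otus = otu_id[is_pseudo],
    species_presence = data.frame(
      species_id = rep(species_id, n_samples)[as.vector(presence)],
      sample_id = rep(samples$sample_id, each = n_sp)[as.vector(presence)],
      stringsAsFactors = FALSE))

  list(table = table, annotations = annotations, samples = samples,
       traps = traps, occurrences = occurrences, checklist = checklist,
       expert = expert, reference_counts = reference_counts, truth = truth,
       spec = spec)
}
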