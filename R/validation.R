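#' Species name list with synonym resolution
#'
#' Used for both the national checklist criterion and the expert-accepted
#' list. A query name matches if it is a canonical entry or a synonym
#' resolving to one.
#'
#' @param canonical character vector of accepted names (must pass name
#'   hygiene).
#' @param synonyms named character vector: `names()` are synonyms, values the
#'   canonical names they resolve to.
#' @return object of class `name_list`.
#' @export
name_list <- function(canonical, synonyms = character()) {
  canonical <- unique(as.character(canonical))
  bad <- clean_species_names(canonical)$dropped
  if (length(bad))
    stop("canonical names failing hygiene: ", paste(bad, collapse = ", "))
  if (length(synonyms)) {
    if (is.null(names(synonyms))) stop("synonyms must be a named vector")
    unknown <- setdiff(unname(synonyms), canonical)
    if (length(unknown))
      stop("synonyms resolving to non-canonical names: ",
           paste(unknown, collapse = ", "))
  }
  structure(list(canonical = canonical, synonyms = synonyms),
            class = "name_list")
}

#' Resolve species names through a synonym table
#' @param species character vector.
#' @param nl a [name_list()].
#' @return character vector of canonical names (input left unchanged when it
#'   is neither canonical nor a known synonym).
#' @export
resolve_name <- function(species, nl) {
  stopifnot(inherits(nl, "name_list"))
  hit <- match(species, names(nl$synonyms))
  out <- species
  out[!is.na(hit)] <- unname(nl$synonyms[hit[!is.na(hit)]])
  out
}

#' Checklist criterion: does the species occur in the national checklist?
#' @param species character vector of species names.
#' @param checklist a [name_list()].
#' @return logical vector.
#' @export
check_checklist <- function(species, checklist) {
  resolve_name(species, checklist) %in% checklist$canonical
}

#' Expert criterion: membership in the expert-accepted species list
#'
#' The artifact's stand-in for human plausibility judgement: a provided
#' accepted-species file, resolved through the same synonym machinery as the
#' checklist.
#'
#' @inheritParams check_checklist
#' @param expert_list a [name_list()].
#' @return logical vector.
#' @export
check_expert <- function(species, expert_list) {
  check_checklist(species, expert_list)
}

#' Map species to the traps where they were detected
#'
#' @param st a `species_table` (post-filtering counts).
#' @param samples data.frame with columns `sample_id`, `trap_id` covering the
#'   table's sample columns.
#' @return named list: species -> character vector of trap ids with >0 reads.
#' @export
species_detections <- function(st, samples) {
  stopifnot(inherits(st, "species_table"))
  idx <- match(colnames(st$counts), samples$sample_id)
  if (anyNA(idx))
    stop("samples sheet missing: ",
         paste(colnames(st$counts)[is.na(idx)], collapse = ", "))
  trap_of <- samples$trap_id[idx]
  out <- lapply(seq_len(nrow(st$counts)), function(i)
    unique(trap_of[st$counts[i, ] > 0]))
  names(out) <- rownames(st$counts)
  out
}

#' Occurrence-record criterion: GBIF-style spatial range check
#'
#' For each species, a search region is built around the traps where the
#' species was detected (convex hull buffered by `radius_km`); the criterion
#' is met when at least one occurrence record of the species falls inside.
#'
#' @param species character vector.
#' @param detections named list species -> trap ids (see
#'   [species_detections()]).
#' @param traps data.frame `trap_id`, `latitude`, `longitude`.
#' @param occurrences data.frame `species`, `latitude`, `longitude`.
#' @param radius_km buffer radius, default 200.
#' @param synonyms optional [name_list()] through which both detected and
#'   record names are resolved.
#' @return data.frame with `species`, `occurrence_ok`, `n_records_inside`.
#' @export
check_occurrences <- function(species, detections, traps, occurrences,
                              radius_km = 200, synonyms = NULL) {
  occ_sp <- occurrences$species
  qry <- species
  if (!is.null(synonyms)) {
    occ_sp <- resolve_name(occ_sp, synonyms)
    qry <- resolve_name(qry, synonyms)
  }
  res <- lapply(seq_along(species), function(i) {
    tr <- detections[[species[i]]]
    if (is.null(tr) || length(tr) == 0L) {
      warning("species with zero occupied traps skipped: ", species[i])
      return(c(ok = FALSE, n = 0))
    }
    ti <- match(tr, traps$trap_id)
    if (anyNA(ti)) stop("unknown trap ids for ", species[i], ": ",
                        paste(tr[is.na(ti)], collapse = ", "))
    rec <- occurrences[occ_sp == qry[i], , drop = FALSE]
    if (nrow(rec) == 0L) return(c(ok = FALSE, n = 0))
    region <- build_search_region(traps$latitude[ti], traps$longitude[ti],
                                  radius_km)
    inside <- region_contains(region, rec$latitude, rec$longitude)
    c(ok = any(inside), n = sum(inside))
  })
  data.frame(species = species,
             occurrence_ok = vapply(res, function(r) r[["ok"]] > 0, logical(1)),
             n_records_inside = vapply(res, function(r) as.integer(r[["n"]]), integer(1)),
             stringsAsFactors = FALSE)
}

#' Consensus verdict over the enabled validation criteria
#'
#' A species record is accepted when at least `min_criteria` of the enabled
#' criteria hold (default: two of three).
#'
#' @param expert_ok,occurrence_ok,checklist_ok logical vectors (pass `NULL`
#'   for a disabled criterion).
#' @param min_criteria minimum number of criteria that must hold, default 2.
#' @return logical vector of verdicts.
#' @export
validate_species <- function(expert_ok = NULL, occurrence_ok = NULL,
                             checklist_ok = NULL, min_criteria = 2) {
  crit <- Filter(Negate(is.null),
                 list(expert_ok, occurrence_ok, checklist_ok))
  if (length(crit) == 0L) stop("no criteria enabled")
  if (min_criteria < 1 || min_criteria > length(crit))
    stop("min_criteria must be between 1 and the number of enabled criteria")
  Reduce(`+`, lapply(crit, as.integer)) >= min_criteria
}

#' Run all enabled validation criteria over a species table
#'
#' @param st a `species_table`.
#' @param samples samples sheet (`sample_id`, `trap_id`).
#' @param traps trap coordinates.
#' @param occurrences occurrence records.
#' @param checklist,expert_list [name_list()] objects.
#' @param radius_km buffer radius for the occurrence criterion.
#' @param min_criteria consensus threshold.
#' @param criteria character subset of `c("expert", "occurrence",
#'   "checklist")` to enable.
#' @return data.frame of class `validation_result`: one row per species with
#'   the per-criterion booleans, the verdict and supporting evidence counts.
#' @export
validate_dataset <- function(st, samples, traps, occurrences, checklist,
                             expert_list, radius_km = 200, min_criteria = 2,
                             criteria = c("expert", "occurrence", "checklist")) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  sp <- rownames(st$counts)
  out <- data.frame(species = sp, stringsAsFactors = FALSE)
  expert_ok <- occurrence_ok <- checklist_ok <- NULL
  if ("expert" %in% criteria)
    out$expert_ok <- expert_ok <- check_expert(sp, expert_list)
  if ("occurrence" %in% criteria) {
    det <- species_detections(st, samples)
    occ <- check_occurrences(sp, det, traps, occurrences, radius_km,
                             synonyms = checklist)
    out$occurrence_ok <- occurrence_ok <- occ$occurrence_ok
    out$n_records_inside <- occ$n_records_inside
  }
  if ("checklist" %in% criteria)
    out$checklist_ok <- checklist_ok <- check_checklist(sp, checklist)
  out$validated <- validate_species(expert_ok, occurrence_ok, checklist_ok,
                                    min_criteria)
  class(out) <- c("validation_result", "data.frame")
  out
}

#' Pairwise percent agreement between validation criteria
#'
#' @param results a [validate_dataset()] data.frame (or any data.frame with
#'   logical `*_ok` columns).
#' @return symmetric matrix of percentages: 100 x (species where both
#'   criteria give the same boolean) / species count.
#' @export
agreement_matrix <- function(results) {
  cols <- grep("_ok$", names(results), value = TRUE)
  if (nrow(results) < 1L || length(cols) < 2L)
    stop("need >=1 species and >=2 criteria")
  m <- matrix(100, length(cols), length(cols), dimnames = list(cols, cols))
  for (i in seq_along(cols))
    for (j in seq_along(cols))
      m[i, j] <- 100 * mean(results[[cols[i]]] == results[[cols[j]]])
  m
}
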