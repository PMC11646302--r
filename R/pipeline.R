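#' Shared and unique elements between year (or site) groups
#'
#' @param groups named list of character vectors (e.g. OTU ids per sampling
#'   year).
#' @return list with `shared` (elements in every group), `unique` (named
#'   list, elements exclusive to each group), `union_size`, `shared_pct` and
#'   `unique_pct` (percentages of the union).
#' @export
year_overlap <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  groups <- lapply(groups, unique)
  un <- Reduce(union, groups)
  shared <- Reduce(intersect, groups)
  uniq <- lapply(seq_along(groups), function(i)
    setdiff(groups[[i]], Reduce(union, groups[-i])))
  names(uniq) <- names(groups)
  pct <- function(x) if (length(un)) 100 * length(x) / length(un) else 0
  list(shared = shared, unique = uniq, union_size = length(un),
       shared_n = length(shared), shared_pct = pct(shared),
       unique_n = vapply(uniq, length, integer(1)),
       unique_pct = vapply(uniq, pct, numeric(1)))
}

#' Run the full post-clustering analysis pipeline
#'
#' Executes the curation and estimation stages in their canonical order:
#' replicate merge, negative subtraction, stop-codon screen, dataset split,
#' name hygiene + species merge, multi-criteria validation, dark-taxa
#' estimation at order and family level, and the year-overlap summary.
#'
#' @param inputs a [read_inputs()] result or a [generate_dataset()] result.
#' @param radius_km occurrence-check buffer radius (default 200).
#' @param min_criteria consensus threshold (default 2 of 3).
#' @param level taxonomic level whose plausible-species count enters the
#'   summary total (`"order"` or `"family"`); both levels are computed.
#' @param exclude taxa excluded from plausible-species estimation (default
#'   Orthoptera).
#' @param genetic_code passed to [screen_stop_codons()].
#' @param verbose log one line per stage with counts in/out.
#' @return list of class `pipeline_result` with the stage artifacts
#'   (`filtered`, `species_table`, `validation`, `agreement`,
#'   `dark_order`, `dark_family`), the `summary` block and a `log`
#'   data.frame.
#' @export
run_pipeline <- function(inputs, radius_km = 200, min_criteria = 2,
                         level = c("order", "family"), exclude = "Orthoptera",
                         genetic_code = "invertebrate_mito", verbose = TRUE) {
  level <- match.arg(level)
  log <- list()
  note <- function(stage, n_in, n_out) {
    if (verbose) message(sprintf("[%s] %s -> %s", stage, n_in, n_out))
    log[[length(log) + 1L]] <<- data.frame(stage = stage, n_in = n_in,
                                           n_out = n_out)
  }

  tb <- inputs$table
  ann <- inputs$annotations
  n_raw <- nrow(tb$counts)

  merged <- merge_replicates(tb)
  note("merge_replicates", ncol(tb$counts), ncol(merged$counts))
  clean <- subtract_negatives(merged)
  note("subtract_negatives", sum(as.numeric(merged$counts)),
       sum(as.numeric(clean$counts)))
  scr <- screen_stop_codons(ann, code = genetic_code)
  keep <- rownames(clean$counts) %in% scr$kept
  clean <- otu_table(clean$counts[keep, , drop = FALSE])
  note("screen_stop_codons", n_raw, sum(keep))
  ds <- split_datasets(clean, ann)
  note("split_datasets", nrow(clean$counts),
       sprintf("species=%d insects=%d", nrow(ds$species$counts),
               nrow(ds$insects$counts)))
  st <- merge_by_species(ds$species, ann)
  note("merge_by_species", nrow(ds$species$counts), nrow(st$counts))

  val <- validate_dataset(st, inputs$samples, inputs$traps,
                          inputs$occurrences, inputs$checklist, inputs$expert,
                          radius_km = radius_km, min_criteria = min_criteria)
  note("validate", nrow(val), sum(val$validated))
  agree <- agreement_matrix(val)
  validated <- val$species[val$validated]

  dark_o <- estimate_dark(st, ds$insects, ann, validated,
                          inputs$reference_counts, level = "order",
                          exclude = exclude)
  dark_f <- estimate_dark(st, ds$insects, ann, validated,
                          reference_counts = NULL, level = "family",
                          exclude = exclude)
  note("estimate_dark", sum(dark_o$n_unnamed_otus),
       sprintf("order=%d family=%d", sum(dark_o$n_plausible),
               sum(dark_f$n_plausible)))

  plaus <- if (level == "order") sum(dark_o$n_plausible) else
    sum(dark_f$n_plausible)

  # year overlap on insect OTUs and validated species
  overlap <- NULL
  if (!is.null(inputs$samples$year) &&
      length(unique(inputs$samples$year)) >= 2) {
    yr <- split(inputs$samples$sample_id, inputs$samples$year)
    ins <- ds$insects$counts
    otu_sets <- lapply(yr, function(sids) {
      sids <- intersect(sids, colnames(ins))
      rownames(ins)[rowSums(ins[, sids, drop = FALSE]) > 0]
    })
    sp_sets <- lapply(yr, function(sids) {
      sids <- intersect(sids, colnames(st$counts))
      sp <- rownames(st$counts)[rowSums(st$counts[, sids, drop = FALSE]) > 0]
      intersect(sp, validated)
    })
    overlap <- list(otus = year_overlap(otu_sets),
                    species = year_overlap(sp_sets))
  }

  summary <- list(
    n_raw_otus = n_raw,
    n_kept_otus = nrow(clean$counts),
    n_insect_otus = nrow(ds$insects$counts),
    n_named_species = nrow(st$counts),
    n_validated_expert = sum(val$expert_ok),
    n_validated_occurrence = sum(val$occurrence_ok),
    n_validated_checklist = sum(val$checklist_ok),
    n_validated = length(validated),
    n_plausible_order = sum(dark_o$n_plausible),
    n_plausible_family = sum(dark_f$n_plausible),
    n_total_species = total_species(length(validated), plaus),
    level = level)

  structure(list(filtered = clean, datasets = ds, species_table = st,
                 validation = val, agreement = agree, dark_order = dark_o,
                 dark_family = dark_f, overlap = overlap, summary = summary,
                 log = do.call(rbind, log)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("Metabarcoding curation summary\n",
      sprintf("  raw OTUs:          %d\n", s$n_raw_otus),
      sprintf("  insect OTUs:       %d\n", s$n_insect_otus),
      sprintf("  named species:     %d\n", s$n_named_species),
      sprintf("  validated species: %d (expert %d / occurrence %d / checklist %d)\n",
              s$n_validated, s$n_validated_expert, s$n_validated_occurrence,
              s$n_validated_checklist),
      sprintf("  plausible species: %d (order level) / %d (family level)\n",
              s$n_plausible_order, s$n_plausible_family),
      sprintf("  total species:     %d (validated + plausible, %s level)\n",
              s$n_total_species, s$level), sep = "")
  invisible(x)
}

#' Write pipeline artifacts to an output directory
#'
#' Serialises the validation table, agreement matrix, per-taxon estimates,
#' stage log and summary (TSV + JSON).
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_report <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv(result$validation, file.path(dir, "validation.tsv"))
  write_tsv(as.data.frame(result$agreement), file.path(dir, "agreement.tsv"))
  write_tsv(result$dark_order, file.path(dir, "estimates_order.tsv"))
  write_tsv(result$dark_family, file.path(dir, "estimates_family.tsv"))
  write_tsv(result$log, file.path(dir, "stages.tsv"))
  jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
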