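# Plain-text fixture formats shared by the generator, the readers and the
# CLI. All tables are tab-separated with a header row; coordinates are CSV
# in WGS84 decimal degrees (longitude east-positive).

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_name_list_tsv <- function(nl, path) {
  df <- data.frame(name = nl$canonical, status = "accepted",
                   accepted_name = "", stringsAsFactors = FALSE)
  if (length(nl$synonyms))
    df <- rbind(df, data.frame(name = names(nl$synonyms), status = "synonym",
                               accepted_name = unname(nl$synonyms),
                               stringsAsFactors = FALSE))
  write_tsv(df, path)
}

read_name_list_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  acc <- df$status == "accepted"
  syn <- stats::setNames(df$accepted_name[!acc], df$name[!acc])
  name_list(df$name[acc], syn)
}

#' Write a dataset as the pipeline's fixture file set
#'
#' Emits the exact formats consumed by [read_inputs()]: the OTU table TSV
#' (first column `otu_id`, one column per library), a library sidecar TSV, a
#' samples sheet, OTU sequences as FASTA, taxonomy TSV, trap and occurrence
#' CSVs, checklist/expert/reference-count TSVs, and (for tests) a
#' ground-truth JSON.
#'
#' @param dataset a [generate_dataset()] result (or a compatible list).
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_fixture <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  p <- function(f) file.path(dir, f)
  tb <- dataset$table
  write_tsv(data.frame(otu_id = rownames(tb$counts), tb$counts,
                       check.names = FALSE, stringsAsFactors = FALSE),
            p("otu_table.tsv"))
  rp <- tb$replicate_pairs
  libs <- rbind(
    data.frame(library_id = rp$lib_a, sample_id = rp$sample_id, role = "A",
               stringsAsFactors = FALSE),
    data.frame(library_id = rp$lib_b, sample_id = rp$sample_id, role = "B",
               stringsAsFactors = FALSE),
    data.frame(library_id = tb$negative_ids, sample_id = "",
               role = "negative", stringsAsFactors = FALSE))
  write_tsv(libs, p("libraries.tsv"))
  write_tsv(dataset$samples, p("samples.tsv"))
  seqs <- Biostrings::DNAStringSet(dataset$annotations$sequence)
  names(seqs) <- dataset$annotations$otu_id
  Biostrings::writeXStringSet(seqs, p("otus.fasta"), width = 80L)
  write_tsv(dataset$annotations[, c("otu_id", "class", "order", "family",
                                    "genus", "species")],
            p("taxonomy.tsv"))
  utils::write.csv(dataset$traps, p("traps.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(dataset$occurrences, p("occurrences.csv"),
                   row.names = FALSE, quote = FALSE)
  write_name_list_tsv(dataset$checklist, p("checklist.tsv"))
  write_name_list_tsv(dataset$expert, p("expert.tsv"))
  write_tsv(dataset$reference_counts, p("reference_counts.tsv"))
  if (!is.null(dataset$truth))
    jsonlite::write_json(dataset$truth, p("ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c("otu_table.tsv", "libraries.tsv", "samples.tsv", "otus.fasta",
             "taxonomy.tsv", "traps.csv", "occurrences.csv", "checklist.tsv",
             "expert.tsv", "reference_counts.tsv")
  invisible(stats::setNames(file.path(dir, files), files))
}

#' Read and cross-validate a fixture directory
#'
#' Loads the full file set written by [write_fixture()] and cross-validates
#' it: every OTU in the table must be annotated and have a sequence, every
#' library must be declared in the sidecar, every sample must name a known
#' trap. Violations raise errors enumerating the offending ids.
#'
#' @param dir directory containing the fixture files.
#' @return list with `table`, `annotations`, `samples`, `traps`,
#'   `occurrences`, `checklist`, `expert`, `reference_counts` and, when
#'   present, `truth`.
#' @export
read_inputs <- function(dir) {
  p <- function(f) {
    fp <- file.path(dir, f)
    if (!file.exists(fp)) stop("missing input file: ", fp)
    fp
  }
  tab <- utils::read.delim(p("otu_table.tsv"), check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "otu_id")
    stop(p("otu_table.tsv"), ": first column must be 'otu_id'")
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab$otu_id
  libs <- utils::read.delim(p("libraries.tsv"), stringsAsFactors = FALSE,
                            colClasses = "character")
  undeclared <- setdiff(colnames(counts), libs$library_id)
  if (length(undeclared))
    stop("libraries absent from libraries.tsv: ",
         paste(undeclared, collapse = ", "))
  a <- libs[libs$role == "A", ]; b <- libs[libs$role == "B", ]
  rp <- merge(a[, c("sample_id", "library_id")],
              b[, c("sample_id", "library_id")], by = "sample_id")
  names(rp) <- c("sample_id", "lib_a", "lib_b")
  table <- otu_table(counts, replicate_pairs = rp,
                     negative_ids = libs$library_id[libs$role == "negative"])

  tax <- utils::read.delim(p("taxonomy.tsv"), stringsAsFactors = FALSE,
                           colClasses = "character")
  seqs <- Biostrings::readDNAStringSet(p("otus.fasta"))
  sq <- stats::setNames(as.character(seqs), names(seqs))
  noseq <- setdiff(tax$otu_id, names(sq))
  if (length(noseq))
    stop("OTUs without FASTA sequence: ", paste(noseq, collapse = ", "))
  annotations <- otu_annotations(tax$otu_id, sq[tax$otu_id], tax$class,
                                 tax$order, tax$family, tax$genus, tax$species)
  unannotated <- setdiff(rownames(counts), annotations$otu_id)
  if (length(unannotated))
    stop("table OTUs without annotation: ",
         paste(unannotated, collapse = ", "))

  samples <- utils::read.delim(p("samples.tsv"), stringsAsFactors = FALSE)
  traps <- utils::read.csv(p("traps.csv"), stringsAsFactors = FALSE)
  if (any(abs(traps$latitude) > 90) || any(abs(traps$longitude) > 180))
    stop("traps.csv: coordinates out of range")
  badtrap <- setdiff(samples$trap_id, traps$trap_id)
  if (length(badtrap))
    stop("samples referencing unknown traps: ",
         paste(badtrap, collapse = ", "))
  occurrences <- utils::read.csv(p("occurrences.csv"),
                                 stringsAsFactors = FALSE)
  refc <- utils::read.delim(p("reference_counts.tsv"),
                            stringsAsFactors = FALSE)
  out <- list(table = table, annotations = annotations, samples = samples,
              traps = traps, occurrences = occurrences,
              checklist = read_name_list_tsv(p("checklist.tsv")),
              expert = read_name_list_tsv(p("expert.tsv")),
              reference_counts = refc)
  gt <- file.path(dir, "ground_truth.json")
  if (file.exists(gt)) out$truth <- jsonlite::read_json(gt, simplifyVector = TRUE)
  out
}
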