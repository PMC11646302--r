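# Laboratory cost/time accounting.
#
# Per-step figures (vendor list prices, liquid-handler runtimes, hands-on
# time) are taken as authoritative inputs; the reproducible computation is
# the aggregation. Currency arithmetic is done on integer cents so column
# sums carry no floating-point drift.

#' Parse a duration string
#'
#' Accepts `"H:MM:SS"` or `"H:MM"` (hours may exceed 23 and carry any number
#' of digits).
#'
#' @param text character vector of durations; empty strings and `"-"` /
#'   em-dash placeholders give 0.
#' @param field label used in parse-error messages.
#' @return numeric vector of seconds.
#' @export
parse_duration <- function(text, field = "duration") {
  vapply(as.character(text), function(x) {
    x <- trimws(x)
    if (is.na(x) || x == "" || x %in% c("-", "—")) return(0)
    m <- regmatches(x, regexec("^([0-9]+):([0-5]?[0-9])(?::([0-5]?[0-9]))?$", x))[[1]]
    if (length(m) == 0)
      stop(sprintf("malformed duration in '%s': '%s'", field, x), call. = FALSE)
    h <- as.numeric(m[2]); mi <- as.numeric(m[3])
    s <- if (m[4] == "") 0 else as.numeric(m[4])
    3600 * h + 60 * mi + s
  }, numeric(1), USE.NAMES = FALSE)
}

#' Format seconds as canonical H:MM:SS
#' @param seconds numeric vector.
#' @return character vector.
#' @export
format_duration <- function(seconds) {
  sprintf("%d:%02d:%02d", floor(seconds / 3600),
          floor((seconds %% 3600) / 60), round(seconds %% 60))
}

# euros -> integer cents; "—", "" and "<x" placeholders contribute 0 to sums
parse_euro_cents <- function(x) {
  vapply(as.character(x), function(v) {
    v <- gsub(",", "", trimws(v))
    if (is.na(v) || v == "" || v %in% c("-", "—") || startsWith(v, "<")) return(0L)
    as.integer(round(as.numeric(v) * 100))
  }, integer(1), USE.NAMES = FALSE)
}

#' Assemble a cost ledger from per-step figures
#'
#' @param steps data.frame with columns `step`, `material_per_sample`,
#'   `material_total`, `labour_per_sample`, `time_per_sample`, `time_total`,
#'   `total_cost`. Currency columns in whole currency units (numeric or
#'   character; `"—"`, `""` and `"<0.01"` count as 0); time columns as
#'   `H:MM:SS` strings or seconds.
#' @param n_samples number of samples the per-sample figures refer to.
#' @param labour_rate currency per hour (default 60); recorded, not used to
#'   re-derive the printed labour figures.
#' @param overheads named numeric vector of fixed costs added to the grand
#'   total only if they are not already carried as steps (default none).
#' @return object of class `cost_ledger`.
#' @export
cost_ledger <- function(steps, n_samples, labour_rate = 60,
                        overheads = numeric()) {
  need <- c("step", "material_per_sample", "material_total",
            "labour_per_sample", "time_per_sample", "time_total", "total_cost")
  miss <- setdiff(need, names(steps))
  if (length(miss)) stop("steps missing columns: ", paste(miss, collapse = ", "))
  stopifnot(n_samples >= 1)
  parse_time_col <- function(x, field)
    if (is.numeric(x)) x else parse_duration(x, field)
  ledger <- data.frame(
    step = as.character(steps$step),
    material_per_sample = parse_euro_cents(steps$material_per_sample),
    material_total = parse_euro_cents(steps$material_total),
    labour_per_sample = parse_euro_cents(steps$labour_per_sample),
    time_per_sample = parse_time_col(steps$time_per_sample, "time_per_sample"),
    time_total = parse_time_col(steps$time_total, "time_total"),
    total_cost = parse_euro_cents(steps$total_cost),
    stringsAsFactors = FALSE)
  structure(list(steps = ledger, n_samples = n_samples,
                 labour_rate = labour_rate,
                 overheads = as.numeric(overheads)),
            class = "cost_ledger")
}

#' Aggregate a cost ledger into workflow totals
#'
#' Column-wise sums over the steps (absent cells contribute 0) plus any fixed
#' overheads; the per-sample cost is per-sample material + per-sample labour,
#' rounded to the nearest whole currency unit.
#'
#' @param ledger a [cost_ledger()].
#' @return list with `material_per_sample`, `material_total`,
#'   `labour_per_sample`, `time_per_sample_s`, `total_time_s`, `grand_total`,
#'   `per_sample_cost`, `per_sample_cost_rounded` (currency values in whole
#'   units, exact at cent precision).
#' @export
aggregate_costs <- function(ledger) {
  stopifnot(inherits(ledger, "cost_ledger"))
  s <- ledger$steps
  cents <- function(x) sum(as.numeric(x)) / 100
  grand <- cents(s$total_cost) + sum(ledger$overheads)
  per_sample <- cents(s$material_per_sample) + cents(s$labour_per_sample)
  list(material_per_sample = cents(s$material_per_sample),
       material_total = cents(s$material_total),
       labour_per_sample = cents(s$labour_per_sample),
       time_per_sample_s = sum(s$time_per_sample),
       total_time_s = sum(s$time_total),
       grand_total = grand,
       per_sample_cost = per_sample,
       per_sample_cost_rounded = round(per_sample))
}

#' Read a per-step cost table (TSV)
#'
#' Expects tab-separated columns `step`, `material_per_sample`,
#' `material_total`, `labour_per_sample`, `time_per_sample`, `time_total`,
#' `total_cost`.
#'
#' @param path file path.
#' @return data.frame suitable for [cost_ledger()].
#' @export
read_cost_steps <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE)
}
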