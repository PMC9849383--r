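#' Read long-format performance records from delimited text
#'
#' One row per performance result: individual identifier, age in years,
#' and a lower-is-better points score. The delimiter is autodetected
#' from the file extension (`.tsv`/`.tab` means tab, anything else
#' comma). Rows whose age or score cannot be parsed as a finite number,
#' or whose score is not strictly positive, are dropped; the drop count
#' is reported via `message()` and attached as attribute `"n_dropped"`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named list mapping the canonical fields
#'   `id`, `age`, `score` (mandatory) and `season`, `discipline`, `sex`
#'   (optional) to column names in the file.
#' @return Data frame with columns `individual_id` (character, verbatim),
#'   `age`, `score`, plus any mapped optional columns.
#' @export
read_records <- function(path,
                         column_map = list(id = "id", age = "age",
                                           score = "points")) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", encoding = "UTF-8")
  for (field in c("id", "age", "score")) {
    col <- column_map[[field]]
    if (is.null(col) || !col %in% names(raw))
      stop("mandatory column missing from ", path, ": '",
           if (is.null(col)) field else col, "'")
  }
  age <- suppressWarnings(as.numeric(raw[[column_map$age]]))
  score <- suppressWarnings(as.numeric(raw[[column_map$score]]))
  keep <- is.finite(age) & is.finite(score) & score > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " record(s) dropped (unparseable or non-positive age/score)")
  out <- data.frame(individual_id = as.character(raw[[column_map$id]])[keep],
                    age = age[keep], score = score[keep],
                    stringsAsFactors = FALSE)
  for (field in c("season", "discipline", "sex")) {
    col <- column_map[[field]]
    if (!is.null(col) && col %in% names(raw)) out[[field]] <- raw[[col]][keep]
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Best performance per individual per age
#'
#' Counter-performances (atypically bad results) are neutralized by
#' training only on each individual's best (minimum-score) result per
#' age bin. Ages are binned to integer years by `floor()`; records
#' outside `age_bounds` (inclusive, applied to the binned age) are
#' dropped first. Ties are broken by first occurrence in the input.
#'
#' @param records Data frame with `individual_id`, `age`, `score`.
#' @param age_bounds Length-2 numeric, inclusive retention bounds on the
#'   binned age (default `c(10, 25)`).
#' @return Data frame with one row per (individual, age bin): columns of
#'   `records` plus integer `age_bin`; attribute `"n_in"` records the
#'   post-bounds input size.
#' @export
best_per_age <- function(records, age_bounds = c(10, 25)) {
  stopifnot(is.data.frame(records), nrow(records) > 0L,
            all(c("individual_id", "age", "score") %in% names(records)))
  bin <- floor(records$age)
  keep <- bin >= age_bounds[1L] & bin <= age_bounds[2L]
  records <- records[keep, , drop = FALSE]
  bin <- bin[keep]
  if (nrow(records) == 0L)
    stop("no records left within age bounds [", age_bounds[1L], ", ",
         age_bounds[2L], "]")
  key <- paste(records$individual_id, bin, sep = "\r")
  # stable min: order by score with original order as tiebreak, keep first per key
  ord <- order(key, records$score, seq_len(nrow(records)), method = "radix")
  first <- !duplicated(key[ord])
  out <- records[ord[first], , drop = FALSE]
  out$age_bin <- bin[ord[first]]
  out <- out[order(out$individual_id, out$age_bin, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_in") <- length(key)
  out
}

#' Write the standardized training table and its transform sidecar
#'
#' @param std_table Data frame from [standardize_records()].
#' @param spec The `"standardization"` object used.
#' @param path Output CSV path; the transform is written alongside as
#'   `<path>.json`.
#' @return Invisibly, the CSV path.
#' @export
write_training_table <- function(std_table, spec, path) {
  utils::write.csv(std_table, path, row.names = FALSE)
  jsonlite::write_json(unclass(spec), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a standardization sidecar written by [write_training_table()]
#' @param path Path to the JSON sidecar.
#' @return A `"standardization"` object.
#' @export
read_standardization <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  standardization(x$age_mean, x$age_sd, x$score_mean, x$score_sd,
                  x$positivity_shift)
}
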