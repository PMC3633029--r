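# File readers and writers: tab-separated tables (UTF-8, header row,
# '#' comment lines) and JSON reports.

#' Read observed section-classification data from a TSV file
#'
#' Expects a header row with columns `p`, `pure_A`, `pure_B`, `mixed` (one
#' data row); shares may be percentages (summing to ~100) or fractions
#' (summing to ~1). Lines starting with `#` are comments.
#'
#' @param path Path to the file.
#' @return An [observed_section_data()].
#' @export
read_observed_data <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  tab <- utils::read.delim(path, comment.char = "#", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("p", "pure_A", "pure_B", "mixed")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("malformed observed-data file ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) != 1L) {
    stop("observed-data file ", path, " must contain exactly one data row, found ",
         nrow(tab))
  }
  n_sections <- if ("n_sections" %in% names(tab)) tab$n_sections else NULL
  observed_section_data(tab$pure_A, tab$pure_B, tab$mixed, p = tab$p,
                        n_sections = n_sections)
}

#' Read a clone-abundance table
#'
#' Accepts either a TSV with header columns `clone_id`, `count` and an
#' optional `sample_id` (one sample per distinct `sample_id`; a single
#' unnamed sample when absent), or a bare whitespace-separated vector of
#' counts. Lines starting with `#` are comments. Zero or negative counts
#' are rejected with their row numbers.
#'
#' @param path Path to the file.
#' @return A named list of [abundance_sample()] objects.
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[!grepl("^\\s*#", first) & nzchar(trimws(first))]
  if (!length(first)) stop("abundance file ", path, " is empty")
  if (grepl("clone_id", first[1], fixed = TRUE)) {
    tab <- utils::read.delim(path, comment.char = "#", header = TRUE,
                             stringsAsFactors = FALSE)
    if (!all(c("clone_id", "count") %in% names(tab))) {
      stop("malformed abundance file ", path,
           ": need columns clone_id, count")
    }
    bad <- which(!is.finite(tab$count) | tab$count < 1 |
                   abs(tab$count - round(tab$count)) > 1e-8)
    if (length(bad)) {
      stop("abundance file ", path, ": invalid count in data row(s) ",
           paste(bad, collapse = ", "), " (counts must be positive integers)")
    }
    sid <- if ("sample_id" %in% names(tab)) tab$sample_id else "sample1"
    split_counts <- split(tab$count, sid)
    out <- lapply(names(split_counts), function(nm) {
      abundance_sample(split_counts[[nm]], name = nm)
    })
    stats::setNames(out, names(split_counts))
  } else {
    counts <- scan(path, what = numeric(), comment.char = "#", quiet = TRUE)
    if (any(counts < 1)) {
      stop("abundance file ", path, ": counts must be positive integers")
    }
    list(sample1 = abundance_sample(counts, name = "sample1"))
  }
}

# JSON writer used by all reports: bare numbers, full precision.
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
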