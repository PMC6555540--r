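#' Write a table as TSV with a commented metadata preamble
#'
#' Writes `# key: value` comment lines (seed, parameters, provenance)
#' followed by a header line and tab-separated rows.
#'
#' @param x data frame to write.
#' @param path output file path.
#' @param meta named list of metadata written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_sgr_tsv <- function(x, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")),
               con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_sgr_tsv()]
#'
#' @param path file path; `#` lines are treated as comments.
#' @return A data frame; the parsed preamble is attached as attribute
#'   `meta` (named character vector).
#' @export
read_sgr_tsv <- function(path) {
  lines <- readLines(path, n = 100L)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- NULL
  if (length(meta_lines) > 0L) {
    kv <- regmatches(meta_lines,
                     regexec("^#\\s*([^:]+):\\s*(.*)$", meta_lines))
    ok <- lengths(kv) == 3L
    meta <- stats::setNames(vapply(kv[ok], `[`, "", 3L),
                            vapply(kv[ok], `[`, "", 2L))
  }
  out <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  attr(out, "meta") <- meta
  out
}

#' Read a barcode table (deletion-collection screen read-out)
#'
#' Expects tab-separated columns `barcode_id`, `gene`, `chrom`, `pos`,
#' `intensity_query`, `intensity_control` (alias columns `query`/`control`
#' are accepted).
#'
#' @inheritParams read_sgr_tsv
#' @return A `barcode_table` data frame.
#' @export
read_barcode_table <- function(path) {
  x <- read_sgr_tsv(path)
  if ("query" %in% names(x) && !"intensity_query" %in% names(x))
    names(x)[names(x) == "query"] <- "intensity_query"
  if ("control" %in% names(x) && !"intensity_control" %in% names(x))
    names(x)[names(x) == "control"] <- "intensity_control"
  x <- validate_barcode_table(x)
  class(x) <- c("barcode_table", "data.frame")
  x
}

#' Write locus calls as a BED-like TSV
#'
#' One row per call: `chrom`, `peak_start`, `peak_end` (peak position
#' +/- half the mean window span on that chromosome), `name` (top
#' candidate gene), `score`, `p_value`.
#'
#' @param calls a `locus_calls` data frame (see [call_loci()]).
#' @param profile the `linkage_profile` the calls came from (used for the
#'   window span).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_locus_bed <- function(calls, profile, path) {
  half_span <- vapply(seq_len(nrow(calls)), function(i) {
    ctr <- profile$center[profile$chrom == calls$chrom[i]]
    if (length(ctr) > 1) stats::median(diff(ctr)) * attr(profile, "W") / 2
    else 0
  }, numeric(1))
  bed <- data.frame(chrom = calls$chrom,
                    peak_start = pmax(0, round(calls$peak_pos - half_span)),
                    peak_end = round(calls$peak_pos + half_span),
                    name = sub(",.*", "", calls$candidate_genes),
                    score = calls$score, p_value = calls$p_value)
  write_sgr_tsv(bed, path,
                meta = list(null_model = attr(calls, "null_model"),
                            n_perm = attr(calls, "n_perm"),
                            map_function = "haldane"))
}
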