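## TSV input/output. All files carry comment headers with a format tag and
## the full parameterization, so a result can be traced back to its run.

tsv_header <- function(kind, params = list()) {
    pstr <- if (length(params))
        paste(names(params), unlist(params), sep = "=", collapse = " ")
    else ""
    c(sprintf("# mldtools %s format v1", kind),
      if (nzchar(pstr)) paste("#", pstr))
}

write_tsv_with_header <- function(df, path, kind, params = list()) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(tsv_header(kind, params), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write and read MLD tables
#'
#' A raw MLD is stored as a 2-column TSV (`r`, `count`); a log-binned MLD as
#' a 5-column TSV (`lo`, `hi`, `mean_r`, `count`, `density`); matches as a
#' 3-column TSV (`pos_a`, `pos_b`, `length`). Comment lines starting with
#' `#` carry the format tag and run parameters.
#'
#' @param mld an [mld_histogram()] object.
#' @param path file path.
#' @param params named list recorded in the comment header.
#' @export
write_mld <- function(mld, path, params = list()) {
    write_tsv_with_header(mld$counts, path, "mld", params)
}

#' @rdname write_mld
#' @export
read_mld <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
    stopifnot(all(c("r", "count") %in% names(df)))
    structure(list(counts = df[, c("r", "count")],
                   total_matches = sum(df$count)),
              class = "mld")
}

#' @rdname write_mld
#' @param binned a [log_bin()] result.
#' @export
write_binned_mld <- function(binned, path, params = list()) {
    params$ratio <- attr(binned, "ratio")
    write_tsv_with_header(as.data.frame(binned), path, "mld-binned", params)
}

#' @rdname write_mld
#' @param matches a `mem_matches` data frame.
#' @export
write_matches <- function(matches, path, params = list()) {
    write_tsv_with_header(as.data.frame(matches), path, "matches", params)
}
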