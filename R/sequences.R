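#' Normalize a raw DNA character string
#'
#' Uppercases the input and maps every symbol outside `A`, `C`, `G`, `T` to
#' the ambiguity code `N`. `N` positions never take part in any exact match
#' (not even against another `N`). With `mask_lowercase = TRUE` lowercase
#' input symbols are masked to `N` as well, which reproduces the effect of
#' soft-masked repeat annotation; by default lowercase letters are simply
#' uppercased, the appropriate choice for hard-masked input.
#'
#' @param x character scalar of DNA bases.
#' @param mask_lowercase logical; mask lowercase symbols to `N`.
#' @return A character scalar over the alphabet `{A,C,G,T,N}`.
#' @examples
#' normalize_sequence("acgtACGT", mask_lowercase = TRUE)
#' normalize_sequence("ACRYT")
#' @export
normalize_sequence <- function(x, mask_lowercase = FALSE) {
    stopifnot(is.character(x), length(x) == 1L)
    ch <- strsplit(x, "", fixed = TRUE)[[1L]]
    if (mask_lowercase)
        ch[ch %in% c("a", "c", "g", "t", "n")] <- "N"
    ch <- toupper(ch)
    ch[!ch %in% c("A", "C", "G", "T")] <- "N"
    paste0(ch, collapse = "")
}

#' Read a FASTA file as a single analysis sequence
#'
#' Multi-record FASTA files are concatenated into one sequence with a single
#' `N` inserted between records, so that no exact match can span a record
#' boundary. This mirrors the construction of a "pseudogenome" from many
#' individual sequences.
#'
#' @param path path to a FASTA file.
#' @param mask_lowercase logical, passed to [normalize_sequence()].
#' @return A normalized character scalar; the attribute `"ids"` carries the
#'   record identifiers.
#' @export
read_fasta_sequence <- function(path, mask_lowercase = FALSE) {
    recs <- Biostrings::readBStringSet(path)   # preserves soft-masking case
    if (length(recs) == 0L) stop("no sequences in FASTA file: ", path)
    joined <- paste0(as.character(recs), collapse = "N")
    out <- normalize_sequence(joined, mask_lowercase = mask_lowercase)
    attr(out, "ids") <- names(recs)
    out
}

#' Generate a random iid DNA sequence
#'
#' Bases are drawn independently and uniformly from `{A,C,G,T}` (uniform
#' composition, chance-match probability p = 1/4).
#'
#' @param L sequence length in bp.
#' @return A character scalar of length `L`.
#' @export
random_genome <- function(L) {
    paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

## integer encoding used by the simulators: A,C,G,T -> 0..3
encode_bases <- function(x) {
    v <- match(strsplit(x, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T")) - 1L
    if (anyNA(v))
        stop("sequence contains non-ACGT symbols where none are allowed")
    v
}

decode_bases <- function(v) {
    paste0(c("A", "C", "G", "T")[v + 1L], collapse = "")
}
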