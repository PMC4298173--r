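## Maximal exact match (MEM) enumeration and MLD histograms.
##
## The engine builds a generalized suffix array over the concatenation of the
## input sequences with unique separator symbols; every N also receives a
## unique symbol, so ambiguous bases match nothing and no match spans an N.
## A MEM corresponds one-to-one to a pair of suffixes whose longest common
## prefix is at least minlen and whose preceding symbols differ (or hit a
## boundary): the LCP gives right-maximality, the preceding-symbol test
## left-maximality. All occurrences are reported, regardless of uniqueness.

## codes: ACGT -> 1..4, every other symbol -> unique code >= 5
mem_codes <- function(ch, next_code) {
    v <- match(ch, c("A", "C", "G", "T"))
    idx <- which(is.na(v))
    if (length(idx)) {
        v[idx] <- next_code + seq_along(idx) - 1L
        next_code <- next_code + length(idx)
    }
    list(codes = as.integer(v), next_code = next_code)
}

mem_matches_df <- function(raw) {
    out <- data.frame(pos_a = as.integer(raw$pos_a),
                      pos_b = as.integer(raw$pos_b),
                      length = as.integer(raw$length))
    class(out) <- c("mem_matches", "data.frame")
    out
}

#' Find maximal exact matches between two sequences
#'
#' Enumerates all maximal exact matches (MEMs) of length at least `minlen`
#' between `a` and `b`: identical substring pairs that cannot be extended on
#' either side without a mismatch, a sequence boundary, or an `N`. All
#' occurrences are reported (the equivalent of a MAXMATCH search), `N` never
#' matches anything, and matching is forward-strand only.
#'
#' @param a,b character scalars over `{A,C,G,T,N}` (see
#'   [normalize_sequence()]).
#' @param minlen minimum match length in bp (default 20).
#' @return A data frame of class `mem_matches` with columns `pos_a`, `pos_b`
#'   (0-based offsets) and `length` (bp).
#' @examples
#' find_mems("ACGNACG", "ACGTACG", minlen = 3)
#' @export
find_mems <- function(a, b, minlen = 20L) {
    stopifnot(minlen >= 1)
    ca <- strsplit(a, "", fixed = TRUE)[[1L]]
    cb <- strsplit(b, "", fixed = TRUE)[[1L]]
    if (length(ca) == 0L || length(cb) == 0L)
        return(mem_matches_df(list(pos_a = integer(), pos_b = integer(),
                                   length = integer())))
    ea <- mem_codes(ca, 5L)
    eb <- mem_codes(cb, ea$next_code + 1L)
    sep <- ea$next_code                       # unique separator symbol
    codes <- c(ea$codes, sep, eb$codes)
    owner <- c(rep(0L, length(ca)), -1L, rep(1L, length(cb)))
    raw <- .mem_enumerate(codes, owner, as.integer(minlen), 0L)
    raw$pos_b <- raw$pos_b - (length(ca) + 1L)   # to b coordinates
    mem_matches_df(raw)
}

#' Find maximal exact matches within one sequence (self-alignment)
#'
#' Enumerates all maximal exact matches between distinct locus pairs of a
#' single sequence. The trivial identity diagonal is excluded and each
#' unordered locus pair is reported once, with `pos_a < pos_b`.
#'
#' @inheritParams find_mems
#' @return A data frame of class `mem_matches` (see [find_mems()]).
#' @examples
#' find_self_mems("ACGTTTACGTTT", minlen = 4)
#' @export
find_self_mems <- function(a, minlen = 20L) {
    stopifnot(minlen >= 1)
    ca <- strsplit(a, "", fixed = TRUE)[[1L]]
    if (length(ca) < minlen)
        return(mem_matches_df(list(pos_a = integer(), pos_b = integer(),
                                   length = integer())))
    ea <- mem_codes(ca, 5L)
    raw <- .mem_enumerate(ea$codes, rep(0L, length(ca)),
                          as.integer(minlen), 1L)
    mem_matches_df(raw)
}

#' Build a match length distribution from a set of matches
#'
#' Counts matches per length: `counts[r]` is the number of maximal exact
#' matches of length exactly `r` bp.
#'
#' @param matches a `mem_matches` data frame, or any data frame with a
#'   `length` column, or a bare integer vector of match lengths.
#' @return An object of class `mld`: a list with `counts` (data frame with
#'   columns `r`, `count`) and `total_matches`.
#' @export
mld_histogram <- function(matches) {
    lens <- if (is.numeric(matches)) as.integer(matches) else
        as.integer(matches$length)
    tab <- table(lens)
    counts <- data.frame(r = as.integer(names(tab)),
                         count = as.integer(tab))
    counts <- counts[order(counts$r), , drop = FALSE]
    rownames(counts) <- NULL
    structure(list(counts = counts, total_matches = sum(counts$count)),
              class = "mld")
}

#' @export
print.mld <- function(x, ...) {
    cat("Match length distribution:", x$total_matches, "matches")
    if (nrow(x$counts))
        cat(", lengths", min(x$counts$r), "-", max(x$counts$r), "bp")
    cat("\n")
    invisible(x)
}

#' @export
as.data.frame.mld <- function(x, ...) x$counts

## merge several mld objects into one pooled histogram
pool_mlds <- function(mlds) {
    all <- do.call(rbind, lapply(mlds, function(m) m$counts))
    if (is.null(all) || nrow(all) == 0L)
        return(mld_histogram(integer()))
    agg <- stats::aggregate(count ~ r, data = all, FUN = sum)
    agg <- agg[order(agg$r), , drop = FALSE]
    rownames(agg) <- NULL
    structure(list(counts = agg, total_matches = sum(agg$count)),
              class = "mld")
}

#' Logarithmic binning of a match length distribution
#'
#' Rebins the raw per-length counts into contiguous geometric bins
#' (`hi = lo * ratio`) starting at the smallest observed length, and reports
#' the match density per unit length in each bin. Logarithmic binning reduces
#' the sampling noise in the sparse tail of the distribution. The total match
#' count is conserved: `sum(density * (hi - lo)) == total_matches`.
#'
#' Match lengths are integers, so bin edges are snapped to integers (each
#' bin advances by at least 1 bp); the bin width then equals the number of
#' distinct lengths it covers, and `mean_r` is the geometric mean of those
#' lengths. This keeps the per-bin density free of the coverage jitter a
#' real-valued grid would impose on integer data.
#'
#' @param mld an [mld_histogram()] object.
#' @param ratio geometric bin growth factor, strictly greater than 1
#'   (default 1.25).
#' @return A data frame of class `mld_binned` with columns `lo`, `hi`
#'   (integer edges, half-open bins), `mean_r`, `count` and `density`; the
#'   attribute `"ratio"` stores the growth factor.
#' @export
log_bin <- function(mld, ratio = 1.25) {
    if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 1)
        stop("`ratio` must be a single number > 1")
    counts <- mld$counts
    if (nrow(counts) == 0L) {
        out <- data.frame(lo = numeric(), hi = numeric(), mean_r = numeric(),
                          count = integer(), density = numeric())
        class(out) <- c("mld_binned", "data.frame")
        attr(out, "ratio") <- ratio
        return(out)
    }
    rmin <- min(counts$r)
    rmax <- max(counts$r)
    edges <- rmin
    x <- rmin
    while (edges[length(edges)] <= rmax) {
        x <- x * ratio
        edges <- c(edges, max(edges[length(edges)] + 1, round(x)))
    }
    nbin <- length(edges) - 1L
    bin <- findInterval(counts$r, edges, rightmost.closed = FALSE)
    cnt <- vapply(seq_len(nbin), function(k) sum(counts$count[bin == k]), 0)
    lo <- edges[-length(edges)]
    hi <- edges[-1]
    mean_r <- vapply(seq_len(nbin), function(k)
        exp(mean(log(seq(lo[k], hi[k] - 1L)))), numeric(1))
    out <- data.frame(lo = lo, hi = hi, mean_r = mean_r,
                      count = cnt, density = cnt / (hi - lo))
    class(out) <- c("mld_binned", "data.frame")
    attr(out, "ratio") <- ratio
    out
}

#' Filter out matches occurring more than once
#'
#' Removes every match whose sequence shares a continuous exact segment
#' longer than `share_threshold` bp with the sequence of any other match in
#' the set (an all-vs-all maximal-match search among the extracted match
#' strings). A match passing the filter is unique: its sequence occurs only
#' at its own pair of loci.
#'
#' @param matches a `mem_matches` data frame as produced by [find_mems()] or
#'   [find_self_mems()].
#' @param a the sequence the `pos_a` coordinates refer to (the match
#'   sequences are extracted from it).
#' @param share_threshold matches sharing a continuous segment of more than
#'   this many bp (i.e. `>= share_threshold + 1`) are non-unique; default 20.
#' @return The retained subset of `matches`.
#' @export
filter_unique <- function(matches, a, share_threshold = 20L) {
    n <- nrow(matches)
    if (n <= 1L) return(matches)
    ca <- strsplit(a, "", fixed = TRUE)[[1L]]
    codes <- integer(0)
    owner <- integer(0)
    next_code <- 5L
    for (i in seq_len(n)) {
        seg <- ca[(matches$pos_a[i] + 1L):(matches$pos_a[i] + matches$length[i])]
        enc <- mem_codes(seg, next_code)
        next_code <- enc$next_code + 1L      # +1 reserves a separator code
        codes <- c(codes, enc$codes, enc$next_code)
        owner <- c(owner, rep(i, length(seg)), -1L)
    }
    raw <- .mem_enumerate(codes, owner, as.integer(share_threshold) + 1L, 2L)
    bad <- unique(c(raw$owner_a, raw$owner_b))
    out <- matches[!seq_len(n) %in% bad, , drop = FALSE]
    rownames(out) <- NULL
    out
}
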