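## Tree-level samplers of pairwise evolutionary distances. These are fast
## oracles for the pair densities N(tau): they sample the same distances the
## sequence-level simulators realize, without paying the sequence cost.

#' Simulate a Yule tree and return all leaf-pair distances
#'
#' Event-driven simulation of a Yule branching process: starting from one
#' lineage, each of the `n` current lineages branches at rate `lamK`, so the
#' waiting time to the next branching is exponential with rate `n * lamK`.
#' After time `T` every unordered leaf pair contributes a distance
#' `tau = 2 mu (T - t_mrca)`, twice the time back to the pair's most recent
#' common ancestor scaled by the mutation rate.
#'
#' @param lamK branching (duplication) rate per lineage per time.
#' @param mu mutation rate per bp per time.
#' @param T total simulation time.
#' @param max_leaves guard on the exponentially growing leaf count.
#' @return An object of class `distance_samples`: list with `tau` (numeric
#'   vector of pairwise distances), `n_leaves`, `provenance = "yule"`.
#' @export
simulate_yule_tree <- function(lamK, mu, T, max_leaves = 100000L) {
    stopifnot(lamK > 0, mu > 0, T > 0)
    n <- 1L
    t <- rexp(1L, lamK)
    cap <- 16L
    mrca <- matrix(NA_real_, cap, cap)   # symmetric matrix of MRCA times
    while (t <= T) {
        j <- if (n == 1L) 1L else sample.int(n, 1L)
        n <- n + 1L
        if (n > max_leaves) stop("Yule tree exceeded max_leaves")
        if (n > cap) {
            cap <- cap * 2L
            m2 <- matrix(NA_real_, cap, cap)
            m2[seq_len(n - 1L), seq_len(n - 1L)] <-
                mrca[seq_len(n - 1L), seq_len(n - 1L)]
            mrca <- m2
        }
        if (n > 2L) {
            prev <- seq_len(n - 1L)[-j]
            mrca[n, prev] <- mrca[j, prev]
            mrca[prev, n] <- mrca[j, prev]
        }
        mrca[n, j] <- t
        mrca[j, n] <- t
        t <- t + rexp(1L, n * lamK)
    }
    tau <- if (n >= 2L) {
        m <- mrca[seq_len(n), seq_len(n)]
        2 * mu * (T - m[upper.tri(m)])
    } else numeric(0)
    structure(list(tau = as.numeric(tau), n_leaves = n, provenance = "yule"),
              class = "distance_samples")
}

#' Sample pairwise distances of a retroduplicated family
#'
#' Draws `n` pairs of retroduplication times `(T1, T2)` uniform on
#' `[0, T]^2` and returns the pairwise distance between the two copies,
#' `tau = mu (T - T1) + mu (T - T2) + a mu |T1 - T2|`: each copy diverges at
#' rate `mu` since its own birth, and the slowly evolving source gene
#' (rate `a * mu`) separates the two birth states.
#'
#' @param n number of pairs to sample.
#' @param mu copy mutation rate per bp per time.
#' @param a source-to-copy rate ratio in `[0, 1]`.
#' @param T family age.
#' @return A `distance_samples` object with `provenance = "retro"`; all
#'   sampled distances lie in `[0, 2 mu T]`.
#' @export
simulate_retro_distances <- function(n, mu, a, T) {
    stopifnot(n >= 1, mu > 0, T > 0, a >= 0, a <= 1)
    t1 <- runif(n, 0, T)
    t2 <- runif(n, 0, T)
    tau <- mu * (2 * T - t1 - t2) + a * mu * abs(t1 - t2)
    structure(list(tau = tau, n_leaves = NA_integer_, provenance = "retro"),
              class = "distance_samples")
}

#' @export
print.distance_samples <- function(x, ...) {
    cat("Pairwise distance samples (", x$provenance, "): ",
        length(x$tau), " pairs\n", sep = "")
    invisible(x)
}

#' Empirical pair density from distance samples
#'
#' Bins sampled pairwise distances into a histogram density: the returned
#' `pair_density` integrates to the number of pairs it was built from.
#'
#' @param samples a `distance_samples` object or a numeric vector of
#'   distances.
#' @param breaks number of equal-width bins, or a vector of bin edges.
#' @return A `pair_density` of form `"empirical-histogram"`.
#' @export
pair_density_histogram <- function(samples, breaks = 50L) {
    tau <- if (inherits(samples, "distance_samples")) samples$tau else samples
    stopifnot(length(tau) >= 1, all(tau >= 0))
    if (length(breaks) == 1L)
        breaks <- seq(0, max(tau) * (1 + 1e-9), length.out = breaks + 1L)
    h <- graphics::hist(tau, breaks = breaks, plot = FALSE)
    dens <- h$counts / diff(h$breaks)
    edges <- h$breaks
    f <- function(x) {
        k <- findInterval(x, edges, rightmost.closed = TRUE)
        out <- numeric(length(x))
        ok <- k >= 1 & k <= length(dens)
        out[ok] <- dens[k[ok]]
        out
    }
    pair_density(f, support = range(edges), form = "empirical-histogram")
}

#' Rank taxa by average distance to the others
#'
#' Orders the rows of a pairwise distance matrix by their mean distance to
#' all other taxa (diagonal excluded), ascending; ties are broken by label.
#' This ranking fixes the attachment order when building a pseudogene-family
#' tree with a constrained topology.
#'
#' @param d square symmetric numeric matrix with zero diagonal; row names
#'   are used as labels (defaulting to row indices).
#' @return Character vector of labels in ranked order, with the mean
#'   distances as the `"means"` attribute.
#' @export
rank_by_average_distance <- function(d) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d)) stop("distance matrix must be square")
    if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be 0")
    if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
    labels <- rownames(d)
    if (is.null(labels)) labels <- as.character(seq_len(nrow(d)))
    means <- rowSums(d) / (nrow(d) - 1)
    ord <- order(means, labels)
    structure(labels[ord], means = unname(means[ord]))
}

#' Read and write square distance matrices
#'
#' `read_distance_matrix()` reads either a labelled square TSV (header line
#' of labels, one labelled row per taxon) or a PHYLIP square distance matrix
#' (leading line holding the taxon count). `write_distance_matrix()` writes
#' the labelled TSV form.
#'
#' @param path file path.
#' @return A square numeric matrix with row and column labels.
#' @export
read_distance_matrix <- function(path) {
    first <- readLines(path, n = 1L)
    tok <- strsplit(trimws(first), "\\s+")[[1L]]
    if (length(tok) == 1L && !is.na(suppressWarnings(as.integer(tok)))) {
        ## PHYLIP square format
        n <- as.integer(tok)
        rows <- read.table(path, skip = 1L, header = FALSE,
                           stringsAsFactors = FALSE)
        if (nrow(rows) != n || ncol(rows) != n + 1L)
            stop("malformed PHYLIP distance matrix")
        m <- as.matrix(rows[, -1L, drop = FALSE])
        dimnames(m) <- list(rows[[1L]], rows[[1L]])
    } else {
        m <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                                  row.names = 1L, check.names = FALSE))
        colnames(m) <- rownames(m)
    }
    storage.mode(m) <- "double"
    m
}

#' @rdname read_distance_matrix
#' @param d square numeric matrix to write.
#' @export
write_distance_matrix <- function(d, path) {
    d <- as.matrix(d)
    labels <- rownames(d)
    if (is.null(labels)) labels <- as.character(seq_len(nrow(d)))
    df <- data.frame(labels, d, check.names = FALSE)
    colnames(df) <- c("id", labels)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
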