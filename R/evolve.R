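## Kinetic Monte Carlo genome evolution: point mutations (optionally with
## region-wise heterogeneous rates) plus segmental duplications in three
## modes, and the two-species divergence protocol. Event scheduling is exact
## Gillespie over the summed rates; every source of randomness goes through
## R's RNG, so seeded runs are bit-reproducible.

#' Evolve a sequence under mutation and random segmental duplication
#'
#' Runs exact Gillespie dynamics on a fixed-length sequence. Point mutations
#' replace one nucleotide by one of the other three, uniformly. A random
#' segmental duplication picks two uniform loci `c` and `v`, copies the
#' `K`-bp segment starting at `c` over the positions starting at `v`
#' (overwriting the pre-existing bases), so total length is conserved.
#' Region-wise heterogeneous mutation rates are supported via `rates`/`M`;
#' duplications always occur at the uniform rate `lambda` per bp.
#'
#' @param seq character scalar over `{A,C,G,T}`.
#' @param duration elapsed evolutionary time.
#' @param mu mutation rate per bp per time (used when `rates` is `NULL`).
#' @param lambda duplication rate per bp per time.
#' @param K duplicated segment length in bp; must satisfy `K <= nchar(seq)`.
#' @param rates optional vector of per-region mutation rates (one per `M`-bp
#'   region, `ceiling(L / M)` values); overrides `mu`.
#' @param M region length in bp for heterogeneous rates.
#' @return The evolved sequence (character scalar); attributes `n_mut` and
#'   `n_dup` carry the realized event counts.
#' @export
evolve_sequence <- function(seq, duration, mu = 1, lambda = 1e-3, K = 1000L,
                            rates = NULL, M = NULL) {
    stopifnot(duration >= 0, mu >= 0, lambda >= 0, K >= 1)
    v <- encode_bases(seq)
    L <- length(v)
    if (K > L) stop("duplication length K exceeds sequence length")
    if (is.null(rates)) {
        rates <- mu
        M <- L
    } else {
        if (is.null(M)) stop("`M` is required when `rates` is given")
        if (length(rates) != ceiling(L / M))
            stop("`rates` must hold one rate per ", M, "-bp region")
    }
    if (duration == 0) {
        out <- seq
        attr(out, "n_mut") <- 0
        attr(out, "n_dup") <- 0
        return(out)
    }
    res <- .evolve_seq(v, lambda, as.integer(K), as.numeric(rates),
                       as.integer(M), duration)
    out <- decode_bases(res$seq)
    attr(out, "n_mut") <- res$n_mut
    attr(out, "n_dup") <- res$n_dup
    out
}

family_result <- function(res, K, mode) {
    structure(list(seq = decode_bases(res$seq),
                   n_segments = res$n_segments,
                   K = as.integer(K),
                   times = res$times,
                   mode = mode),
              class = "segment_family")
}

#' @export
print.segment_family <- function(x, ...) {
    cat("Segment family (", x$mode, "): ", x$n_segments, " segments of ",
        x$K, " bp\n", sep = "")
    invisible(x)
}

#' Evolve a Yule family of duplicating segments
#'
#' Starts from one segment of length `K` (random iid unless `init` is
#' given). Every one of the `n` current segments duplicates at rate
#' `lambda * K`; a duplication copies a uniformly chosen segment to the end
#' of the sequence (position `n * K`) and increments `n`. All segments
#' mutate at rate `mu` per bp.
#'
#' @param duration elapsed time.
#' @param K segment length in bp.
#' @param lambda duplication rate per bp per time (per-segment rate is
#'   `lambda * K`).
#' @param mu mutation rate per bp per time.
#' @param init optional founder segment (character scalar of length `K`).
#' @return An object of class `segment_family`: list with `seq` (the
#'   `n * K`-bp concatenated family), `n_segments`, `K`, `times`
#'   (duplication event times) and `mode`.
#' @export
evolve_yule <- function(duration, K = 1000L, lambda = 1e-3, mu = 1,
                        init = NULL) {
    stopifnot(duration >= 0, K >= 1, lambda > 0, mu >= 0)
    if (is.null(init)) init <- random_genome(K)
    v <- encode_bases(init)
    if (length(v) != K) stop("`init` must have length K")
    res <- .evolve_family(v, lambda * K, mu, 1, duration, TRUE)
    family_result(res, K, "yule")
}

#' Evolve a retroduplicated pseudogene family
#'
#' Starts from one source gene of length `K`. Only the source duplicates
#' (rate `lambda * K`); each duplication appends a copy of the source's
#' current state at position `n * K`. Copies mutate at rate `mu` per bp; the
#' source mutates at the reduced rate `a * mu`, mimicking selective
#' constraint on the functional gene.
#'
#' @inheritParams evolve_yule
#' @param a source-to-copy mutation rate ratio in `[0, 1)`.
#' @return A `segment_family`; segment 1 is the source gene, segments
#'   2..n are the processed pseudogene copies (see [family_copies()]).
#' @export
evolve_retro <- function(duration, K = 1000L, lambda = 1e-3, mu = 1,
                         a = 0.1, init = NULL) {
    stopifnot(duration >= 0, K >= 1, lambda > 0, mu >= 0)
    if (a < 0 || a >= 1) stop("`a` must satisfy 0 <= a < 1")
    if (is.null(init)) init <- random_genome(K)
    v <- encode_bases(init)
    if (length(v) != K) stop("`init` must have length K")
    res <- .evolve_family(v, lambda * K, mu, a, duration, FALSE)
    family_result(res, K, "retro")
}

#' Extract the copy-only part of a segment family
#'
#' Drops the founder/source segment and returns the concatenation of the
#' copies (segments 2..n). For a retro family this is the "processed
#' pseudogenome" whose self-alignment exhibits the alpha = -4 tail; keeping
#' the slowly evolving source in the self-alignment would mix in
#' source-copy pairs whose pair density does not vanish at tau = 0.
#'
#' @param fam a `segment_family` object.
#' @return Character scalar of length `(n_segments - 1) * K` (empty string
#'   if no copies exist yet).
#' @export
family_copies <- function(fam) {
    stopifnot(inherits(fam, "segment_family"))
    if (fam$n_segments < 2L) return("")
    substr(fam$seq, fam$K + 1L, nchar(fam$seq))
}

#' Speciation followed by independent divergence
#'
#' Duplicates an ancestral sequence into two species A and B, draws a fresh
#' field of region-wise mutation rates for each (one Exponential(mean 1)
#' rate per `M`-bp region, independent between species), and evolves both
#' independently for time `t1` under those rates.
#'
#' Post-split segmental duplications default to off (`lambda = 0`): the
#' comparative power-law tail of this model is an orthologous-divergence
#' effect, and duplications at the stationary-state rate would both
#' overwrite conserved regions (suppressing surviving orthologous matches
#' by `exp(-2 lambda (r + K) t1)`) and overlay a steeper paralogous
#' component, neither of which belongs to the conserved-element mechanism
#' being modelled. Set `lambda > 0` to study that interplay. The ancestor
#' itself should be at stationarity under the full dynamics (see
#' [evolve_sequence()] and [simulate_mld_ensemble()]).
#'
#' @param ancestor character scalar over `{A,C,G,T}`.
#' @param t1 post-speciation divergence time.
#' @param lambda post-split duplication rate per bp per time (default 0).
#' @param K duplicated segment length in bp.
#' @param M heterogeneity region length in bp.
#' @param rate_mean mean of the exponential distribution of region rates.
#' @return List with elements `a`, `b` (evolved sequences), and `rates_a`,
#'   `rates_b` (the realized per-region rate fields).
#' @export
speciate_and_diverge <- function(ancestor, t1, lambda = 0, K = 1000L,
                                 M = 1000L, rate_mean = 1) {
    stopifnot(t1 >= 0)
    L <- nchar(ancestor)
    nreg <- ceiling(L / M)
    rates_a <- rexp(nreg, rate = 1 / rate_mean)
    rates_b <- rexp(nreg, rate = 1 / rate_mean)
    a <- evolve_sequence(ancestor, t1, lambda = lambda, K = K,
                         rates = rates_a, M = M)
    b <- evolve_sequence(ancestor, t1, lambda = lambda, K = K,
                         rates = rates_b, M = M)
    list(a = a, b = b, rates_a = rates_a, rates_b = rates_b)
}
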