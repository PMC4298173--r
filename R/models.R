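## Analytic MLD models and pair densities.
##
## The central object is the pair density N(tau): the number of pairs of
## homologous sequence segments separated by a (dimensionless) evolutionary
## distance tau. The expected MLD follows by integrating the stick-breaking
## kernel of a single diverged pair against N(tau); the small-tau behaviour
## of N(tau) sets the power-law exponent of the MLD tail: N ~ tau^beta gives
## m(r) ~ r^-(3+beta).

#' Expected MLD of iid random sequences
#'
#' Expected number of maximal exact matches of length `r` between two iid
#' random sequences of length `L` with chance-match probability `p` per bp
#' (p = 1/4 at uniform composition): a geometric distribution in `r`.
#' The `"half"` convention counts each unordered locus pair once,
#' `L^2 (1-p)^2 p^r / 2`, the natural convention for a self-alignment; the
#' `"full"` convention counts ordered pairs and is twice that, matching the
#' expectation of a comparative match search where every (locus in A, locus
#' in B) pair is reported.
#'
#' @param r match length in bp (vectorized).
#' @param L sequence length in bp.
#' @param p per-bp chance match probability, in (0, 1).
#' @param convention `"half"` (default) or `"full"`.
#' @return Expected match count, same length as `r`.
#' @export
iid_mld <- function(r, L, p = 0.25, convention = c("half", "full")) {
    convention <- match.arg(convention)
    stopifnot(all(r >= 1), p > 0, p < 1)
    v <- L^2 * 0.5 * (1 - p)^2 * p^r
    if (convention == "full") v <- 2 * v
    v
}

#' Expected number of iid matches longer than r
#'
#' Cumulative form of [iid_mld()]: the expected number of chance matches of
#' length strictly greater than `r`.
#'
#' @inheritParams iid_mld
#' @export
iid_mld_tail_count <- function(r, L, p = 0.25,
                               convention = c("half", "full")) {
    convention <- match.arg(convention)
    v <- L^2 * 0.5 * (1 - p) * p^(r + 1)
    if (convention == "full") v <- 2 * v
    v
}

#' Stick-breaking MLD of a single diverged duplicated pair
#'
#' Expected number of maximal exact matches of length `r` between two copies
#' of an initially identical segment of length `K` after the pair has
#' accumulated `tau` mutations per site along the path separating them:
#' `m(r, tau) = [2 tau + tau^2 (K - r)] exp(-tau r)`, valid for
#' `1 <= r < K`. Mutations break the initially fully matching "stick" into
#' exponentially distributed exact fragments; the bracket counts interior
#' fragments (both ends broken by a mutation) and the two boundary fragments.
#'
#' @param r match length in bp (vectorized), smaller than `K`.
#' @param tau pairwise evolutionary distance (expected mutations per site).
#' @param K initial segment length in bp.
#' @export
stick_mld <- function(r, tau, K) {
    stopifnot(tau >= 0, all(r >= 1))
    if (any(r >= K)) stop("stick_mld requires r < K")
    (2 * tau + tau^2 * (K - r)) * exp(-tau * r)
}

#' Construct a pair density object
#'
#' Wraps a density of segment pairs over evolutionary distance tau into the
#' `pair_density` class used by [mld_from_density()] and
#' [convolve_pair_density()]. The function is treated as zero outside
#' `support`.
#'
#' @param fun vectorized function of tau returning a non-negative density.
#' @param support numeric length-2 vector, the interval of tau on which the
#'   density lives (the upper bound may be `Inf`).
#' @param form descriptive label.
#' @return An object of class `pair_density`.
#' @export
pair_density <- function(fun, support, form = "user-function") {
    stopifnot(is.function(fun), length(support) == 2L,
              support[1] >= 0, support[2] > support[1])
    structure(list(fun = fun, support = as.numeric(support), form = form),
              class = "pair_density")
}

#' @export
print.pair_density <- function(x, ...) {
    cat("Pair density N(tau) [", x$form, "] on [",
        x$support[1], ", ", x$support[2], "]\n", sep = "")
    invisible(x)
}

## evaluate a pair density, clamped to its support
pd_eval <- function(pd, tau) {
    out <- numeric(length(tau))
    ok <- tau >= pd$support[1] & tau <= pd$support[2]
    if (any(ok)) out[ok] <- pd$fun(tau[ok])
    out
}

#' Pair density of a Yule family of segmental duplications
#'
#' A segment of length `K` and all of its descendants duplicate at rate
#' `lam` per bp (`lam * K` per segment) while mutating at rate `mu` per bp.
#' After time `T` the density of segment pairs separated by evolutionary
#' distance tau is `(lam K / (2 mu)) exp(lam K T) exp(lam K tau / (2 mu))`
#' for `0 <= tau <= 2 mu T` and zero otherwise. The density does not vanish
#' at tau = 0 (ongoing duplication keeps producing identical pairs), which
#' drives the alpha = -3 MLD tail.
#'
#' @param tau evolutionary distance (vectorized).
#' @param lam duplication rate per bp per time.
#' @param K duplicated segment length in bp.
#' @param mu mutation rate per bp per time.
#' @param T elapsed time since the family founder.
#' @return Density values; use [as_yule_density()] for the corresponding
#'   `pair_density` object.
#' @export
yule_pair_density <- function(tau, lam, K, mu, T) {
    stopifnot(lam > 0, K > 0, mu > 0, T > 0)
    ifelse(tau >= 0 & tau <= 2 * mu * T,
           lam * K / (2 * mu) * exp(lam * K * T) * exp(lam * K * tau / (2 * mu)),
           0)
}

#' @rdname yule_pair_density
#' @export
as_yule_density <- function(lam, K, mu, T) {
    pair_density(function(tau) yule_pair_density(tau, lam, K, mu, T),
                 support = c(0, 2 * mu * T), form = "analytic-yule")
}

#' Pair density of a retroduplicated pseudogene family
#'
#' A source gene of length `K` retroduplicates at rate `lam * K`; the copies
#' (processed pseudogenes) never duplicate and mutate at rate `mu` per bp
#' while the source mutates at the reduced rate `a * mu` (`0 <= a < 1`).
#' With the two retroduplication times uniform on `[0, T]`, the pairwise
#' distance between two copies is
#' `tau = mu (2T - T1 - T2) + a mu |T1 - T2|`, giving the continuous
#' piecewise-linear (triangular) density
#' \deqn{N(\tau) = \frac{(\lambda K T)^2}{2\mu T}\,
#'   \min\!\left(\frac{\tau/(\mu T)}{1+a},\ \frac{2-\tau/(\mu T)}{1-a}\right)}
#' on `[0, 2 mu T]`: it vanishes at tau = 0, rises linearly to its maximum at
#' `tau = (1 + a) mu T`, falls linearly to zero at `tau = 2 mu T`, and
#' integrates to the expected number of copy pairs `(lam K T)^2 / 2`. The
#' vanishing density at tau = 0 drives the alpha = -4 MLD tail.
#'
#' @inheritParams yule_pair_density
#' @param a source-to-copy mutation rate ratio, in `[0, 1)`.
#' @export
retro_pair_density <- function(tau, lam, K, mu, a, T) {
    stopifnot(lam > 0, K > 0, mu > 0, T > 0)
    if (a < 0 || a >= 1) stop("`a` must satisfy 0 <= a < 1")
    npairs <- (lam * K * T)^2 / 2
    s <- tau / (mu * T)
    shape <- pmin(s / (1 + a), (2 - s) / (1 - a))
    ifelse(tau >= 0 & tau <= 2 * mu * T,
           npairs / (mu * T) * pmax(shape, 0), 0)
}

#' @rdname retro_pair_density
#' @export
as_retro_density <- function(lam, K, mu, a, T) {
    pair_density(function(tau) retro_pair_density(tau, lam, K, mu, a, T),
                 support = c(0, 2 * mu * T), form = "analytic-retro")
}

#' Convolve two pair densities
#'
#' The comparative pair density between two species is the convolution of
#' the per-species densities of distances to the common ancestor:
#' `N(tau) = integral of NA(tau - s) NB(s) ds`. The convolution always
#' vanishes at tau = 0, which is why comparative MLD tails are steeper than
#' self-alignment tails.
#'
#' @param na,nb `pair_density` objects supported on finite intervals of
#'   tau >= 0.
#' @param n number of grid points for the numeric convolution.
#' @return A `pair_density` of form `"analytic-convolution"` supported on
#'   the sum of the two supports.
#' @export
convolve_pair_density <- function(na, nb, n = 4097L) {
    stopifnot(inherits(na, "pair_density"), inherits(nb, "pair_density"))
    hi <- na$support[2] + nb$support[2]
    if (!is.finite(hi)) stop("convolution requires finite supports")
    tau <- seq(0, hi, length.out = n)
    h <- tau[2] - tau[1]
    fa <- pd_eval(na, tau)
    fb <- pd_eval(nb, tau)
    ## trapezoid quadrature of the convolution integral on the shared grid
    conv <- stats::convolve(fa, rev(fb), type = "open")[seq_len(n)] * h
    conv <- conv - 0.5 * h * (fa[1] * fb + fb[1] * fa)
    conv[1] <- 0
    conv[conv < 0] <- 0
    f <- approxfun(tau, conv, yleft = 0, yright = 0)
    pair_density(f, support = c(0, hi), form = "analytic-convolution")
}

#' Expected MLD from an arbitrary pair density
#'
#' Integrates the stick-breaking kernel against a pair density:
#' `m(r) = integral of [2 tau + tau^2 (K - r)] exp(-tau r) N(tau) dtau`.
#' Adaptive quadrature; the integration is truncated where the kernel factor
#' `exp(-tau r)` falls below machine-negligible levels.
#'
#' @param r match lengths in bp (vectorized), `1 <= r < K`.
#' @param density a `pair_density` object, or a plain function of tau
#'   (then assumed supported on `[0, Inf)`).
#' @param K segment length in bp entering the stick-breaking kernel.
#' @param rel_tol relative integration tolerance.
#' @return Expected match counts `m(r)`.
#' @export
mld_from_density <- function(r, density, K, rel_tol = 1e-6) {
    if (is.function(density))
        density <- pair_density(density, c(0, Inf))
    stopifnot(inherits(density, "pair_density"))
    if (any(r < 1 | r >= K)) stop("mld_from_density requires 1 <= r < K")
    vapply(r, function(ri) {
        ## exp(-tau r) < 1e-13 beyond tau = 30/ri even against growing N
        upper <- min(density$support[2], 40 / ri)
        if (upper <= density$support[1]) return(0)
        f <- function(tau)
            (2 * tau + tau^2 * (K - ri)) * exp(-tau * ri) * pd_eval(density, tau)
        out <- integrate(f, lower = density$support[1], upper = upper,
                         rel.tol = rel_tol, subdivisions = 500L,
                         stop.on.error = TRUE)
        out$value
    }, numeric(1))
}

#' Closed-form MLD tails of the duplication models
#'
#' Closed forms for the power-law tails of the expected MLD:
#' * `yule_mld_tail()`: a Yule family of segmental duplications,
#'   `m(r) = lam K^2 exp(lam K T) / (mu r^3)`, valid for
#'   `lam K / (2 mu) << r < K`;
#' * `random_dup_mld_tail()`: random segmental duplications anywhere in a
#'   genome of length `L`, `m(r) = A L / r^3` with `A = lam K / mu`;
#' * `retro_mld_tail()`: a retroduplicated pseudogene family,
#'   `m(r) = 3 K^3 lam^2 / ((1 + a) mu^2 r^4)` for match lengths well below `K`;
#' * `comparative_mld_tail()`: two diverged species whose comparative pair
#'   density rises linearly from zero with slope `dN0 = N'(0)`,
#'   `m(r) = N'(0) (6 K - 2 r) / r^4`.
#'
#' @inheritParams retro_pair_density
#' @param r match length in bp (vectorized).
#' @name mld_tails
NULL

#' @rdname mld_tails
#' @export
yule_mld_tail <- function(r, lam, K, mu, T) {
    exp(log(lam) + 2 * log(K) + lam * K * T - log(mu) - 3 * log(r))
}

#' @rdname mld_tails
#' @param L genome length in bp.
#' @export
random_dup_mld_tail <- function(r, lam, K, mu, L) {
    (lam * K / mu) * L / r^3
}

#' @rdname mld_tails
#' @export
retro_mld_tail <- function(r, lam, K, mu, a) {
    if (a < 0 || a >= 1) stop("`a` must satisfy 0 <= a < 1")
    3 * K^3 * lam^2 / ((1 + a) * mu^2) / r^4
}

#' @rdname mld_tails
#' @param dN0 slope of the comparative pair density at tau = 0, `N'(0)`.
#' @export
comparative_mld_tail <- function(r, dN0, K) {
    dN0 * (6 * K - 2 * r) / r^4
}

#' Longest expected exact match under neutral duplication
#'
#' The longest match expected from random segmental duplication in a genome
#' of length `L` with dimensionless duplication prefactor `A = lam K / mu`:
#' `rmax = (A L)^(1/3)`, capped at the duplication length `K`.
#'
#' @param A dimensionless prefactor `lam K / mu`.
#' @param L genome length in bp.
#' @param K duplication segment length in bp (default `Inf`, i.e. no cap).
#' @export
expected_rmax <- function(A, L, K = Inf) {
    stopifnot(A >= 0, L >= 0, K > 0)
    pmin((A * L)^(1 / 3), K)
}

#' MLD tail exponent implied by the small-tau behaviour of N(tau)
#'
#' If the pair density scales as `tau^beta` for small tau, the MLD tail is a
#' power law with exponent `alpha = -(3 + beta)`: beta = 0 (ongoing
#' duplication) gives -3, beta = 1 (comparative alignments, pseudogene
#' families) gives -4, beta = 2 (vanishing first derivative) gives -5.
#'
#' @param beta small-tau scaling exponent of the pair density, `beta >= 0`.
#' @export
exponent_from_beta <- function(beta) {
    stopifnot(all(beta >= 0))
    -(3 + beta)
}
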