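## Tail definition and power-law exponent estimation on log-binned MLDs.

#' First match length of the MLD tail
#'
#' The tail of an MLD consists of match lengths not expected in iid random
#' sequences. This returns the smallest `r` at which the expected iid match
#' count (see [iid_mld()]) drops below 0.5; for Gbp-scale genomes at
#' p = 1/4 this lands near 30 bp, just past the classical ~25 bp rule of
#' thumb.
#'
#' @param L_a,L_b lengths of the two aligned sequences in bp (equal for a
#'   self-alignment).
#' @param p per-bp chance match probability.
#' @param convention prefactor convention, see [iid_mld()].
#' @param min_r smallest admissible value (returned when `p` is 0 or the
#'   expectation is below 0.5 everywhere).
#' @return Integer match length in bp.
#' @export
tail_start <- function(L_a, L_b = L_a, p = 0.25,
                       convention = c("half", "full"), min_r = 1L) {
    convention <- match.arg(convention)
    stopifnot(L_a >= 1, L_b >= 1, p >= 0, p < 1)
    if (p == 0) return(as.integer(min_r))
    pref <- L_a * L_b * 0.5 * (1 - p)^2
    if (convention == "full") pref <- 2 * pref
    if (pref < 0.5) return(as.integer(min_r))
    ## smallest r with pref * p^r < 0.5
    r <- ceiling(log(0.5 / pref) / log(p) + 1e-12)
    as.integer(max(min_r, r))
}

#' Fit the power-law exponent of an MLD tail
#'
#' Weighted least-squares fit of `log(density)` against `log(mean_r)` over
#' the occupied logarithmic bins in `[r_lo, r_hi]`, with the per-bin match
#' counts as weights (the variance of the log of a Poisson count scales as
#' 1 / count). The slope is the tail exponent alpha of `m(r) ~ r^alpha`.
#'
#' `fit_mld_tail()` is a convenience wrapper that bins a raw MLD first.
#'
#' @param binned a [log_bin()] result.
#' @param r_lo lower end of the fit range in bp (default: smallest occupied
#'   bin).
#' @param r_hi upper end of the fit range in bp; the default keeps bins up
#'   to the largest one holding at least `min_tip_count` matches, which
#'   suppresses noise at the very tip of the distribution.
#' @param min_tip_count occupancy required of the last fitted bin.
#' @return An object of class `mld_tail_fit` with components `exponent`,
#'   `stderr`, `r_lo`, `r_hi`, `n_tail` (matches in the fitted range),
#'   `method`, `bins` (the fitted bins) and `fit` (the underlying `lm`).
#' @export
fit_tail_exponent <- function(binned, r_lo = NULL, r_hi = NULL,
                              min_tip_count = 5L) {
    stopifnot(inherits(binned, "mld_binned") || is.data.frame(binned))
    occ <- binned[binned$count > 0, , drop = FALSE]
    if (is.null(r_lo)) r_lo <- if (nrow(occ)) min(occ$mean_r) else 1
    if (is.null(r_hi)) {
        heavy <- occ$mean_r[occ$count >= min_tip_count]
        r_hi <- if (length(heavy)) max(heavy) else -Inf
    }
    if (r_lo >= r_hi)
        stop(insufficient_data_error(
            "fit range is empty; too few matches beyond r_lo"))
    use <- occ[occ$mean_r >= r_lo & occ$mean_r <= r_hi, , drop = FALSE]
    if (nrow(use) < 4L)
        stop(insufficient_data_error(sprintf(
            "only %d occupied bins in [%.4g, %.4g]; need at least 4",
            nrow(use), r_lo, r_hi)))
    fit <- lm(log(density) ~ log(mean_r), data = use, weights = use$count)
    sm <- summary(fit)$coefficients
    structure(list(exponent = unname(coef(fit)[2L]),
                   stderr = unname(sm[2L, 2L]),
                   r_lo = r_lo, r_hi = r_hi,
                   n_tail = sum(use$count),
                   method = "wls-logbin",
                   bins = use, fit = fit),
              class = "mld_tail_fit")
}

#' @rdname fit_tail_exponent
#' @param mld an [mld_histogram()] object.
#' @param ratio logarithmic binning ratio, see [log_bin()].
#' @export
fit_mld_tail <- function(mld, r_lo = NULL, r_hi = NULL, ratio = 1.25,
                         min_tip_count = 5L) {
    fit_tail_exponent(log_bin(mld, ratio), r_lo = r_lo, r_hi = r_hi,
                      min_tip_count = min_tip_count)
}

insufficient_data_error <- function(msg) {
    errorCondition(msg, class = c("mld_insufficient_data", "error"))
}

#' @export
print.mld_tail_fit <- function(x, digits = 3, ...) {
    cat("MLD tail exponent fit (", x$method, ")\n", sep = "")
    cat(sprintf("  alpha = %.*f (se %.*f), range %.4g - %.4g bp, %d matches\n",
                digits, x$exponent, digits, x$stderr, x$r_lo, x$r_hi,
                x$n_tail))
    invisible(x)
}

#' @export
summary.mld_tail_fit <- function(object, ...) {
    print(object)
    cat("  occupied bins used:", nrow(object$bins), "\n")
    invisible(object)
}

#' @export
coef.mld_tail_fit <- function(object, ...) {
    c(alpha = object$exponent, log_intercept = unname(coef(object$fit)[1L]))
}

#' @export
predict.mld_tail_fit <- function(object, r, ...) {
    cf <- coef(object$fit)
    exp(cf[[1L]] + cf[[2L]] * log(r))
}

#' @export
plot.mld_tail_fit <- function(x, ...) {
    plot(x$bins$mean_r, x$bins$density, log = "xy",
         xlab = "match length r (bp)", ylab = "match density m(r)",
         main = sprintf("MLD tail, alpha = %.2f", x$exponent), ...)
    rr <- range(x$bins$mean_r)
    rs <- exp(seq(log(rr[1]), log(rr[2]), length.out = 50))
    lines(rs, predict(x, rs), lty = 2)
    invisible(x)
}
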