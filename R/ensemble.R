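## Ensemble protocol: pool the MLDs of many independent replicate
## simulations, mirroring how simulated MLDs are aggregated over thousands
## of sequences before the tail is examined.

#' Simulate an ensemble of genomes and pool their MLDs
#'
#' Runs `reps` independent replicates of one of the evolutionary scenarios
#' and pools the per-replicate MLDs into one histogram:
#'
#' * `"random-dup"`: an iid genome of length `L` is evolved to stationarity
#'   (`t_burnin` expected substitutions per site) under mutation and random
#'   segmental duplication; the self-alignment MLD is computed. Expected
#'   tail: `alpha = -3`.
#' * `"yule"`: a Yule segment family is grown for `duration`; the
#'   self-alignment MLD of the family sequence is computed. Expected tail:
#'   `alpha = -3`.
#' * `"retro"`: a retro family is grown for `duration`; the self-alignment
#'   MLD of the copy-only "pseudogenome" ([family_copies()]) is computed.
#'   Expected tail: `alpha = -4`.
#' * `"diverge"`: an ancestor with its own Exponential(mean 1) region-rate
#'   field is evolved to stationarity (mutations plus duplications),
#'   speciates, and the two descendants diverge for `t1` with fresh
#'   independent rate fields and post-split duplication rate `lambda_post`
#'   (default 0, see [speciate_and_diverge()]); the comparative MLD is
#'   computed. Expected tail for `t1 >~ 2`: `alpha = -4`; for small `t1`
#'   the tail is exponential.
#'
#' @param mode one of `"random-dup"`, `"yule"`, `"retro"`, `"diverge"`.
#' @param reps number of independent replicates.
#' @param L genome length in bp (modes `"random-dup"` and `"diverge"`).
#' @param mu mutation rate per bp per time.
#' @param lambda duplication rate per bp per time.
#' @param K duplication length in bp.
#' @param M heterogeneity region length in bp (mode `"diverge"`).
#' @param t1 post-speciation divergence time (mode `"diverge"`).
#' @param lambda_post post-split duplication rate (mode `"diverge"`).
#' @param duration family growth time (modes `"yule"` and `"retro"`).
#' @param a source-to-copy rate ratio (mode `"retro"`).
#' @param t_burnin equilibration time in expected substitutions per site.
#' @param minlen minimum match length in bp.
#' @return A pooled [mld_histogram()] object; the attribute `"config"`
#'   records the full parameterization.
#' @export
simulate_mld_ensemble <- function(mode = c("random-dup", "yule", "retro",
                                           "diverge"),
                                  reps, L = 1e5, mu = 1, lambda = 1e-3,
                                  K = 1000L, M = 1000L, t1 = 2,
                                  lambda_post = 0, duration = 2, a = 0.1,
                                  t_burnin = 5, minlen = 20L) {
    mode <- match.arg(mode)
    mlds <- vector("list", reps)
    for (i in seq_len(reps)) {
        mlds[[i]] <- switch(mode,
            "random-dup" = {
                g <- evolve_sequence(random_genome(L), t_burnin, mu = mu,
                                     lambda = lambda, K = K)
                mld_histogram(find_self_mems(g, minlen))
            },
            "yule" = {
                fam <- evolve_yule(duration, K = K, lambda = lambda, mu = mu)
                mld_histogram(find_self_mems(fam$seq, minlen))
            },
            "retro" = {
                fam <- evolve_retro(duration, K = K, lambda = lambda,
                                    mu = mu, a = a)
                copies <- family_copies(fam)
                if (nchar(copies) < minlen) mld_histogram(integer()) else
                    mld_histogram(find_self_mems(copies, minlen))
            },
            "diverge" = {
                nreg <- ceiling(L / M)
                anc <- evolve_sequence(random_genome(L), t_burnin,
                                       lambda = lambda, K = K,
                                       rates = rexp(nreg), M = M)
                sp <- speciate_and_diverge(as.character(anc), t1,
                                           lambda = lambda_post, K = K,
                                           M = M)
                mld_histogram(find_mems(sp$a, sp$b, minlen))
            })
    }
    out <- pool_mlds(mlds)
    attr(out, "config") <- list(mode = mode, reps = reps, L = L, mu = mu,
                                lambda = lambda, K = K, M = M, t1 = t1,
                                lambda_post = lambda_post,
                                duration = duration, a = a,
                                t_burnin = t_burnin, minlen = minlen)
    out
}
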