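test_that("iid chance-match law reproduces worked values", {
    ## frozen reference values from an independent arbitrary-precision
    ## evaluation of L^2/2 (1-p)^2 p^r at L=1e9, p=1/4, r=27
    expect_equal(iid_mld(27, 1e9, 0.25, "half"), 15.61251128379126,
                 tolerance = 1e-12)
    expect_equal(iid_mld(27, 1e9, 0.25, "full"), 31.22502256758253,
                 tolerance = 1e-12)
    ## fewer than one chance match longer than 30 bp in a 1 Gbp genome
    expect_lt(iid_mld_tail_count(30, 1e9, 0.25, "half"), 1)
    expect_lt(iid_mld_tail_count(30, 1e9, 0.25, "full"), 1)
    expect_equal(iid_mld_tail_count(30, 1e9, 0.25, "half"),
                 0.08131516293641283, tolerance = 1e-12)
    ## cumulative form consistent with direct summation
    direct <- sum(iid_mld(31:200, 1e9, 0.25))
    expect_equal(iid_mld_tail_count(30, 1e9, 0.25), direct,
                 tolerance = 1e-10)
    ## vanishing limit for small p (fixed L)
    expect_lt(iid_mld(1, 1e3, 1e-12), 1e-5)
    expect_lt(iid_mld(1, 1e3, 1e-15) / iid_mld(1, 1e3, 1e-12), 1e-2)
})

test_that("stick-breaking MLD matches closed form and worked value", {
    ## at 25% divergence, one expected match of 72 bp between Gbp genomes
    v <- stick_mld(72, tau = 0.25, K = 1e9)
    expect_equal(v, 0.9518736731246203, tolerance = 1e-12)
    expect_equal(round(v), 1)
    ## tau = 0: no broken fragments reported by the tail formula
    expect_equal(stick_mld(10, 0, 1e4), 0)
    ## domain error
    expect_error(stick_mld(10, 0.1, 10), "r < K")
})

test_that("stick-breaking formula agrees with Monte-Carlo fragmentation", {
    set.seed(101)
    K <- 1e4; tau <- 0.05; n_trials <- 5000L
    frags <- oracle_stick_fragments(n_trials, K, tau)
    edges <- seq(20, 200, by = 20)
    lo <- edges[-length(edges)]; hi <- edges[-1]
    obs <- vapply(seq_along(lo), function(k)
        sum(frags >= lo[k] & frags < hi[k]), 0)
    exp_bin <- n_trials * oracle_stick_expected(lo, hi, K, tau)
    ## same kernel as stick_mld: cross-check the two expressions first
    expect_equal(oracle_stick_expected(50, 51, K, tau),
                 integrate(function(r) stick_mld(r, tau, K), 50, 51)$value,
                 tolerance = 1e-8)
    expect_true(all(abs(obs - exp_bin) < 3 * sqrt(exp_bin)),
                label = paste("stick-breaking bins within 3 sigma:",
                              paste(round((obs - exp_bin) / sqrt(exp_bin), 2),
                                    collapse = " ")))
})

test_that("Yule pair density has the stated support and values", {
    lam <- 1e-3; K <- 1e3; mu <- 1; T <- 5
    expect_equal(yule_pair_density(0, lam, K, mu, T),
                 lam * K / (2 * mu) * exp(lam * K * T))
    expect_equal(yule_pair_density(2 * mu * T + 1e-9, lam, K, mu, T), 0)
    expect_equal(yule_pair_density(-1, lam, K, mu, T), 0)
    ## density integrates to the expected number of leaf pairs n(n-1)
    pd <- as_yule_density(lam, K, mu, T)
    total <- integrate(function(x) pd_eval_test(pd, x), 0, 2 * mu * T,
                       rel.tol = 1e-10)$value
    g <- exp(lam * K * T)
    expect_equal(total, g * (g - 1), tolerance = 1e-6)
})

test_that("retro pair density is triangular with the stated anchors", {
    lam <- 1e-3; K <- 1e3; mu <- 1; a <- 0.1; T <- 1
    expect_equal(retro_pair_density(0, lam, K, mu, a, T), 0)
    expect_equal(retro_pair_density(2 * mu * T, lam, K, mu, a, T), 0)
    expect_equal(retro_pair_density(2 * mu * T + 0.01, lam, K, mu, a, T), 0)
    ## maximum at (1+a) mu T
    taus <- seq(0, 2 * mu * T, length.out = 20001)
    dens <- retro_pair_density(taus, lam, K, mu, a, T)
    expect_equal(taus[which.max(dens)], (1 + a) * mu * T, tolerance = 1e-3)
    ## integral equals expected number of copy pairs (lam K T)^2 / 2
    total <- integrate(function(x) retro_pair_density(x, lam, K, mu, a, T),
                       0, 2 * mu * T, rel.tol = 1e-10)$value
    expect_equal(total, (lam * K * T)^2 / 2, tolerance = 1e-6)
    expect_error(retro_pair_density(0.1, lam, K, mu, a = 1, T), "a")
})

test_that("retro pair density matches direct sampling of the pair distance", {
    set.seed(77)
    mu <- 1; a <- 0.1; T <- 1; n <- 2e5
    t1 <- runif(n, 0, T); t2 <- runif(n, 0, T)
    tau <- mu * (2 * T - t1 - t2) + a * mu * abs(t1 - t2)
    edges <- seq(0, 2 * mu * T, length.out = 21)
    obs <- as.numeric(table(cut(tau, edges)))
    ## analytic probability per bin: density / total pair count
    lam <- 1e-3; K <- 1e3
    total <- (lam * K * T)^2 / 2
    p_bin <- vapply(seq_len(length(edges) - 1L), function(k)
        integrate(function(x) retro_pair_density(x, lam, K, mu, a, T) / total,
                  edges[k], edges[k + 1L], rel.tol = 1e-9)$value, numeric(1))
    exp_bin <- n * p_bin
    expect_true(all(abs(obs - exp_bin) < 3 * sqrt(exp_bin) + 3),
                label = paste("retro density bins within 3 sigma:",
                              paste(round((obs - exp_bin) / sqrt(exp_bin), 2),
                                    collapse = " ")))
})

test_that("convolution of pair densities vanishes at zero and is exact on knowns", {
    ## uniform * uniform on [0,1] -> triangle peaking at 1
    u <- pair_density(function(x) rep(1, length(x)), c(0, 1))
    tri <- convolve_pair_density(u, u)
    expect_equal(pd_eval_test(tri, 0), 0)
    expect_equal(pd_eval_test(tri, 1), 1, tolerance = 1e-2)
    expect_equal(pd_eval_test(tri, 0.5), 0.5, tolerance = 1e-2)
    expect_equal(pd_eval_test(tri, 1.5), 0.5, tolerance = 1e-2)
    ## exp(-x) * exp(-2x): closed form exp(-tau)(1 - exp(-tau))
    e1 <- pair_density(function(x) exp(-x), c(0, 30))
    e2 <- pair_density(function(x) 2 * exp(-2 * x), c(0, 30))
    cv <- convolve_pair_density(e1, e2, n = 8193L)
    xs <- c(0.25, 0.5, 1, 2, 4)
    expect_equal(pd_eval_test(cv, xs), 2 * exp(-xs) * (1 - exp(-xs)),
                 tolerance = 5e-3)
})

test_that("numeric MLD integration reproduces the three exponent regimes", {
    K <- 1e6
    rs <- exp(seq(log(100), log(10000), length.out = 41))
    for (beta in 0:2) {
        nd <- pair_density(function(tau) tau^beta, c(0, 1))
        mr <- mld_from_density(rs, nd, K)
        slope <- unname(coef(lm(log(mr) ~ log(rs)))[2])
        expect_lt(abs(slope - (-(3 + beta))), 0.02,
                  label = sprintf("beta=%d slope=%.4f", beta, slope))
    }
    expect_error(mld_from_density(10, function(x) x, K = 5), "r < K")
})

test_that("closed-form tails agree with numeric integration within 5%", {
    mu <- 1
    ## Yule: lam K/(2 mu) << r < K
    lam <- 1e-3; K <- 1e3; T <- 3
    rs <- c(50, 100, 200, 400)
    num <- mld_from_density(rs, as_yule_density(lam, K, mu, T), K)
    expect_true(all(abs(num / yule_mld_tail(rs, lam, K, mu, T) - 1) < 0.05))
    ## random duplication: constant N(tau) = lam L / (2 mu) gives A L / r^3
    L <- 1e9
    ndc <- pair_density(function(x) rep(lam * L / (2 * mu), length(x)),
                        c(0, 50))
    num <- mld_from_density(rs, ndc, K)
    expect_true(all(abs(num / random_dup_mld_tail(rs, lam, K, mu, L) - 1)
                    < 0.05))
    ## retro: r << K
    a <- 0.1; T <- 1
    rs2 <- c(30, 50, 80)
    num <- mld_from_density(rs2, as_retro_density(lam, K, mu, a, T), K)
    expect_true(all(abs(num / retro_mld_tail(rs2, lam, K, mu, a) - 1) < 0.05))
    ## comparative: N = N'(0) tau integrates exactly to N'(0)(6K-2r)/r^4
    dN0 <- 2.5
    ndl <- pair_density(function(x) dN0 * x, c(0, 50))
    num <- mld_from_density(rs2, ndl, K)
    expect_true(all(abs(num / comparative_mld_tail(rs2, dN0, K) - 1) < 1e-4))
})

test_that("closed-form tails obey their scaling identities", {
    lam <- 1e-3; K <- 1e3; mu <- 1; T <- 3
    ## frozen value from independent arbitrary-precision evaluation
    expect_equal(yule_mld_tail(100, lam, K, mu, T), 0.020085536923187668,
                 tolerance = 1e-12)
    expect_equal(yule_mld_tail(200, lam, K, mu, T) /
                 yule_mld_tail(100, lam, K, mu, T), 1 / 8, tolerance = 1e-12)
    expect_equal(retro_mld_tail(200, lam, K, mu, 0.1) /
                 retro_mld_tail(100, lam, K, mu, 0.1), 1 / 16,
                 tolerance = 1e-12)
    ## doubling genome length doubles the random-duplication count
    expect_equal(random_dup_mld_tail(100, lam, K, mu, 2e9),
                 2 * random_dup_mld_tail(100, lam, K, mu, 1e9))
    ## slower source gene (a -> 1) halves the retro prefactor vs a = 0
    expect_equal(retro_mld_tail(100, lam, K, mu, 0.999999) /
                 retro_mld_tail(100, lam, K, mu, 0), 0.5, tolerance = 1e-5)
    ## comparative tail vanishes at r = 3K
    expect_equal(comparative_mld_tail(3 * K, 1, K), 0)
})

test_that("expected longest match follows the cube-root law with a cap", {
    expect_equal(expected_rmax(1, 1e9, 1e4), 1000)
    expect_equal(expected_rmax(0.1, 1e9, 1e4), 464.1588833612779,
                 tolerance = 1e-12)
    expect_equal(round(expected_rmax(0.1, 1e9, 1e4), -2), 500)
    expect_equal(expected_rmax(1, 1e9, 500), 500)   # capped at K
    ## monotone in A and L
    expect_true(expected_rmax(2, 1e9, 1e6) >= expected_rmax(1, 1e9, 1e6))
    expect_true(expected_rmax(1, 2e9, 1e6) >= expected_rmax(1, 1e9, 1e6))
})

test_that("tail exponent follows alpha = -(3 + beta)", {
    expect_equal(exponent_from_beta(0), -3)
    expect_equal(exponent_from_beta(1), -4)
    expect_equal(exponent_from_beta(2), -5)
    expect_error(exponent_from_beta(-1))
})
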