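## Independent oracles used across the test files. These deliberately avoid
## the package's suffix-array and closed-form code paths: matches are found
## by per-diagonal run-length scans, and densities by direct Monte Carlo.

random_dna <- function(n, n_frac = 0) {
    alpha <- c("A", "C", "G", "T", "N")
    prob <- c(rep((1 - n_frac) / 4, 4), n_frac)
    paste0(sample(alpha, n, replace = TRUE, prob = prob), collapse = "")
}

## brute-force MEM oracle: scan every alignment diagonal, take maximal runs
## of equal non-N positions
oracle_mems_pair <- function(a, b, minlen) {
    ca <- strsplit(a, "", fixed = TRUE)[[1L]]
    cb <- strsplit(b, "", fixed = TRUE)[[1L]]
    la <- length(ca); lb <- length(cb)
    out <- list()
    if (la >= minlen && lb >= minlen) {
        for (d in (-(la - 1L)):(lb - 1L)) {
            i <- max(1L, 1L - d)
            j <- i + d
            n <- min(la - i, lb - j) + 1L
            if (n < minlen) next
            ia <- i:(i + n - 1L); ib <- j:(j + n - 1L)
            eq <- ca[ia] == cb[ib] & ca[ia] != "N" & cb[ib] != "N"
            r <- rle(eq)
            ends <- cumsum(r$lengths)
            starts <- ends - r$lengths + 1L
            for (k in seq_along(r$values))
                if (r$values[k] && r$lengths[k] >= minlen)
                    out[[length(out) + 1L]] <-
                        c(ia[starts[k]] - 1L, ib[starts[k]] - 1L, r$lengths[k])
        }
    }
    df <- if (length(out)) {
        m <- do.call(rbind, out)
        data.frame(pos_a = m[, 1], pos_b = m[, 2], length = m[, 3])
    } else data.frame(pos_a = integer(), pos_b = integer(),
                      length = integer())
    df[order(df$pos_a, df$pos_b, df$length), , drop = FALSE]
}

## self-alignment oracle: diagonals d >= 1 only (each unordered pair once,
## identity diagonal excluded)
oracle_mems_self <- function(a, minlen) {
    ca <- strsplit(a, "", fixed = TRUE)[[1L]]
    la <- length(ca)
    out <- list()
    if (la >= minlen + 1L) {
        for (d in 1:(la - 1L)) {
            n <- la - d
            if (n < minlen) next
            ia <- 1:n; ib <- ia + d
            eq <- ca[ia] == ca[ib] & ca[ia] != "N" & ca[ib] != "N"
            r <- rle(eq)
            ends <- cumsum(r$lengths)
            starts <- ends - r$lengths + 1L
            for (k in seq_along(r$values))
                if (r$values[k] && r$lengths[k] >= minlen)
                    out[[length(out) + 1L]] <-
                        c(ia[starts[k]] - 1L, ib[starts[k]] - 1L, r$lengths[k])
        }
    }
    df <- if (length(out)) {
        m <- do.call(rbind, out)
        data.frame(pos_a = m[, 1], pos_b = m[, 2], length = m[, 3])
    } else data.frame(pos_a = integer(), pos_b = integer(),
                      length = integer())
    df[order(df$pos_a, df$pos_b, df$length), , drop = FALSE]
}

expect_same_matches <- function(got, want) {
    got <- got[order(got$pos_a, got$pos_b, got$length), , drop = FALSE]
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)),
                 ignore_attr = TRUE)
}

## evaluate a pair_density object, clamped to its support
pd_eval_test <- function(pd, x) {
    out <- numeric(length(x))
    ok <- x >= pd$support[1] & x <= pd$support[2]
    out[ok] <- pd$fun(x[ok])
    out
}

## Monte-Carlo stick breaking: Poisson(K * tau) uniform break points on a
## stick of length K; returns all fragment lengths (boundary + interior)
oracle_stick_fragments <- function(n_trials, K, tau) {
    unlist(lapply(seq_len(n_trials), function(i) {
        nb <- rpois(1L, K * tau)
        diff(c(0, sort(runif(nb, 0, K)), K))
    }))
}

## expected fragment count with length in [lo, hi) from the stick model:
## integral of tau^2 (K - r) exp(-tau r) + 2 tau exp(-tau r) over the bin
oracle_stick_expected <- function(lo, hi, K, tau) {
    f <- function(r) (2 * tau + tau^2 * (K - r)) * exp(-tau * r)
    vapply(seq_along(lo), function(k)
        stats::integrate(f, lo[k], hi[k], rel.tol = 1e-9)$value, numeric(1))
}
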