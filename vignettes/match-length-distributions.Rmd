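---
title: "Match length distributions: models, simulators and tail fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Match length distributions: models, simulators and tail fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mldtools)
```

## The match length distribution

A *maximal exact match* (MEM) between two DNA sequences is a pair of
identical substrings that cannot be extended on either side without hitting
a mismatch, a sequence boundary, or an ambiguous base `N`. The *match
length distribution* (MLD) `m(r)` counts MEMs of each length `r` in the
self-alignment of one genome or the comparative alignment of two genomes.

For two iid random sequences of length $L$ with per-site chance-match
probability $p$ the MLD is geometric,
$$m_{\mathrm{iid}}(r) = \tfrac{1}{2}L^2(1-p)^2 p^r,$$
so matches much longer than $\sim \log_{1/p} L^2$ (about 25–30 bp for
Gbp-scale genomes at $p = 1/4$) are not chance events. Real genomes show a
heavy *power-law* tail beyond this point, $m(r)\sim r^\alpha$, and the
exponent $\alpha$ is diagnostic of the evolutionary process that created
the similarities. This package computes MLDs, evaluates the analytic
models that predict them, simulates the underlying evolutionary dynamics,
and estimates $\alpha$.

A note on the prefactor: the printed iid law above counts each unordered
locus pair once (convention `"half"`), which is the natural count for a
self-alignment. A comparative MEM search reports every ordered (locus in
A, locus in B) pair, which doubles the expectation; `iid_mld()` exposes
both conventions (`"full"` is $L^2(1-p)^2p^r$) because published worked
examples mix the two, and our comparative test assertions use `"full"`,
which is what an all-vs-all match search actually returns.

## From pair density to MLD

The central object of the theory is the *pair density* $N(\tau)$: the
number of homologous segment pairs separated by evolutionary distance
$\tau$ (expected substitutions per site along the path connecting them).
A single pair of initially identical segments of length $K$ at distance
$\tau$ contributes the *stick-breaking* MLD
$$m(r,\tau) = \left[2\tau + \tau^2 (K - r)\right] e^{-\tau r},$$
an exponential tail (`stick_mld()`). A genome's MLD is this kernel
integrated against the pair density,
$$m(r) = \int_0^\infty m(r,\tau)\, N(\tau)\, d\tau,$$
implemented by `mld_from_density()` with adaptive quadrature. Because the
kernel concentrates on $\tau \lesssim 1/r$, the *small-$\tau$ behaviour*
of $N$ controls the tail: if $N(\tau)\sim\tau^\beta$ then
$\alpha = -(3+\beta)$ (`exponent_from_beta()`).

Three mechanisms give the three regimes:

* **Ongoing segmental duplication** (random copies, or a Yule family in
  which every copy duplicates again at rate $\lambda K$) keeps producing
  identical pairs, so $N(0) > 0$, $\beta = 0$, $\alpha = -3$
  (`yule_pair_density()`, `yule_mld_tail()`, `random_dup_mld_tail()`).
  The longest match expected this way is
  $r_{\max} \simeq (A L)^{1/3}$ with $A = \lambda K / \mu$, capped at $K$
  (`expected_rmax()`); at $A = 1$, $L = 1$ Gbp that is about 1000 bp, and
  only about 500 bp at $A = 0.1$ — long exact self-similarities require no
  selection.
* **Retroduplication**: a conserved source gene (mutation rate $a\mu$,
  $0 \le a < 1$) spawns processed pseudogenes (rate $\mu$) that never
  duplicate. With copy birth times uniform over the family age $T$, the
  copy-pair distance $\tau = \mu(2T - T_1 - T_2) + a\mu\lvert T_1 -
  T_2\rvert$ has a triangular density rising from $N(0) = 0$ to a peak at
  $(1+a)\mu T$ and vanishing at $2\mu T$ (`retro_pair_density()`; the
  explicit coefficients are derived from the geometry of $(T_1, T_2)$ on
  the square $[0,T]^2$ and locked in by a direct sampling test). Hence
  $\beta = 1$ and $\alpha = -4$, with closed form
  $m(r) = 3K^3\lambda^2 / ((1+a)\mu^2 r^4)$ (`retro_mld_tail()`).
* **Divergence of two species** with region-wise heterogeneous mutation
  rates: the comparative pair density is the convolution of the two
  per-species densities (`convolve_pair_density()`), which always vanishes
  at $\tau = 0$; for any rate distribution smooth and positive at zero the
  linear term dominates and $\alpha = -4$
  (`comparative_mld_tail()`). If the rate distribution vanishes at zero
  the linear term drops out and $\alpha = -5$, the $\beta = 2$ regime.

## MEM enumeration

`find_mems()` / `find_self_mems()` build a generalized suffix array
(prefix-doubling construction with counting sort, Kasai LCP array) over
the concatenation of the inputs. Every `N` and every record separator is
encoded as a globally unique symbol, so ambiguous bases match nothing —
not even another `N` — and no match crosses a record boundary. A MEM
corresponds one-to-one to a suffix pair whose longest common prefix is at
least `minlen` (right-maximality) and whose preceding symbols differ or
hit a boundary (left-maximality); all occurrences are reported, the
equivalent of a MAXMATCH search. Self-alignments exclude the identity
diagonal and report each unordered locus pair once (`pos_a < pos_b`);
duplicated loci therefore enter the histogram with the multiplicity the
pair-counting models assume. Matching is forward-strand; coordinates are
0-based.

`filter_unique()` implements the uniqueness filter used to separate
orthologous from duplication-derived matches: a match is non-unique if its
sequence shares a continuous exact segment of more than `share_threshold`
bp (default 20, i.e. a shared 21-mer) with any other match's sequence, as
determined by an all-vs-all MEM search among the extracted match strings.

`log_bin()` rebins the integer histogram into geometric bins
(`ratio = 1.25` by default). Bin edges are snapped to integers so that a
bin's width equals the number of distinct lengths it covers, and `mean_r`
is the geometric mean of those integer lengths. With real-valued edges the
fluctuating integer coverage of the narrow first bins adds enough jitter
to bias a weighted slope fit by up to ~0.05; integer-aligned edges remove
that bias while keeping the count-conservation identity
`sum(density * (hi - lo)) == total_matches` exact.

## Tail fitting

`tail_start()` defines the tail as the lengths whose iid expectation falls
below 0.5. `fit_tail_exponent()` (and the convenience wrapper
`fit_mld_tail()`) performs weighted least squares of `log(density)` on
`log(mean_r)` over the occupied bins in the fit range, weighting each bin
by its match count (the log of a Poisson count has variance ~1/count).
This mirrors how power-law guide lines are judged on log-binned MLD plots;
a maximum-likelihood estimator was deliberately not made the default so
that fitted exponents remain comparable with that visual practice. The
upper fit bound defaults to the last bin holding at least 5 matches, which
suppresses noise at the very tip of the distribution, where fresh
duplications and selection-driven conservation both distort the power
law. Fewer than 4 occupied bins raises a classed insufficient-data error
rather than returning a spurious exponent — iid-like data selected via
`tail_start()` lands in this branch by construction. The returned
`mld_tail_fit` object carries the exponent, its standard error, the fit
range and the underlying `lm`, with `print`/`summary`/`coef`/`predict`/
`plot` methods.

## The simulators

`evolve_sequence()` runs an exact Gillespie (kinetic Monte Carlo) scheme:
point mutations and segmental duplications are independent Poisson
streams, so waiting times are exponential in the summed rate. A mutation
replaces one nucleotide by one of the other three uniformly — the MLD is
insensitive to substitution-model details because any replacement breaks a
match, which is also why $\mu$ can be read as an effective rate subsuming
short indels. A duplication copies a uniformly chosen `K`-bp segment over
a uniformly chosen target locus (source read before paste, so overlapping
loci are well defined), conserving total length. Region-wise heterogeneous
mutation rates (`rates`, `M`) weight mutation positions; duplications stay
uniform. All randomness flows through R's RNG: seeded runs are
bit-reproducible.

`evolve_yule()` and `evolve_retro()` grow segment families: in Yule mode
every segment duplicates at $\lambda K$; in retro mode only the source
duplicates, and it mutates at the reduced rate $a\mu$. Copies append at
position $nK$, mirroring how a pseudogenome is assembled by
concatenation. For retro analyses the MLD is computed on
`family_copies()` — the copies *without* the source — because the analytic
$\alpha=-4$ result describes copy–copy pairs; source–copy pairs have
$N(0)>0$ (the source keeps spawning fresh identical copies) and would mix
an $\alpha=-3$ component into the histogram, just as a real "processed
pseudogenome" excludes the parent genes.

`speciate_and_diverge()` duplicates a stationary ancestor and evolves the
two descendants for `t1` with fresh, independent Exponential(mean 1)
region rates (the maximum-entropy choice given only the mean). Post-split
duplications default to off. This is a deliberate design decision: the
comparative $\alpha = -4$ tail is an orthologous conserved-element effect,
and its derivation contains no duplication term. Keeping duplications
running at the stationary rate $\lambda K = 1$ per site would (i)
overwrite conserved regions, thinning surviving orthologous matches by
$e^{-2\lambda (r+K) t_1}$ — an $r$-dependent factor that steepens the
apparent slope — and (ii) generate ortholog-of-copy pairs whose pair
density grows as $\tau^2$, overlaying an $r^{-5}$ component that dominates
below roughly 55 bp at these parameters. Both effects are independent of
genome length, so they are not a small-scale artefact; measured at desk
scale they shift the fitted exponent to about $-4.8$. With mutation-only
divergence the measured tail sits at $-4$ as the theory predicts. Users
can re-enable post-split duplications via the `lambda` argument to study
exactly this interplay.

With per-site independent rates (`M = 1`) the model loses the property
that the rate field is correlated over lengths comparable to a match, and
long comparative matches vanish instead of forming a power law — the
package's simulations reproduce that limiting behaviour too.

## Study conditions and problem sizes

The simulation defaults mirror the published study conditions: mutation
rate $\mu = 1$ (time is measured in expected substitutions per site),
duplication rate $\lambda = 10^{-3}$ per bp, duplication and region
lengths $K = M = 1000$ bp, Exponential(mean 1) region rates, divergence
times $t_1 \in \{0.01, 0.2, 2\}$ spanning the exponential-to-power-law
crossover. Stationarity is reached with a burn-in of 5 expected
substitutions per site; the tail-relevant pairs ($\tau \lesssim 1/r
\lesssim 0.05$) equilibrate well inside that window, and tail match counts
are stable between burn-in 4 and 5 within sampling error.

Ensemble sizes are scaled down from the published $10^4$ sequences of
$10^6$ bp to desk scale: 200 replicates of $10^5$ bp for the
random-duplication and divergence scenarios, 40 Yule families grown for
$T=5$ at $\lambda K = 1$, and 400 retro families grown for $T = 2$ at
$\lambda K = 30$, $a = 0.1$. The retro duplication rate is the one
generator parameter without a published value; it was chosen once so that
the ensemble accumulates the $\ge 10^4$ tail matches a stable $\pm 0.3$
exponent fit needs within desk-scale compute, and the closed form
$3K^3\lambda^2/((1+a)\mu^2 r^4)$ is checked against the numeric integral
independently of this choice. Tail fits start at $r = 30$ bp (the
pooled-ensemble iid boundary is ~18 bp, so 30 is conservative) and use
binning ratio 1.25; exponent recovery is invariant to ratios in
[1.1, 1.5].

What the simulations do *not* emulate: real genomes have indels (subsumed
into the effective $\mu$, so simulated coordinates stay aligned while real
ones drift), repetitive elements (the analysis assumes repeat-masked
input), selection, base-composition bias and assembly artefacts. Passing
tests therefore demonstrate that the implementation realizes the stated
stochastic models and their analytic consequences — not that any
particular genome follows them.

## Numerical choices

* `mld_from_density()` truncates integration where $e^{-\tau r} <
  10^{-13}$ (at $\tau = 40/r$) or at the density's support edge, and uses
  `stats::integrate()` at relative tolerance $10^{-6}$.
* Closed-form tails with $e^{\lambda K T}$ prefactors are evaluated in log
  space to avoid overflow.
* `convolve_pair_density()` uses FFT convolution with trapezoid endpoint
  weights on a shared 4097-point grid and pins the value at $\tau = 0$ to
  zero exactly.
* The Yule tree sampler is event-driven on the lineage count (waiting time
  Exponential($n\lambda K$)), storing pairwise MRCA times incrementally,
  so pair distances cost no sequence-level work.
* Ties in `rank_by_average_distance()` break lexicographically by label,
  making the constrained-topology ranking deterministic. Full
  branch-length refitting under a fixed topology is out of scope.
* Degenerate inputs: empty sequences and empty MLDs propagate as empty
  results; `minlen` greater than the sequence length yields no matches;
  `ratio <= 1`, `a >= 1`, `K > L` and `r >= K` raise immediate errors.

## Known limitations

Forward-strand matching only by default (reverse-complement matches would
add a strand flag, not change the exponents); no gapped or inexact
alignment; no maximum-likelihood tail estimator; pair densities with
infinite support must decay fast enough for the truncated quadrature; the
MEM enumerator holds the suffix array of the concatenation in memory,
which is comfortable for desk-scale genomes (~10 MB per Mbp) but not for
mammalian chromosomes in one piece.
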