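---
title: "Methods: testing homogeneity of variance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing homogeneity of variance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homovar)
```

This vignette documents the statistical model behind `homovar`, the exact
procedures each test implements, the numerical choices made in the
implementation, and the design of the synthetic-data generators and the
Monte-Carlo engine. It is the reference for *why* the package behaves as
it does; the README covers *how* to use it.

## 1. Model and hypotheses

Data are $k \ge 2$ independent samples
$Y_{i1}, \dots, Y_{in_i}$, $i = 1, \dots, k$, from continuous
distributions with finite variances $\sigma_i^2$. The hypotheses are

$$H_0:\ \sigma_1^2 = \cdots = \sigma_k^2
\qquad\text{vs.}\qquad
H_1:\ \sigma_i^2 \ne \sigma_j^2 \text{ for some } i \ne j .$$

All tests treat groups as independent and observations within a group as
i.i.d.; none of them models covariates, repeated measures, or censoring.
The container type is `grouped_sample`: a named list of numeric vectors,
validated to have $k \ge 2$ groups, $n_i \ge 2$ finite observations each.

A recurring theme: tests derived under normality (F, Bartlett, Hartley,
Cochran) are exact for normal data but their size is not robust — under
heavy tails they reject a true $H_0$ far too often, because the null
distribution of a sample variance depends on the population kurtosis.
The robust family (Levene-type, Fligner–Killeen, Ansari–Bradley, Moses,
jackknife) trades some normal-theory power for size that survives
non-normality. The simulation engine (§5) exists to quantify that
trade-off; the recommender (§7) encodes its conclusions.

## 2. Two-sample procedures

### 2.1 Variance-ratio F test (`f_test`)

$F = s_x^2/s_y^2 \sim F(n_1-1,\, n_2-1)$ under $H_0$ and normality.
Two-sided p-value $2\min\{P(F \le f), P(F \ge f)\}$ capped at 1, matching
the standard convention. Its power against a true ratio $\rho$ has the
closed form
$$\pi(\rho) = P\!\big(F > q_{1-\alpha/2}/\rho\big)
            + P\!\big(F < q_{\alpha/2}/\rho\big),$$
implemented as `f_test_power()` and used as an analytic oracle for the
Monte-Carlo engine: simulated F-test power must agree with it within
Monte-Carlo error, which is a strong end-to-end check on generators,
seeding and decision logic.

### 2.2 Ansari–Bradley (`ansari_bradley_test`)

Pool the samples, sort, and score position $j$ among $N = m+n$ as
$s(j) = \min(j,\, N+1-j)$: small scores at the extremes, large in the
middle. $W$ = sum of scores of the *smaller* sample (scoring the smaller
group keeps the exact-null computation cheapest; when the roles are
swapped the alternative is flipped so the user-facing semantics —
"is `x` more dispersed than `y`?" — never change). A dispersed sample
concentrates at the extremes, so *small* $W$ indicates that the scored
sample is more spread out.

**Exact null.** Under $H_0$ every $\binom{N}{m}$ assignment of pooled
positions to the scored sample is equally likely. The exact pmf of $W$ is
computed by dynamic programming over (number of items taken, score sum):
a $(m+1) \times (w_{\max}+1)$ count table updated one score at a time.
This is exact at *every* sample size; we use it as the single production
path whenever $m+n \le 200$ (beyond that the table is large and the
normal approximation is indistinguishable), memoised per $(m, N)$.
An independent brute-force enumeration over `combn` output serves as the
test-suite oracle for $m+n \le 12$. Critical values are defined
conservatively: the upper critical value is the smallest $w$ with
$P(W \ge w) \le \alpha$ (NA if unattainable), and symmetrically for the
lower tail — attainable size never exceeds nominal.

**Ties and large samples.** With ties, positions in a tied block receive
the *average* of their scores, and the null is evaluated by a normal
approximation with the finite-population moments of the realized score
vector:
$E W = m \bar s$, $\operatorname{Var} W = \frac{mn}{N-1}
\big(\overline{s^2} - \bar s^2\big)$ (no continuity correction). This is
the same approximation path as the classical large-sample treatment and
agrees with `stats::ansari.test`'s normal path on tie-free data.

**Median alignment.** The test assumes equal medians. With
`align_medians = TRUE` each sample is centred at the median of its Walsh
averages $(x_i + x_j)/2$, $i \le j$ (the Hodges–Lehmann centre), with a
warning that the exact null is then only approximate. The battery runs
both variants.

### 2.3 Moses rank-like test (`moses_test`)

Each sample is randomly partitioned into disjoint subsets of size $h$
(default `subset_size = 3` — the smallest size for which a within-subset
sum of squares has more than one degree of freedom, keeping the number of
subsets, and hence power, as large as possible); leftover observations
are dropped. The within-subset sums of squares are compared across the
two samples with a Wilcoxon rank-sum test. Because the result depends on
the random partition, the procedure is repeated (`repartitions = 200`,
seeded) and the **median p-value** across repartitions is reported: the
median is invariant to relabelling repartitions and removes the
"re-run until significant" degree of freedom. The defaults balance
stability of the median p (MC noise on the median shrinks like the
density of p at its median over repartitions) against cost; they are
package choices, adjustable per call. Moses needs no equal-median
assumption at all, which is its niche, but it discards information and is
the least powerful option — which is also why it is *excluded* from the
default simulation registry and the battery's power claims (§5): it is
provided for completeness and for median-free designs, not as a
recommended workhorse.

### 2.4 Jackknife test (`jackknife_test`)

Miller's procedure. For sample $x$ of size $n$ with variance $s^2$,
define leave-one-out variances $s^2_{(i)}$ and pseudo-values
$$A_i = n \ln s^2 - (n-1) \ln s^2_{(i)} .$$
The $A_i$ behave asymptotically like i.i.d. observations with mean
$\ln \sigma_x^2$, so equality of variances becomes an ordinary
two-sample comparison of the pseudo-value means:
$$Q = \frac{\bar B - \bar A}{\sqrt{V_A + V_B}},\qquad
V_A = \frac{1}{n_1(n_1-1)}\sum_i (A_i - \bar A)^2 .$$
The leave-one-out variances are computed by the exact $O(n)$ update
$D_i = \big(SS - \tfrac{n}{n-1}(x_i - \bar x)^2\big)/(n-2)$, not by $n$
recomputations. $\exp(\bar B - \bar A)$ estimates
$\gamma^2 = \sigma_y^2/\sigma_x^2$; the identity $y = c\,x \Rightarrow
\hat\gamma^2 = c^2$ holds *exactly* and is unit-tested. Reference
distribution: `mode = "auto"` uses a $t$ with $n_1+n_2-2$ df when
$n_1+n_2 < 60$ (the exact-t reference is noticeably better calibrated in
small samples) and the normal otherwise; both are available explicitly.
$n_i \ge 3$ is required — at $n = 2$ the leave-one-out variance is
degenerate, and the test errors rather than guessing.

## 3. Multi-sample procedures

### 3.1 Levene family (`levene_test`, `brown_forsythe_test`)

Transform to absolute deviations $Z_{ij} = |Y_{ij} - c_i|$ and compute
the one-way ANOVA F statistic
$$W = \frac{N-k}{k-1}\,
\frac{\sum_i n_i (\bar Z_{i\cdot} - \bar Z_{\cdot\cdot})^2}
     {\sum_i \sum_j (Z_{ij} - \bar Z_{i\cdot})^2}
\ \sim\ F(k-1,\, N-k) \text{ approximately under } H_0 .$$
Centres $c_i$: group `"mean"` (classical Levene, most powerful under
near-normality), `"median"` (Brown–Forsythe, the robust default
recommendation for skewed data), `"trimmed"` mean with
`trim = 0.25` per tail by default (floor$(p\,n_i)$ observations trimmed
from each tail — a compromise between mean and median; 0.25 is a common
heavy-trim default, adjustable), and `"rank"` (pooled midranks replace
the data, then mean-centring — a fully distribution-free variant).
`brown_forsythe_test` returns the identical object as
`levene_test(gs, "median")`. If every $Z_{ij} - \bar Z_{i\cdot}$ is zero
(e.g. all groups of size 2), the statistic is undefined and the function
errors with "degenerate" rather than returning 0/0.

### 3.2 Bartlett (`bartlett_test`)

$$M = \frac{(N-k)\ln s_p^2 - \sum_i (n_i-1) \ln s_i^2}{1 +
\frac{1}{3(k-1)}\Big(\sum_i \frac{1}{n_i-1} - \frac{1}{N-k}\Big)}
\ \sim\ \chi^2_{k-1}$$
with $s_p^2$ the pooled variance. Any group with zero sample variance
makes $\ln s_i^2$ undefined; the function errors explicitly. Verified
against `stats::bartlett.test` to $10^{-12}$ and against the hand-checked
$k=2$, $n_i = 11$, $s^2 = (1, 2)$ example
$M = (20\ln 1.5 - 10\ln 2)/1.05$.

### 3.3 Hartley's Fmax (`hartley_test`)

$F_{\max} = \max_i s_i^2 / \min_i s_i^2$ for balanced groups with
$\text{df} = n - 1$. Writing $G$ for the CDF of $s^2/\sigma^2$ (a scaled
$\chi^2_{\text{df}}$), the null CDF is
$$P(F_{\max} \le c) = k \int g(u)\,\big[G(cu) - G(u)\big]^{k-1}\, du .$$
Rather than interpolating published tables, the package evaluates this
integral directly, so any $(k, \text{df}, \alpha)$ is available.
**Numerical choice:** the integrand over $u \in (0,\infty)$ becomes
extremely peaked at large df and defeats adaptive quadrature; the
implementation substitutes $p = G(u)$, giving the bounded, smooth form
$$P(F_{\max} \le c) = k \int_0^1
\big[G\big(c\,G^{-1}(p)\big) - p\big]^{k-1}\, dp$$
(`pchisq(c * qchisq(p, df), df)` inside), which `integrate()` handles
robustly up to df $= 10^4$ and beyond. Quantiles invert the CDF with
`uniroot` on a doubling bracket. Cross-checks: the closed form at df = 2,
$P(F_{\max}\le c) = 1 + \sum_{j\ge1} (-1)^j \binom{k-1}{j}
\frac{k}{(k-j)+jc}$, and classical table entries (39.0 at
$k=2$, df 2, $\alpha=.05$; 87.5 at $k=3$). Unbalanced designs use the
*minimum* df (conservative) and flag the method string with
"unbalanced". Both a critical-value decision and a quadrature p-value are
reported, and they agree by construction.

### 3.4 Cochran's C (`cochran_c_test`)

$C = \max_i s_i^2 / \sum_j s_j^2$ for $k$ balanced groups of size $n$.
**Design decision:** published statements of the critical bound are often
garbled in transcription; this package derives and uses the standard form
$$C_{UL}(\alpha) = \Big(1 + \frac{k-1}{F^*}\Big)^{-1},\qquad
F^* = F_{1-\alpha/k}\big(n-1,\ (k-1)(n-1)\big),$$
which follows from the union bound over which group attains the maximum
plus the exact null distribution of $s_{\max}^2 / \bar s^2_{\text{rest}}$
as an F ratio. Self-consistency check: at $k=2$, $n=3$, $\alpha=.05$ it
gives $39/40$, i.e. the same 39.0 as the Fmax table. The reported p-value
is the exact inversion of the bound,
$p = \min\{1,\ k\,P(F(n-1,(k-1)(n-1)) > (k-1)C/(1-C))\}$, so the
p-value decision and the bound decision can never disagree. Unequal group
sizes are rejected with an informative error (the bound assumes balance).

### 3.5 Fligner–Killeen (`fligner_killeen_test`)

Ranks $r_{ij}$ of $|Y_{ij} - \tilde Y_i|$ (group medians $\tilde Y_i$)
across the pooled sample are transformed to increasing normal scores
$a(r) = \Phi^{-1}\big((1 + \tfrac{r}{N+1})/2\big)$; with $\bar a_i$ the
group means and $v^2$ the variance of all scores (denominator $N-1$),
$$X^2 = \frac{\sum_i n_i (\bar a_i - \bar a)^2}{v^2} \sim \chi^2_{k-1}.$$
This matches `stats::fligner.test` to $10^{-12}$, including midrank tie
handling. One subtlety, documented in the test suite: the statistic is
exactly invariant to per-group location shifts in exact arithmetic, but a
floating-point shift can reorder *nearly tied* deviations and move the
statistic in the fourth decimal; tests assert invariance at $10^{-3}$.

### 3.6 Location tests (`welch_t_test`, `welch_anova`, `one_way_anova`)

Provided because the practical question is usually "which mean test may I
run?". Welch's ANOVA weights groups by $w_i = n_i/s_i^2$ and uses the
Welch–Satterthwaite denominator df; at $k=2$ it reproduces the squared
Welch t statistic exactly (unit-tested). The battery (§7) prints pooled
and Welch analyses side by side, labelling which applies given the
homogeneity verdict.

## 4. Synthetic data generators

Population specifications, not samples, are the primitive: `pop_normal`,
`pop_t(df)` (requires df > 2 so the variance $\text{df}/(\text{df}-2)$
exists), and `pop_skew_normal(xi, omega, alpha)`.

**Skew-normal sampling** uses the delta representation
$$Y = \xi + \omega\big(\delta\,|U_0| + \sqrt{1-\delta^2}\,U_1\big),
\qquad \delta = \alpha/\sqrt{1+\alpha^2},$$
with $U_0, U_1$ independent standard normals — an exact construction
needing only `rnorm`. Its variance is
$\omega^2 (1 - 2\delta^2/\pi)$, and `omega_for_variance(v, alpha)`
inverts this in closed form, so scenarios can pin the **true** variance
of a skewed population exactly. Validated against the closed-form
variance and mean ($\xi + \omega\delta\sqrt{2/\pi}$) at $n = 10^6$.

**Caveat:** changing the variance of a skew-normal while holding $\xi$
fixed also changes its *mean* (the mean shift is
$\omega\delta\sqrt{2/\pi}$), so a skewed "scale" alternative is really a
scale-and-location alternative, which flatters tests sensitive to
location. `scenario_skew_normal(..., match_means = TRUE)` re-centres
every population to a common mean so pure-scale questions can be asked;
the default leaves means unmatched, which mimics the common situation in
practice where a more variable arm also shifts.

**Scenarios** (`scenario_normal(ratios, n, ...)`, `scenario_t(dfs, ...)`,
`scenario_skew_normal(ratios, shape, ...)`) bundle populations, group
size, replicate count, $\alpha$, a seed and an auto-generated id, and
flag whether they sit in the null ($H_0$ true). These generators emulate
the *shape* features that break variance tests — heavy tails (Student-t)
and skewness (skew-normal) — under ideal i.i.d. conditions. They do not
emulate real clinical data's measurement rounding, outliers from protocol
deviations, correlated baselines, or missingness; conclusions transfer to
the extent those features resemble tail weight and asymmetry.

**Reproducibility.** Each (replicate, group) pair gets its own substream
via
`derive_seed(seed, rep, group) = (seed·48271 + rep·69621 + group·16807) mod (2^31−1) + 1`,
a cheap LCG-style hash into the valid seed range. Consequences: any
single replicate can be regenerated in isolation (`make_scenario_groups(sc,
rep = r)`), adding replicates never perturbs earlier ones, and group
streams are effectively independent (tested: $|\text{cor}| < 0.01$ at
$n = 10^5$).

## 5. Monte-Carlo engine

`estimate_rejection(scenario, tests)` draws each replicate, runs every
requested test at the scenario's $\alpha$, and returns a tidy data frame
with `reject_prop`, the binomial `mc_se`
$\sqrt{\hat p (1-\hat p)/R}$, and `n_error`. The registry covers the
two-sample battery (F, Bartlett, four Levene variants, Fligner,
Ansari–Bradley raw and median-aligned, jackknife with normal and exact-t
references) plus Hartley and Cochran; `available_tests(k, normal_only)`
filters it. Hartley and Cochran contribute their critical-value
*decisions*. Moses is deliberately not in the registry: its per-replicate
cost is ~200 Wilcoxon tests and its power is dominated by the other rank
options, so including it would multiply runtime for no ranking value; it
remains available for direct calls.

**Degenerate-replicate policy.** A test that *errors* on a replicate
(e.g. zero within-group variance) is recorded as a non-rejection and
tallied in `n_error` — errors can only make a test look weaker, never
stronger, and the tally makes the event visible instead of silently
biasing power.

`run_power_grid` / `run_type1_grid` sweep sample sizes (type-I grids
force equal variances); `f_test_power` provides the analytic anchor.
Default problem sizes used in the package's own studies and tests —
2000 replicates for headline power numbers (MC se $\approx 0.01$),
500 replicates and a reduced $n$ grid for ordinal comparisons in the test
suite — are the package's own cost/precision choices: 2000 replicates
resolve power differences of ~3 points, and ordinal claims (test A beats
test B) are asserted with a 3-MC-se margin so they are stable across
seeds.

## 6. Critical-value machinery

`critical_value_tables()` regenerates reference tables (Ansari–Bradley
exact critical values over a small-sample grid; Fmax quantiles over
$(k, \text{df}, \alpha)$) from the same production code paths — they are
outputs, not inputs: nothing in the package looks numbers up in a stored
table.

## 7. Recommender and battery

`recommend(k, distribution, n, ratio)` classifies a design into
$\{2, >2\} \times \{\text{normal, skewed, heavy}\} \times
\{\text{small}, \text{large } n\} \times \{\text{small, large ratio}\}$
(bands: $n < 30$ is small; ratio $\le 2$ is small) and returns a ranked
shortlist with a rationale per row. The rules encode the simulation
evidence: normal-theory tests (F/Bartlett/Hartley/Cochran) are
recommended *only* in the normal branch, because their size failure under
skewness/heavy tails is disqualifying regardless of power; the jackknife
leads small-$n$ two-sample cells (with an explicit size caveat in heavy
tails); Brown–Forsythe/trimmed Levene lead skewed cells; Fligner–Killeen
and rank Levene lead heavy-tailed multi-sample cells.

`battery(gs, alpha)` runs every test applicable to the data's $k$ and
balance, reports raw p-values with an explicit no-multiplicity note,
marks inapplicable tests with the reason, and appends a location analysis
(pooled vs Welch) labelled by which one the homogeneity verdict
justifies.

## 8. Summary of design decisions

- Exact Ansari–Bradley null via score-sum dynamic programming at all
  sizes up to $m+n = 200$; brute-force enumeration kept only as a test
  oracle. Conservative critical values (attainable size $\le \alpha$),
  NA when no critical value exists.
- Hartley CDF by probability-substituted quadrature on $(0,1)$; no table
  interpolation anywhere.
- Cochran bound derived from first principles as
  $1/(1+(k-1)/F^*)$ with Bonferroni $\alpha/k$; p-value defined as the
  bound's exact inversion so the two decisions coincide.
- Moses: median-p aggregation over 200 seeded repartitions of size-3
  subsets; excluded from the simulation registry.
- Skew-normal via the delta representation with closed-form
  $\omega$-for-variance inversion; `match_means` option for pure-scale
  alternatives.
- Errors over guesses: degenerate inputs (zero variances, $n=2$
  jackknife, unequal-$n$ Cochran) raise informative errors; inside the
  Monte-Carlo engine they count as non-rejections with an `n_error`
  audit trail.
- Replicate/group substreams from a deterministic seed hash, so every
  cell of every study is independently reproducible.
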