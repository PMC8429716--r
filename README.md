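# sigclone

Joint inference of intra-tumor heterogeneity and mutational-signature activity
from bulk tumor sequencing.

Bulk tumor samples mix genetically distinct subpopulations (clones). Two
questions are usually answered separately: *how many clones are there and at
what cancer cell fractions (CCF)?* (subclonal reconstruction from variant
allele frequencies) and *which mutational processes wrote the mutations?*
(signature deconvolution over the 96 trinucleotide substitution types).
sigclone answers both jointly, which lets each view sharpen the other: a shift
in signature activity helps separate clones whose CCFs are too close for
read-count clustering alone, and clone structure localizes signature activity
in tumor evolution. The package targets researchers analyzing somatic SNV
calls with allele-specific copy number and purity estimates (WES or WGS), and
methodologists benchmarking subclonal-reconstruction tools.

## Model

For each SNV with variant/total read counts $B \le D$, mutation type $T$, and
clonal allele-specific copy number $(C_{normal}, C^{major}, C^{minor})$ in a
sample of purity $p$, latent clone $U$, signature $S$ and multiplicity $M$ are
drawn as

$$U \sim \mathrm{Cat}(\xi),\quad S\mid U \sim \mathrm{Cat}(\pi_U),\quad
T\mid S \sim \mathrm{Cat}(\mu_S),\quad M\mid C \sim \mathrm{Unif}\{1..C^{major}\},$$

$$B \mid D,U,C,M \sim \mathrm{BetaBinomial}\!\big(D,\ \rho\phi_U\eta,\ \rho(1-\phi_U\eta)\big),
\qquad \eta = \frac{pM}{pC_{tumor} + (1-p)C_{normal}},$$

where $\mu$ is a known $L \times 96$ signature catalogue, $\phi_j$ the CCF of
clone $j$, $\xi$ the clone weights, $\pi$ the per-clone signature exposures and
$\rho$ the read-count overdispersion. Fitting is by EM for $J = 1..8$ clones
with entropy-guided splitting and an adaptively scaled BIC-type criterion for
the number of clones. A likelihood-ratio test with simulation-calibrated
chi-square degrees of freedom flags significant changes of signature activity
between clones. See `vignette("sigclone-methods")` for the full account.

## Worked example

```r
library(sigclone)

sigs <- random_signature_matrix(10, seed = 42)    # or read_signature_matrix("cosmic.tsv")

# simulate a two-clone tumor: clonal clone at CCF 1, subclone at CCF 0.4,
# disjoint signature activity
pi <- matrix(0, 2, 10)
pi[1, 1:3] <- c(0.5, 0.3, 0.2)
pi[2, 8:10] <- c(0.4, 0.4, 0.2)
sim <- simulate_sample(sim_config(J = 2, N = 1000, sigs = sigs,
                                  phi = c(1, 0.4), pi = pi,
                                  depth = 100, seed = 1))

fit <- fit_model(sim$sample, sigs, em_cfg = em_config(seed = 1))
fit
#> sigclone_fit: J = 2
#>   loglik -7241.451 after 42 iterations (converged)
#>   selection criterion -7279.4437
#> sigclone_params: J = 2 clones, 10 signatures, rho = 60.65
#>  clone weight   ccf
#>      1  0.092 1.000
#>      2  0.908 0.396

test_change(sim$sample, sigs, fit)
#> signature-change likelihood-ratio test
#>   statistic 190.444 on 9.068 calibrated df; p = 3.703e-36 (significant)
```

The clone number and CCFs are recovered (fitted 1.000 and 0.396 against the
simulated 1 and 0.4; the clone weights, left free here, were drawn by the
simulator from its prior); `rho` is the fitted read-count precision, close to
the simulator's 60. The change test compares this fit against one forced to
share a single signature mixture across clones — here activity differs sharply
between clones, so the statistic is far in the calibrated chi-square tail.

Per-SNV assignments and change quantification:

```r
resp <- posterior_responsibilities(sim$sample, fit$params, sigs)
head(map_assignments(resp))       # MAP clone / signature / multiplicity per SNV
quantify_changes(fit)             # per-signature clonal vs subclonal activity
evaluate_fit(sim$sample, fit, sim$truth, sigs)  # benchmark scores vs truth
```

A command-line wrapper covers the same workflow
(`fit`, `simulate`, `evaluate`, `test-change`, `calibrate`):

```sh
Rscript inst/cli/sigclone simulate --signatures sigs.tsv --clones 2 --seed 1 --output-dir sim/
Rscript inst/cli/sigclone fit --snv sim/sample.tsv --purity 0.72 --signatures sigs.tsv --output-dir out/
```

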