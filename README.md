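# gklink

Link prediction for bipartite miRNA–lncRNA interaction networks, for
computational biologists studying post-transcriptional regulation and the
competing-endogenous-RNA (ceRNA) hypothesis. Given a curated set of observed
miRNA–lncRNA interactions — and optionally RNA sequences, expression
profiles, or functional annotations — `gklink` ranks the unobserved pairs by
how likely they are to interact, so that wet-lab validation can be focused
on the most promising candidates.

## The model

Let `Adj` be the binary m × l interaction matrix (m miRNAs, l lncRNAs).
Each RNA's *interaction profile* is its row (or column) of `Adj`; the
Gaussian interaction-profile (GIP) kernel turns profiles into a similarity

    GKS(i, j) = exp(−γ ‖p_i − p_j‖²),     γ = n / Σ_i ‖p_i‖²,

so RNAs sharing interaction partners come out similar, and the bandwidth γ
is self-normalizing (the kernel is invariant to a common rescaling of the
profiles). Alternatively the similarity can come from sequences (normalized
Needleman–Wunsch global-alignment scores), expression (Pearson correlation,
clipped at 0) or annotations (Ochiai set similarity |A∩B| / √(|A||B|)).

The similarities and the interaction matrix are stacked into one symmetric
integrated adjacency

    Adj′ = [ Sim_miRNA   Adj      ]
           [ Adjᵀ        Sim_lncRNA ],

and a contribution matrix `C` is fitted by the ridge-type linear
optimization

    min_C  α ‖Adj′ − Adj′·C‖²_F + ‖C‖²_F,

whose closed form solves `(α·Adj′ᵀAdj′ + I)·C* = α·Adj′ᵀAdj′`. The rating
matrix `RS = Adj′·C*` reconstructs the network through the learned
contributions; its top-right m × l block scores every miRNA–lncRNA pair.
For symmetric `Adj′` the eigenvalues of `C*` are `αλ²/(1+αλ²)` for
eigenvalues λ of `Adj′` — a spectral shrinkage with `‖C*‖₂ < 1`, which the
test suite checks exactly.

## Worked example

```r
library(gklink)

# a seeded planted-block synthetic study (5 communities, ~8% density)
net <- planted_block_network(planted_spec(seed = 42))
net$dataset
#> miRNA-lncRNA interaction dataset
#>   60 miRNAs x 100 lncRNAs, 451 interactions (density 7.52%)

fit <- gklink(net$dataset, profile = "network", alpha = 0.007)
summary(fit)
#> gklink fit summary
#>   profile network, alpha 0.007, 60 x 100 network
#>   451 known interactions, 5549 candidate pairs
#>   mean score known 0.1760 / candidate 0.0576, in-sample AUC 0.9975
#>   spectral norm of contribution matrix 0.7938 (< 1 by construction)

head(predict(fit, top = 5))   # top novel candidates, rank among all pairs
#>     mirna_id lncrna_id     score known rank
#> 182  mir-017   lnc-082 0.1845526     0  182
#> 306  mir-009   lnc-064 0.1585096     0  306
#> 311  mir-017   lnc-027 0.1577023     0  311
#> 312  mir-004   lnc-084 0.1572408     0  312
#> 330  mir-054   lnc-069 0.1522493     0  330

run_kfold_cv(net$dataset, k = 5, repeats = 10, seed = 42)
#> 5-fold CV, 10 repeat(s), profile network, alpha 0.007
#>   AUC 0.6395 +/- 0.0117
```

The in-sample AUC (0.9975) says the model reconstructs edges it has seen;
the cross-validated AUC (0.64 here) is the honest estimate of how well
*held-out* edges are recovered after masking them from both the training
matrix and the similarity computation — the gap is the price of avoiding
information leakage. Known interactions score ~3× higher than candidates on
average, and the top-ranked candidates concentrate in the planted blocks.

## Command line

```sh
Rscript inst/cli/gklink simulate --m 60 --l 100 --blocks 5 --seed 1 --out study/
Rscript inst/cli/gklink predict  --interactions study/interactions.tsv --out scores.tsv
Rscript inst/cli/gklink cv       --interactions study/interactions.tsv --k 5 --repeats 100 --seed 1 --out cv.tsv
Rscript inst/cli/gklink sweep    --interactions study/interactions.tsv --out sweep.tsv
```

Subcommands: `predict`, `cv`, `loo`, `sweep` (α-sensitivity grid,
0.001–0.019 in 13 steps by default), `simulate`. All output is
byte-reproducible given the same inputs and `--seed`.

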