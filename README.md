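# transmarker

Dynamic network biomarker (DNB) discovery from multi-state single-cell
expression data by cross-state graph alignment.

## The problem

Cancer progresses through ordered pathological states, and the transitions
are driven as much by *rewiring* of gene regulatory interactions as by
expression changes of individual genes. Given one expression matrix per
disease state (genes × cells) and a prior directed regulatory network,
`transmarker` finds the gene module whose network role is most unstable
across states — a candidate marker of the transitions themselves — and
validates it by multiclass disease-state classification. It is aimed at
computational biologists working with staged single-cell cohorts
(e.g. normal → precancerous lesion → primary tumour → metastasis).

## The method

For states `t = 1, …, T` sharing a gene set of size `N`:

1. **State-specific networks.** The prior network is pruned per state with
   a path-consistency procedure: an edge survives order 0 if its Gaussian
   mutual information `MI(X,Y) = -½ log(1 - cor(X,Y)²)` exceeds a
   threshold (default 0.03), and order 1 if its conditional mutual
   information given every common neighbour does too.
2. **Topological similarity.** `S(t) = α·S_local + (1-α)·S_global` with
   `S_local,ij = exp(-d_ij)` (shortest paths) and
   `S_global,ij = p_i·p_j` (PageRank scores), each row-normalized;
   default `α = 0.3`.
3. **Graph attention embedding.** A two-layer multi-head GAT per state
   (64 hidden units over 2 heads, 62-dim output) is trained without labels
   to reconstruct the state adjacency from embedding dot products,
   `Â_ij = σ(eᵢᵀeⱼ)`, by binary cross-entropy with Adam and early
   stopping.
4. **Gromov–Wasserstein alignment.** Consecutive-state embedding
   geometries are coupled by entropic GW transport
   (`min_Γ Σ (D_ij - D'_kl)² Γ_ik Γ_jl - ε H(Γ)`, default `ε = 1e-2`),
   and each gene's structural-shift score is the population standard
   deviation of its transport-plan row, summed over transitions:
   `R_i = Σ_t std(Γ_i,:)`.
5. **DNB selection.** Genes above the knee of the ranked `R` curve (top
   15% as fallback) induce a union network; its connected components are
   scored by the Dynamic Network Instability
   `DNI = std_t(exp((1-ρ_t)·Ψ_t))`, where `ρ_t` is the component's edge
   density and `Ψ_t` its summed member scores, and the arg-max component
   `C*` is the DNB module.
6. **Classification.** An MLP (128/64/32, class-weighted cross-entropy,
   stratified 70/10/20 splits, early stopping on validation macro AUROC)
   reports accuracy, macro AUROC/AUPRC, F1, precision, recall and
   specificity over repeated runs.

A built-in kinetic simulator (`tm_simulate_benchmark()`) generates
regulon-structured GRNs, rewires a driver compartment across states, and
produces UMI counts with extrinsic/technical noise and dropout, so the
whole pipeline is testable with known ground truth.

## Worked example

```r
library(transmarker)

ds  <- tm_simulate_benchmark(30, seed = 7)   # 4 states x 100 cells, 30 genes
run <- tm_run_pipeline(ds, config = tm_config(seed = 7,
                                              mlp = tm_mlp_config(n_runs = 4)))
run
#> <tm_run> 4 states, 30 genes; 5 selected, DNB module of 1 gene(s) (DNI 0.0000)
#> <tm_metrics> 4 run(s)
#>   accuracy     0.8531 +/- 0.0373
#>   auroc        0.9579 +/- 0.0155
#>   auprc        0.8973 +/- 0.0363
#>   f1           0.8520 +/- 0.0404
#>   precision    0.8620 +/- 0.0303
#>   recall       0.8531 +/- 0.0373
#>   specificity  0.9510 +/- 0.0124

glance(run)
#> # A tibble: 1 x 7
#>   n_states n_genes n_selected n_components n_dnb   dni accuracy
#>      <int>   <int>      <int>        <int> <int> <dbl>    <dbl>
#> 1        4      30          5            5     1     0    0.853
```

The printed block means: 5 of 30 genes were flagged as structurally
variable across the four states, the union network over them decomposed
into 5 components (here all singletons, so the instability index cannot
rank a multi-gene module), and the state classifier — fed the biomarkers
together with the initial feature matrix — distinguishes the four disease
states with mean test accuracy 0.853 over 4 repeated splits. `tidy(run)`
gives the per-gene score table; `autoplot(run$scores)` draws the ranked
score curve used by the knee selection.

## Package layout

| file            | contents                                              |
|-----------------|-------------------------------------------------------|
| `R/grn.R`, `R/simulate.R` | ground-truth networks, rewiring, count simulator |
| `R/network.R`   | DEG screen, background assembly, PC-CMI pruning       |
| `R/topology.R`  | local/global similarity and fusion                    |
| `R/gat.R`       | graph attention embedder (analytic gradients)         |
| `R/gw.R`        | entropic Gromov–Wasserstein solver and scores         |
| `R/dnb.R`       | knee selection, components, DNI ranking               |
| `R/metrics.R`, `R/mlp.R` | evaluation metrics and the MLP classifier    |
| `R/pipeline.R`  | configuration, orchestration, I/O                     |
| `inst/cli/transmarker.R` | command-line wrapper (simulate / run / classify) |

The methods vignette (`vignettes/transmarker-methods.Rmd`) documents the
models, defaults, numerical choices and the simulator's scope in detail.
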