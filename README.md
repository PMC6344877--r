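# regulonkin

Kinetic modeling and genomic mapping of bacterial sigma-factor regulons.

## What problem this solves

A ChIP-seq experiment on a tagged sigma factor yields hundreds to
thousands of bound promoters, but binding is not control: a principal
(housekeeping) sigma factor sits on many promoters whose output never
tracks its concentration. `regulonkin` is for researchers who have (i)
ChIP-seq peak calls, (ii) an expression time course covering the same
growth conditions, and (iii) gene/operon/TSS annotation, and who want to
know **which bound genes are kinetically controlled by the sigma factor,
which need a cofactor complex, and which are constitutive**.

The core is a cascade of three transcription-kinetics ODE models fitted
per gene to the spline-smoothed series x(t):

1. constant synthesis: dx/dt = k1 − k2·x
2. direct regulation: dx/dt = k1 · σ(w·y + b) − k2·x, with y(t) the
   smoothed regulator profile and σ the logistic function
3. cooperative regulation: the same equation driven by the equilibrium
   concentration of a sigma-factor–cofactor complex,
   y_AB = ½(y_A + y_B + q − √((y_A − y_B)² + 2q(y_A + y_B) + q²)),
   evaluated in a cancellation-free rationalized form; q is fitted jointly

A gene is assigned the simplest model that fits it well (rmse ≤ 0.2 ×
mean level by default), giving the categories `constitutive`,
`regulated`, `complex_only`, `not_modeled`, plus 10%/20% improvement
tiers for cooperative-over-direct fits and a permutation-based
false-positive estimate. Companion modules filter peaks (P < 0.05, fold
enrichment ≥ 2), assign summits ≤ 300 bp upstream of start codons,
expand assignments over operons, and compute promoter −10-element
(TANNNT) anchored −14/−13 GG dinucleotide statistics with Fisher
enrichment tests. A synthetic-data module generates every input with
known ground truth.

## Worked example

Simulate a benchmark with known truth and classify it:

```r
library(regulonkin)
cfg  <- sim_config(seed = 42, n_genes = c(constant = 4L, direct = 4L,
                                          cooperative = 4L))
regs <- make_regulator_profiles(cfg)   # early-peaking sigma factor,
                                       # late-peaking cofactor
sim  <- simulate_targets(cfg, regulators = regs)
fc   <- fit_config(seed = 42, n_steps = 400, n_restarts = 2)
classify_genes(sim$matrix, regs$regulator, regs$cofactor, fc)
```

prints (gene ids carry the generating model):

```
         gene_id     category improvement tier rmse_direct rmse_cooperative
1     constant_1 constitutive          NA none          NA               NA
...
5       direct_1    regulated      -1.229 none       0.336            0.748
...
9  cooperative_1 complex_only          NA none       1.510            0.417
11 cooperative_3    regulated       0.598 ge20       1.380            0.554
12 cooperative_4 complex_only          NA none       0.737            0.161
```

Constant-model genes land in `constitutive`; direct-model genes in
`regulated` (their cooperative fit is worse — negative improvement);
complex-driven genes either cannot be fitted by the direct model at all
(`complex_only`) or fit ≥ 20% better with the complex (`ge20`). The
`rmse_*` columns are in expression units.

The promoter statistics reproduce the published worked example exactly:

```r
expected_gg_sites(0.114, 954)
#> $raw 108.756   $rounded 109
complex_concentration(2, 3, q = 0)      # tight binding -> min = 2
complex_concentration(2, 3, q = 1e12)   # no binding    -> 6e-12 ~ 0
```

A full pipeline run (peaks → regulon → classification → promoter stats)
is `run_pipeline(run_config(...))`, or from the shell:

```sh
Rscript exec/regulon simulate --outdir sim --seed 1
Rscript exec/regulon run --expression sim/expression.tsv \
    --genes sim/genes.gff3 --peaks sim/peaks.tsv --operons sim/operons.tsv \
    --tss sim/tss.tsv --genome sim/genome.fasta \
    --regulator sigA --cofactor cofA --outdir out --seed 1
```

## Further reading

The methods vignette (`vignettes/regulon-kinetics.Rmd`) documents the
models and their assumptions, every tunable parameter with units and
defaults, what the synthetic generator does and does not emulate, and the
numerical design choices (stable quadratic root, log-scale q search,
informed annealing starts, acceptance rule).
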