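# knockoutr

Knockout extinction models for bipartite mutualistic networks.

Ecologists assess the vulnerability of plant–pollinator communities by
simulating species loss on the observed interaction network: plants are
removed one at a time, pollinators die once they have lost too many of
their resources, and the network's **robustness** is the normalized area
under the pollinator survival curve,

    R = (1/(A·P)) · Σ_{p=0..P} a(p),

where the network has `A` pollinator and `P` plant species and `a(p)` is
the number of pollinator species surviving after `p` plant extinctions
(`0 < R < 1`; higher is more robust). Secondary extinctions follow a
**threshold rule**: a node dies once it has lost a fraction `T` or more of
its original edges (binary networks) or of its total interaction weight
(weighted networks), with `0 < T ≤ 1`. Because whole edges are lost, the
smallest realizable lost fraction for a node of degree `k` is the
**effective threshold** `ceil(T·k)/k` (a degree-5 node at `T = 0.5` dies
after its third lost edge: 3/5 = 0.6).

`knockoutr` implements a directly comparable suite of three extinction
models, each in binary (`b`) and weighted (`w`) form:

- **SO — Secondary Only.** Every plant extinction is an independent,
  uniformly random primary extinction; only pollinators die by the
  threshold rule.
- **DA — Deterministic Avalanche.** The threshold rule applies to both
  guilds, so a random trigger can set off an avalanche of plant and
  pollinator extinctions rippling out through the network.
- **RW — Random Walk.** Extinction jumps from the current plant to a
  neighbour chosen with probability proportional to their number of
  surviving shared pollinators, like a disease spread by shared visitors.

Around the core engine the package provides robustness distributions
`f(R)` over many runs with median `R_m`, per-plant extinction-rank
statistics `h(r)` and their Spearman correlation with degree, threshold
sweeps `T` vs `T_eff` vs `R_m`, ordered (degree-ranked) extinction
sequences, degree-distribution null models (full and one-guild
randomization with L1-closest exemplar selection), structural metrics
(connectance, NODF nestedness, degree skewness), a synthetic network
generator, and a CLI.

## Worked example

The bundled `ac_like` fixture is a synthetic weighted network with
`P = 25` plants, `A = 79` pollinators, `E = 299` interactions and a
strongly skewed plant degree distribution (hub plant of degree 47):

```r
library(knockoutr)
ac <- fixture_library()$ac_like
network_summary(ac)
#>    P  A   E connectance     NODF largest_plant_degree
#> 1 25 79 299   0.1513924 23.18125                   47

node_average_effective_threshold(ac, 0.5)
#> [1] 0.5729307

for (m in c("SO", "DA", "RW")) {
  s <- simulate_ensemble(ac, model_config(m), 2000, master_seed = 1)
  cat(sprintf("b%s: R_m = %.3f IQR = %.3f\n",
              m, s$distribution$median, s$distribution$iqr))
}
#> bSO: R_m = 0.471 IQR = 0.083
#> bDA: R_m = 0.481 IQR = 0.064
#> bRW: R_m = 0.376 IQR = 0.044
```

The characteristic ordering `R_m(DA) > R_m(SO) > R_m(RW)` appears because
the avalanche model preferentially prunes low-degree plants (high-degree
plants resist extinction, rank–degree Spearman ρ > 0) while the random
walk homes in on well-connected plants (ρ < 0):

```r
rw <- simulate_ensemble(ac, model_config("RW"), 2000, master_seed = 1)
rank_degree_correlation(rw$rank_profiles)
#> $rho
#> [1] -0.9764151
```

Degree-ordered sequences bracket the distribution — removing rare plants
first is benign, removing hubs first is catastrophic:

```r
run_ordered(ac, "increasing_degree", model_config("SO"))$R  # 0.670
run_ordered(ac, "decreasing_degree", model_config("SO"))$R  # 0.269
```

## Command line

```sh
Rscript -e 'knockoutr::ko_main()' generate --plants 25 --animals 79 \
    --edges 299 --skew skewed --seed 1 --out net.tsv
Rscript -e 'knockoutr::ko_main()' run --network net.tsv --model da \
    --binary --threshold 0.5 --nsims 25000 --seed 1 --out da
Rscript -e 'knockoutr::ko_main()' metrics --network net.tsv --json
```

Subcommands: `metrics | generate | run | sweep | randomize | report`.
Every writing subcommand emits a JSON manifest with input/output digests;
identical invocations reproduce identical digests.

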