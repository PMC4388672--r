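# isonymia

Population structure from surnames, for double-surname census registers.

In countries using the Spanish double-surname system, every resident
carries a paternal and a maternal surname; treating each as an
independent *token* turns a census register into a large sample of
vertically transmitted, selectively neutral markers. `isonymia`
implements the full analysis chain used in surname population studies:

* **corpus**: parse individual-level rosters, split double surnames into
  tokens, apply the municipal (≥ 5 bearers) and global (≥ 20
  occurrences) frequency cutoffs, aggregate municipalities to regions;
* **isonymy**: isonymy `I_ij = Σ_s n_si n_sj`, Hedrick's
  `H = I_ij / ½(I_ii + I_jj)` and Nei's `N = I_ij / √(I_ii I_jj)`
  similarity coefficients, their `-log` distance transforms, surname
  entropy, and full pairwise region distance matrices;
* **trees**: neighbor joining (deterministic tie-breaking, exact on
  additive matrices), surname-type bootstrap, noise-injected replicates
  for externally supplied distance matrices, and majority-rule consensus
  trees with percent supports and branch collapsing;
* **matrix statistics**: Mantel permutation tests, OLS
  representativeness regressions, percent-agreement (RIW) linguistic
  similarity and its `1 − RIW/100` distance transform;
* **synthetic data**: a roster generator with planted "kingdom"
  clusters, Zipf surname pools, migration, castilianization
  (pool-merging that depresses diversity), single-surname immigrants,
  plus a synthetic geography and dialect features — so the whole
  pipeline is testable without any non-redistributable register;
* **fixtures**: the published 47-province summary of the 2008 Spanish
  municipal register (token counts, isonymy, entropy, ...) and the
  foreign-population composition, with arithmetic audits.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
reference synthetic scenario (3 kingdoms × 4 regions, 10,000 residents
per region, 11.3% immigrants) and write their outputs under `results/`:

```sh
for f in analysis/0*.R; do Rscript "$f" 1; done
```

which prints, among other things:

```
roster: 120000 residents in 12 regions (3 kingdoms); 8958 (7.5%) single-surname
tokens: 231042 raw -> 212141 after municipal cutoff -> 211289 after global cutoff
12 regions x 192 surnames; isonymy 0.2020-0.2090, entropy 2.48-2.52
nei consensus: 6 retained splits (0 replicates rejected)
  planted kingdom supports: K1=100, K2=100, K3=100
noisy-clustering consensus: 3 retained splits; kingdom supports: K1=100, K2=100, K3=100
              comparison         r p_value
    surname_vs_geography 0.7962900   1e-04
 linguistic_vs_geography 0.7887151   1e-04
representativeness regression (n = 44): slope -0.00107, adj R2 = 0.232, p = 0.000544
```

Reading: the three planted kingdoms are recovered by the bootstrap NJ
consensus of the Nei surname distance with 100% support (branches under
50 would be collapsed); the noisy-clustering consensus of the linguistic
`1 − RIW` matrix recovers the same clusters at the stricter cutoff of
90; surname and linguistic distances both track the planted geography
(Mantel p = 1e-4); and on the packaged province table, tokens-per-capita
falls significantly with the number of municipalities per province
(adjusted R² = 0.23, p = 0.000544, the three large-agglomeration
provinces excluded from the fit).

The same machinery is available programmatically:

```r
library(isonymia)
sc <- generate_scenario(scenario_config(seed = 1))
res <- run_pipeline(sc$roster, pipeline_config(seed = 1),
                    coords = generate_geography(sc$truth, seed = 2))
res$consensus          # majority-rule consensus with percent supports
res$diversity          # random isonymy and entropy per region
```

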