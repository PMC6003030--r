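# tplcea

Decision-analytic cost-effectiveness model for diagnostic triage of
**threatened preterm labor (TPL)** in singleton pregnancy at 24–34 weeks of
gestation.

Most women admitted with contractions and intact membranes do not deliver
within seven days. A triage test that flags the minority who will lets
clinicians hospitalize and treat them (tocolysis, antenatal steroids,
in-utero transfer) while sending the rest home. `tplcea` compares seven such
strategies — cervical length (CL) thresholds, qualitative and quantitative
fetal fibronectin (fFN), cervical interleukin-6, a CL/RANTES/IL-10
combination, and the combined rule "CL < 15 mm, or CL 16–30 mm with positive
qualitative fFN" (S7) — on two payoffs per mother–child pair: expected
direct medical cost (2012 €) and the expected probability of a serious
neonatal adverse event (perinatal death or severe neonatal morbidity).

## The model in brief

For incidence $p$ of delivery within 7 days and a test with sensitivity
$Se$ and specificity $Sp$, the decision tree splits each gestational-age
(GA) stratum (24–27, 28–31, 32–34 weeks) into the contingency cells
$p\,Se$, $p(1-Se)$, $(1-p)(1-Sp)$, $(1-p)Sp$. Positives are admitted and
treated; 7-day deliverers deliver at the entry week (treated or not);
everyone else enters a weekly Markov model — states HOME, REHOSP and
absorbing delivery — run to 37 weeks, with a constant weekly re-admission
hazard solved so the cumulative re-admission probability matches its
published target. Deliveries are priced, and neonatal outcomes drawn, at
the GA of the week they occur. Strategies are ranked by cost with simple
and extended dominance, and incremental cost-effectiveness ratios

$$\mathrm{ICER} = \frac{\Delta \text{cost}}{\Delta \text{adverse events}}$$

are reported in € per additional serious adverse event. Deterministic
scenarios (incidence 5%/15%, joint min/max test accuracy) and a seeded
5,000-iteration probabilistic sensitivity analysis (beta/gamma/log-normal
fits, cost-effectiveness-plane quadrants) complete the pipeline. An
individual-level microsimulation with the identical probabilistic structure
acts as a brute-force oracle for the cohort arithmetic. See the methods
vignette (`vignettes/tpl-cea-model.Rmd`) for assumptions, free-parameter
calibration and known limitations.

## Worked example

Ranking the seven published base-case (cost, adverse-event) pairs:

```r
library(tplcea)
rank_strategies(table3_targets())
#> Cost-effectiveness ranking
#> # A tibble: 7 × 6
#>   strategy  cost adverse status    icer_frontier icer_vs_cheapest
#>   <chr>    <dbl>   <dbl> <chr>             <dbl>            <dbl>
#> 1 S7        3237  0.0233 frontier             NA               NA
#> 2 S3        4344  0.0256 dominated            NA           481304
#> 3 S2        4385  0.026  dominated            NA           425185
#> 4 S_ref     4400  0.0262 dominated            NA           401034
#> 5 S4        4415  0.0264 dominated            NA           380000
#> 6 S5        4431  0.0266 dominated            NA           361818
#> 7 S6        4718  0.0275 dominated            NA           352619
```

S7 is the least costly *and* most effective strategy; every alternative is
simply dominated, and `icer_vs_cheapest` gives the € paid per additional
adverse event under each alternative (e.g. 352,619 € for CL < 15 mm alone).
The headline contrast against CL < 15 mm:

```r
headline_summaries(table3_targets(), reference = "S7")
#> # A tibble: 6 × 6   (S6 row)
#>   reference comparator cost_saving_eur events_avoided_per_1000 ...
#> 6 S7        S6                    1481                     4.2
```

— a saving of 1,481 € per mother–child and 4.2 serious neonatal adverse
events avoided per 1,000 newborns (31% of cost, 15% of events). The full
model pipeline runs from the built-in parameter fixture:

```r
params <- tpl_parameters()                 # published inputs, Tables 1-2
classify(0.097, 0.89, 0.70)                # S7 contingency structure
cal   <- calibrate_parameters(params)      # fit the unpublished free knobs
draws <- run_psa(cal$params, n_iter = 5000, seed = 20180614)
quadrant_summary(draws, "S7", "S6", "24-27")
autoplot(draws, "S7", "S6", "24-27")       # CE-plane scatter
```

A thin command-line wrapper (`inst/cli/tplcea.R`) exposes
`base-case | dsa | psa | calibrate | simulate` with `--config`, `--out`,
`--ga`, `--n-iter`, `--seed`.

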