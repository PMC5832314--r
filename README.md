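# omfingr

Source fingerprinting of river-bed sediment-associated organic matter, with
Monte Carlo uncertainty analysis, plus the sediment oxygen demand (SOD)
computation chain for laboratory incubations.

Organic matter ingressing river substrates consumes dissolved oxygen as it
decays, threatening gravel-spawning fish and benthic ecology. Targeting
mitigation requires apportioning that material among its upstream sources.
`omfingr` implements the full workflow for four source categories —
farmyard manures or slurries, damaged road verges, decaying instream
vegetation, and human septic waste — from tracer properties measured on
composite samples: δ¹³C, δ¹⁵N, %TOC, %TN and near-infrared constituent
band intensities. It is aimed at catchment scientists and environment
agencies running reconnaissance surveys of sediment-associated OM pressure.

## The method

1. **Bracket (mass-conservation) screening** — per subcatchment, a tracer
   is retained only if the sediment range lies inside the envelope of all
   source sample values (`bracket_test`).
2. **Composite signature selection** — three routes over the passing
   tracers (`select_ga_dfa`, `select_kw_h`, `select_pca`): a genetic
   algorithm minimizing Wilks' λ of a stepwise linear discriminant fit
   (entry p ≤ 0.05), Kruskal–Wallis *H* ranking, and PCA loading ranking.
   Each tracer gets a discriminatory weighting
   `W_i = pct_i / min(pct)` (`tdw`), the weakest tracer scoring exactly 1.
3. **Weighted mass-balance unmixing** (`solve_mixing`) — minimize

   ```
   sum_i  W_i * SVbar_i(P) * ((C_i - sum_s P_s S_si) / C_i)^2
   ```

   over the proportion simplex, where `C_i`/`S_si` are sediment/source
   medians and `SV_si = 1/CV` down-weights tracers that vary within a
   source. Goodness of fit is `1 - AMRE` between predicted and measured
   sediment values (`mixing_gof`).
4. **Monte Carlo uncertainty** (`run_monte_carlo`) — all medians perturbed
   jointly by Latin hypercube draws from Normal(median, Qn) truncated to
   observed ranges (Qn = Rousseeuw–Croux robust scale, `qn_scale`); 5,000
   solutions with GOF > 0.85 accepted by default; accepted proportions
   binned into relative-frequency posteriors whose weighted mean
   `R = sum v_i F_i` is the reported contribution.
5. **Combination** (`combine_signatures`, `catchment_summary`) — five
   signatures per subcatchment combined with weights GOF × classification
   %, then averaged across subcatchments.

The SOD chain (`compute_sod`, `run_sod`) converts 25-day headspace O₂
series into consumption rates `(m1 - m2)/t`, blank-corrects, normalizes to
20 °C by the Van't Hoff factor `1.065^(20-T)` (valid for T ≥ 10 °C),
integrates SOC over 0–5 and 0–20 days, and divides by dry sediment mass to
give SOD₅/SOD₂₀ in mg O₂ g⁻¹.

A synthetic-data generator (`source_model`, `generate_sources`,
`generate_sediment`, `generate_incubation`) emulates the sampling design
with known true proportions, so every stage is testable end to end.

## Worked example

Simulate one subcatchment with known truth (0.50, 0.30, 0.15, 0.05) and
run the full pipeline:

```r
library(omfingr)
model <- source_model(panel = tracer_panel(paste0("B", 1:8), kind = "isotope"),
                      n_samples = 8)
src <- generate_sources(model, seed = 11, subcatchment = "demo")
des <- mixture_design(c(0.5, 0.3, 0.15, 0.05))
sed <- generate_sediment(model, des, seed = 12, sources = src,
                         subcatchment = "demo")
run <- run_apportionment(src, sed, model$panel,
                         pipeline_config(seed = 1, n_accept = 500,
                                         ga_repeats = 5))
run$combined_table
```

This prints the per-signature acceptance log and then the combined
apportionment:

```
apportionment run: config 7125c3c8, seed 1
  demo / GA-DFA (B1+B4+B5+B6+B7): accepted 500 of 500 draws, mean GOF 0.982
  ...
  demo / PCA (B2+B5+B6+B7): accepted 500 of 500 draws, mean GOF 0.983
  subcatchment     category proportion
1         demo     farmyard       0.47
2         demo   road_verge       0.26
3         demo instream_veg       0.23
4         demo       septic       0.04
```

Each proportion is the GOF-and-discrimination weighted combination, across
the five selected signatures, of the frequency-weighted average median
contribution of that source — here within a few hundredths of the
generating truth, with the residual shrinkage toward the simplex interior
that posterior means of wide, truncated distributions exhibit.

The numbered scripts under `analysis/` run the same workflow at catchment
scale: `01_simulate.R` (six subcatchments with distinct true mixtures),
`02_screen_select.R` (bracket reports and signature tables),
`03_apportion.R` (per-signature and combined apportionments, posterior
histograms, recovery vs truth), `04_sod.R` (site-level SOD₅/SOD₂₀ from
synthetic incubations). Outputs land under `results/`.

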