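# lesionatoms

Tract-wise lesion-symptom mapping for ischemic stroke, with sex-stratified
Bayesian prediction of language outcomes.

After a stroke, the pattern of white-matter damage — not just its volume —
shapes whether and how severely a patient becomes aphasic, and women and men
are affected in measurably different ways. `lesionatoms` implements a
complete analysis pipeline for studying this in large cohorts:

1. **Quantification.** Binary lesion masks are summarized against a
   28-tract left/right-paired white-matter atlas into a non-negative lesion
   load matrix `V` (tracts × patients), then `log2(1 + x)` stabilized.
2. **Lesion atoms.** Non-negative matrix factorization `V ≈ W H`
   (`W`: tracts × k basis, `H`: k × patients expressions, k = 10 by default)
   discovers latent, strictly additive patterns of co-occurring tract damage
   — *lesion atoms*. Each atom is characterized by its hemispheric
   lateralization index `LI = (L − R)/(L + R)` over its left/right tract
   loadings and named by its highest-weighted tracts; atoms are ranked for
   clinical relevance by the summed absolute Pearson correlation between
   their expressions and the cohort's cognitive scores.
3. **Outcome model.** For each language score (Boston naming, semantic and
   phonemic fluency, z-scored), a Bayesian linear model with sex-indexed
   atom slopes is fitted:

   ```
   outcome = α + β₁[sex]·atom₁ + … + β₁₀[sex]·atom₁₀
           + β_vol·lesion volume + β_age·age + β_age²·age²
           + β_edu·education + β_IQCODE·IQCODE + β_m·male + β_f·female + ε
   ```

   with Normal(0, 1) priors on the intercept, atom, lesion-volume, IQCODE
   and sex-indicator terms, Normal(0, 10) on age and age², Normal(0, 5) on
   education, a half-Normal(1) prior on the noise scale, and a Gaussian
   likelihood. Posteriors are summarized by posterior means and 80%
   highest-density intervals; an atom is flagged *relevant* for a sex
   stratum when its HDI excludes zero. Model fit is reported as
   posterior-predictive R².
4. **Cohort characterization.** Per-sex summaries and Welch t tests
   reproduce standard cohort tables directly from group means, SDs and
   sizes.

Because the underlying patient registry is not public, the package ships a
first-class synthetic-data module that emulates a 1401-patient cohort (42%
women, age 67.58 ± 11.59), a mirror-symmetric 28-tract atlas, planted
non-negative atom structure and model-consistent outcomes — retaining the
ground truth so that every stage is testable by recovery.

## Worked example

```r
library(lesionatoms)
library(dplyr)

cfg <- lesion_config(seed = 7, draws = 1000, warmup = 250)
sim <- simulate_cohort(cfg, n_patients = 500, masks = FALSE)

V   <- sim$ground_truth$W_true %*% sim$H        # planted load matrix
dec <- fit_nnmf(log2(1 + V), k = 10, seed = 1) |> normalize_and_order_atoms()

atom_summary(dec, sim$atlas) |> select(atom, li, name) |> head(4)
#>    atom      li name
#> 1     1  0.0114 internal_capsule_R + internal_capsule_L + corpus_callosum
#> 2     2 -0.374  cingulum_R + fornix_R + optic_radiation_R
#> 3     3  0.213  cst_L + cst_R + middle_cerebellar_peduncle
#> 4     4  0.405  arcuate_long_L + arcuate_anterior_L + arcuate_long_R
```

Atom 4 is a left-lateralized (LI = 0.41) dorsal perisylvian pattern; atom 2
a right-dominant limbic one. Ranking and the Boston-naming model:

```r
atom_outcome_correlations(dec$H, sim$cohort[cfg$outcome_names]) |>
  rank_atoms() |> head(3)
#>    atom score  rank
#> 1     4 0.627     1     # highest summed |r| across the three outcomes
#> 2    10 0.561     2
#> 3     9 0.493     3

fit <- build_design(sim$cohort, dec$H, "boston_naming") |>
  fit_outcome_model(draws = 1000, chains = 4, warmup = 250, seed = 2)
tidy(fit) |> filter(relevant, !is.na(atom)) |> head(4)
#>   term           stratum atom      pm     sd hdi_lower hdi_upper relevant
#> 1 atom_01_female female     1 -0.129  0.0561   -0.202    -0.0572 TRUE
#> 2 atom_04_female female     4 -0.345  0.0590   -0.413    -0.263  TRUE
#> 3 atom_05_female female     5  0.0929 0.0522    0.0234    0.157  TRUE
#> 4 atom_06_female female     6  0.191  0.0568    0.116     0.261  TRUE

posterior_predictive_r2(fit, seed = 3)
#> [1] 0.446
```

Row 2 reads: in women, one standardized unit more expression of atom 4
predicts a 0.35 SD worse naming score, with an 80% HDI of [−0.41, −0.26]
that excludes zero — a relevant effect. The model explains ~45% of outcome
variance here (the generator plants a theoretical R² of 0.5).
`autoplot(dec)`, `plot_lateralization()`, `autoplot()` on the posterior
summary and `plot_ranking()` give the matching figures, and
`run_pipeline(cfg, "out/")` writes every stage as CSV plus a JSON manifest.
A command-line front end with `simulate`, `quantify`, `atoms`, `model` and
`report` verbs is in `inst/cli/lesionatoms.R`.

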