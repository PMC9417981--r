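# dfnmrd

Standardized, fixed-gate flow-cytometric detection of measurable residual
disease (MRD) in acute myeloid leukemia (AML), for hematology labs and
methods researchers who need a reproducible, auditable LAIP-based
different-from-normal (DfN) analysis rather than expert-dependent manual
gating.

## The approach

A single eight-antibody tube (CD7, CD13, CD33, CD34, CD45, CD56, CD117,
HLA-DR plus scatter) is analyzed with a hierarchical gating cascade in
which only the doublet/debris, leukocyte, progenitor-monocyte (P/M) and
lymphocyte gates are adjustable — every marker gate is a fixed threshold:

1. singlets (|FSC-A/FSC-H − 1| bounded), non-debris, CD45⁺ leukocytes;
2. P/M and lymphocyte regions on CD45 vs SSC;
3. **myP/M**: P/M events expressing CD13 and/or CD33;
4. 8 main populations from the backbone CD34±/CD117±/HLA-DR±;
5. 4 aberrant categories — deficiency (true absence) of CD13 or CD33,
   strong cross-lineage CD7 or CD56 — giving **32 subpopulations**, of
   which 24 carry a marker of immaturity (CD34⁺ and/or CD117⁺).

For each subpopulation *s*, the reference value *r\_s* is the upper
limit of the one-sided 97.5% reference range of its frequency (% of
CD45⁺ events) across leukemia-free controls (bone-marrow donors, ALL in
molecular remission, hip-surgery patients, untreated PCNSL), estimated
nonparametrically and attributed to the control cohort that determines
the quantile. At follow-up, only subpopulations with ≥ 20 events are
analyzed; the sample is **MRD⁺** iff some analyzed subpopulation has
frequency *p\_s* > *r\_s*. The excess *p\_s − r\_s* (disease burden, %
of CD45⁺) is summed within each aberrant category and

```
MRD load = max over categories c of  Σ_{s ∈ c, p_s > r_s} (p_s − r_s)
```

A positive category that already affected ≥ 10% of myP/M at diagnosis
(aLAIP) marks reoccurrence; a de-novo category is post-treatment DfN
(ptDfN). Alternative schemes: ELN-style flat 0.1% cutoff on the 24
immature subpopulations, an immature-only restriction with unchanged
references, and a Lo/Hi split at a maximum excess of 0.1. Inter-rater
reliability of frequencies (ratio metric) and MRD status (nominal) is
quantified with Krippendorff's α.

A synthetic bone-marrow simulator (Gaussian population components on the
transformed scale, zero-inflated lognormal background aberrancies with
cohort-specific tails, leukemic clones at configurable residual
fractions) provides exact ground truth, so the whole pipeline is
testable without patient data.

## Worked example

```r
library(dfnmrd)

cohort <- generate_lfc_cohort(n_samples = 90, n_events = 60000, seed = 1)
panel  <- estimate_reference(cohort$tables)
summary(panel)

clone <- clone_spec(cd34 = TRUE, cd117 = TRUE, hladr = FALSE,
                    categories = c("CD13neg", "CD56pos"), fraction = 0.3)
pair  <- generate_patient_pair(clone, residual_fraction = 0.01,
                               seed = 8, n_events = 500000)
run_pipeline(pair$followup$events, gate_config(), panel,
             diagnosis = pair$diagnosis$events)
```

which prints:

```
MRD reference panel (nonparametric type-7 quantile, p = 0.975) from 90 leukemia-free controls
Cohorts: ALL_molCR (n=19), BMD (n=30), hip_surgery (n=32), PCNSL (n=9)
Reference range: 0.04106% - 0.3393% of CD45+ events
Reference values mainly influenced by:
  ALL_molCR: 16/32 (50%)
  hip_surgery: 9/32 (28%)
  BMD: 7/32 (22%)
=== MRD report (schema 1.0) ===
Sample: followup (followup)
Gating: 500000 events -> 475000 singlet non-debris -> 446500 CD45+ -> 65518 P/M -> 55048 myP/M
Main populations (% of CD45+): CD34+CD117+HLA-DR+ 2.10; CD34+CD117+HLA-DR- 1.00; ...
MRD call for followup (N_CD45 = 446500, min 20 events/subpopulation)
  status: MRD-pos (Hi)  load 0.9415% of CD45+ [CD56pos]  origin: aLAIP_only
  alternative schemes: ELN 0.1% = pos, immature-only = pos
  positive subpopulations:
                         id count pct ref_pct burden
 CD34+CD117+HLA-DR- CD13neg  4465   1  0.1630 0.8370
 CD34+CD117+HLA-DR- CD56pos  4465   1  0.0585 0.9415
  30/32 subpopulations below the 20-event minimum
Hashes: gates af06e92f, reference 54cfa618
```

Reading it: the residual clone (1% of CD45⁺, backbone CD34⁺CD117⁺HLA-DR⁻,
CD13-deficient and CD56⁺) exceeds both of its subpopulation references;
the CD56pos category carries the larger summed excess, so it quantifies
the load (0.94% of CD45⁺, class Hi since the excess ≥ 0.1). Both
categories were aLAIP at diagnosis, hence origin `aLAIP_only`. The
report embeds content hashes of the gate configuration and reference
panel so the fixed-gate premise is auditable.

## Acceptance script

`scripts/acceptance.R` re-runs the full computation from scratch —
simulates the 90-sample leukemia-free cohort (30/19/32/9 cohort mix),
estimates the 32 reference values with cohort attribution, simulates a
paired diagnosis/follow-up patient with a residual clone, and produces
the MRD report — then writes its JSON output:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Command line

```sh
Rscript inst/cli/dfnmrd.R simulate  --kind lfc --n-samples 90 --seed 1 --out lfc/
Rscript inst/cli/dfnmrd.R reference --manifest manifest.csv --out ref.json
Rscript inst/cli/dfnmrd.R call      --events followup.csv --reference ref.json \
                                    --diagnosis diagnosis.csv --out report.json
Rscript inst/cli/dfnmrd.R irr       --ratings ratings.csv --metric nominal
```

See `vignettes/dfn-mrd-methods.Rmd` for the modeling assumptions,
default calibration and known limitations.
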