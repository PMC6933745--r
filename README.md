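# biatools

Benefit incidence analysis (BIA) of public health subsidies from household
survey microdata, built for the question of who captures the implicit
subsidy in public-sector care for noncommunicable diseases (NCDs) among
the elderly: the poorest classes the subsidy is meant to reach, or the
richer classes who use the facilities more.

Public facilities charge users far less than private ones, so every public
episode of care carries a subsidy. `biatools` estimates and distributes it:

1. **Stratification** — equivalized monthly per-capita expenditure
   (MPCE = T/√N, OECD square-root scale), survey-weighted quartile classes
   P / LM / UM / R formed separately per (state, sector); ailments grouped
   into CD / NCD / OD via a configurable map; the elderly (60+) NCD
   episode selection, including the all-visits-NCD rule for outpatient
   spells whose out-of-pocket expenditure (OOPE) is pooled across visits.
2. **Descriptive tables** — weighted utilization shares and mean OOPE
   (medicine ≤ medical ≤ total) by class, sector and facility.
3. **Subsidy estimation** — the cost of public provision proxied by the
   *modal* private total OOPE per stratum (state × sector × class ×
   illness-duration band), estimated by fixed-width binning with a pooling
   ladder for sparse strata; net subsidy γ = modal cost − user charges,
   clamped at zero by default.
4. **Benefit incidence** — class utilization rates δ_j of public care and
   benefit π_j = δ_j · Σ_{k∈j} w_k γ_k, reported as percentage shares.
5. **Equity summary** — concentration curves (cumulative subsidy share vs
   cumulative population share ranked by MPCE; above the 45° line =
   pro-poor) with household-bootstrap 95% bands, and concentration indices
   C = (2/μ)·cov_w(h, r) with heteroskedasticity-robust (or
   household-clustered) standard errors via the convenient regression.
6. **Synthetic data** — a generator (`simulate_survey()`) that plants a
   known equity structure (facility-choice gradient, class cost gradient,
   mode-parameterized private costs) and returns the ground truth, so
   every stage is testable against known answers.

## Worked example

```r
library(biatools)

sim    <- simulate_survey(sim_config(n_states = 2, households_per_cell = 5000,
                                     seed = 42))
result <- run_bia(sim$dataset)
result
#> <bia_result>
#> Benefit-incidence shares (%):
#>   service sector      P    LM    UM     R
#> 1 IP      combine  51.2  20.9  23.6  4.25
#> 2 IP      rural    35.3  30.8  30.7  3.22
#> 3 IP      urban    59.0  15.2  20.5  5.30
#> 4 OP      combine  30.4  33.5  25.8 10.3
#> 5 OP      rural    32.7  35.4  19.8 12.1
#> 6 OP      urban    28.3  31.2  31.6  8.84
#>
#> Concentration indices:
#>   service sector  n_obs   index robust_se  p_value
#> 1 IP      combine   197  0.102     0.0226 1.03e- 5
#> 2 IP      rural     104  0.141     0.0247 1.14e- 7
#> ...
```

The share table says where each class's slice of the total public subsidy
lands (the default gradient plants pro-private choice among the rich, so
the poor dominate public utilization and its δ-weighted benefit shares);
the index table summarizes each curve: a positive index means the subsidy
distribution leans pro-rich across the MPCE ranking, with its robust SE
and p-value from the convenient regression. `plot_concentration()` draws
any of the curves with its equality line and bootstrap band, and
`write_bia_tables()` exports all tables as CSV.

The package also ships published reference benefit shares for elderly NCD
care in India:

```r
ref <- reference_benefit_shares()
grouped_index_from_table(ref, "IP", "rural")   # 0.18995  (pro-rich)
grouped_index_from_table(ref, "OP", "rural")   # -0.09932 (pro-poor)
```

A thin command-line front-end over the same functions lives at
`inst/cli/biatools.R` (subcommands `simulate`, `classify`, `tables`,
`bia`, `concentration`).

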