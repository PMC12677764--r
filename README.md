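# sedverify

Lint, repair, and cross-engine verification of simulation-experiment
archives (COMBINE/OMEX bundles of SBML kinetic models with SED-ML
experiment descriptions).

Curated model repositories are full of experiment files that have never
been executed: model references that point to files that do not exist,
broken XPath pointers, simulations nothing uses, duplicated elements,
requests for millions of output points, parameters initialized to infinity.
`sedverify` is for curators and modelers who want such archives to be
*verifiable* — demonstrably runnable, and demonstrably yielding the same
numbers on independent simulator implementations.

The package provides:

* **Archive I/O** — read/write OMEX (ZIP + manifest), tolerate legacy
  manifest-less archives, scan and normalize file hygiene.
* **Lint & repair** — a ten-rule defect catalogue (R1–R10) with automatic,
  idempotent repair; unrepairable defects stay reported, never guessed at.
* **Template generation** — for a model with no experiment: a time course
  over ten time units exporting every variable species, as report and plot.
* **Two independent ODE engines** — a Dormand–Prince 4(5) integrator
  written in the package, and a BDF multistep integrator via `deSolve`,
  both honoring a per-variable absolute-tolerance vector
  (`atol_i = factor · |x_i(0)|`, floored at the factor for zero starts).
* **Verification** — an element-wise criterion with relative tolerance
  `1e-4` and absolute tolerance scaled by each column's value range,
  summarized as a **match score**: the maximum tolerance-normalized
  deviation, so *score ≤ 1 ⇔ the pair matches*. Pairs aggregate per model
  into an agreement size (largest all-pairs-matching engine set) and a
  reproducibility level: `functional` (template experiment verified),
  `end_to_end` (curation-derived experiment verified), or `unverified`.

For the mathematical details — the score formula, the compilation of SBML
to ODEs, rule ordering, fixture design — see the methods vignette,
`vignettes/verification-methods.Rmd`.

## Worked example

```r
library(sedverify)

# a synthetic archive: X0 -> X1 -> X2 decay chain + generated template
a <- gen_decay_chain(2, c(0.1, 0.25))
a
#> <omex_archive> 2 entries
#>   decay_chain_2.xml                2515 B  SBML
#>   decay_chain_2.sedml              2802 B  SED-ML  [master]

lint(a)            # 0 rows: the archive is clean
#> [1] rule_id    severity   location   message    repairable
#> <0 rows> (or 0-length row.names)

rk <- execute_experiment(a, "rk")      # Dormand-Prince 4(5)
st <- execute_experiment(a, "stiff")   # BDF via deSolve
rk
#> <run_result> rk - succeeded
#>   report1: 101 x 4
#>   plot1: 101 x 6

compare_results(rk, st)
#> <pair_comparison> rk vs stiff: compared, score 5.248e-05 -> MATCH

aggregate_runs("decay_chain_2", "template", list(rk, st))
#> <model_verification> decay_chain_2 [template]: 2/2 runs succeeded,
#>   1/1 pairs matched, agreement 2 -> functional
```

The report matrix is 101 output points × (time + 3 species); the match
score 5.2·10⁻⁵ says the two engines' worst element-wise deviation is about
five thousandths of its tolerance envelope, far inside the cutoff of 1. The
first species tracks the closed form: `rk$reports$report1[101, "X0"]` is
3.678794, i.e. 10·e⁻¹.

Breaking the archive and repairing it:

```r
bad <- corrupt_archive(a, "R1")   # SED-ML now points to 'model.xml'
lint(bad)$message
#> "model source 'model.xml' does not exist (resolves to 'decay_chain_2.xml')"
fixed <- repair(bad)
fixed$actions
#>   rule_id location    before                 after
#> 1      R1   model1 model.xml     decay_chain_2.xml
identical(execute_experiment(fixed$archive, "rk")$reports, rk$reports)
#> [1] TRUE
```

## Command line

A thin wrapper is installed in `exec/`:

```sh
sedverify lint ARCHIVE [--json out.json]          # exit 3 if errors found
sedverify repair ARCHIVE --o fixed.omex [--clamp-points] [--point-cap N]
sedverify template MODEL.xml --o archive.omex
sedverify run ARCHIVE --engine all --o results/   # CSV per report
sedverify verify ARCHIVE --o report.json          # exit 4: no matched pair
                                                  # exit 5: <2 successful runs
sedverify fixtures make stiff --o stiff.omex [--corrupt R7]
sedverify report verify1.json verify2.json --o summary.json
```

Exit codes: 0 success/verified, 2 usage, 3 lint errors, 4 compared but
mismatched, 5 could not compare. A YAML `--config` file can supply any
flag's default; explicit flags win.

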