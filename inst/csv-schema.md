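# CSV output schemas

All numeric values are written at full double precision (`%.17g`) so
equal seeds give byte-identical files.

## switching_model.csv  (`write_switching_csv`)

One row per Hill function.

| column | type | meaning |
|---|---|---|
| name | string | `A1`, `A2`, `R1`, `R2` (3-state) or `p1`, `p2` (2-state; `p1` alone in the dependent parameterization) |
| K | number | effective concentration (µg/ml) |
| H | number | Hill coefficient |

## population_dox_NN.csv  (`write_population_csv`)

One row per cell.

| column | type | meaning |
|---|---|---|
| dox | number | dox concentration (µg/ml) of this population |
| cell_index | integer | 1..n_cells |
| X_final | number | expression at the final recorded cycle (a.u.) |

## population_summary.csv  (`cmd_simulate`)

| column | type | meaning |
|---|---|---|
| dox | number | dox concentration (µg/ml) |
| mean_X | number | ensemble mean at the final cycle |
| sd_X | number | ensemble standard deviation |

## dose_response_<chain>.csv  (`write_dose_response_csv`)

One row per dose, sorted ascending.

| column | type | meaning |
|---|---|---|
| dox | number | dox concentration (µg/ml) |
| mean_X | number | ensemble mean expression |
| sd_X | number | ensemble SD |
| norm_mean | number | min–max normalized mean in [0, 1] |

## prediction_report.csv  (`cmd_predict`)

Long format, one quantity per row.

| column | type | meaning |
|---|---|---|
| quantity | string | `H_activator`, `H_repressor`, `H_combined`, `se_H_combined`, `K_combined`, `calc_add`, `calc_mult`, `observed_act`, `observed_rep`, `observed_combined` |
| value | number | the quantity |

Ensemble traces (`ensemble_mean_trace`) are plain data frames with
columns `cycle`, `mean_X`, `sd_X` and can be written with
`utils::write.csv`.

Every command also writes `run_record.yaml`: the configuration snapshot,
seeds, package version, timestamp, a `scaled` flag (config departs from
the 10,000-cell / 34-dose defaults) and an MD5 manifest of all outputs.
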