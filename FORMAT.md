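# File formats

All tabular interchange uses one dialect: tab-separated values, UTF-8,
header row, no quoting, "." as the decimal separator. COG identifiers are
opaque strings matched case-sensitively (any orthology vocabulary works);
missing (COG, dataset) cells mean a count of zero.

## Count matrix (`read_cog_counts(path, format = "matrix")`)

| column | type | meaning |
| --- | --- | --- |
| 1st (any name) | string | COG identifier, unique |
| one per dataset | non-negative integer | reads assigned to the COG in that dataset |

Column sums are the per-dataset library sizes (total assigned reads).

## Read assignments (`read_read_assignments()`, `format = "reads"`)

| column | type | meaning |
| --- | --- | --- |
| `read_id` | string | unique within its dataset |
| `dataset_id` | string | dataset the read belongs to |
| `cog_id` | string | best-hit functional assignment |
| `superkingdom` | string | `Bacteria`, `Archaea`, `Eukarya` or `unidentified` |
| `phylum` | string | best-hit phylum; empty/`NA` when unidentified |

## Dataset metadata (`read_metadata()`)

| column | type | meaning |
| --- | --- | --- |
| `dataset_id` | string | unique |
| `site` | string | sampling site; datasets of one water column share it |
| `depth_m` | non-negative real | sampling depth (m) |
| `do_umol_kg` | non-negative real | dissolved oxygen (µmol/kg) |
| `par_surface` | real, optional | surface PAR (µmol photons m⁻² s⁻¹) |
| `par_at_depth` | real, optional | measured PAR at `depth_m` |
| `attenuation_k` | positive real, optional | diffuse attenuation (1/m); used to derive `par_at_depth` when absent |
| `zone_label` | string, optional | `photic` / `aphotic` / `unset` |

A zone call needs `par_at_depth`, or `par_surface` + `attenuation_k`.

## Result tables (`write_result_table()` / `read_result_table()`)

Generic rectangular TSVs with the columns named by the producing stage
(typically `cog_id`, `statistic`, `p_value`, `p_adj`, `direction` or
`group`, `significant`). Numbers round-trip to at least 12 significant
digits. Dendrograms are written as newick with bootstrap supports
(percent) as internal node labels; the pipeline summary is JSON.
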