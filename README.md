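# clonescape

Reconstruction of the subclonal architecture of drug-resistant cancer cell
populations from paired parental/resistant sequencing, plus the droplet
digital PCR and preclinical computations that accompany such studies.

When a sensitive cancer cell line is cultured under drug until resistant
derivatives emerge, the resistant population is a mixture of related
subclones: truncal alterations shared by every cell, and branch
alterations defining clonal sweeps that happened during the evolution of
resistance. `clonescape` implements the full desk-side analysis chain:

* **Somatic subtraction** — the acquired-mutation catalogue of each
  resistant derivative: every variant key `(chrom, pos, ref, alt)` present
  in the resistant sample but absent from its parental line; shared vs
  private classification across derivatives.
* **Gene copy number (GCN)** — per-gene depth ratios from exome target
  regions: `GCN(g) = median(depth of g's regions) / median(all regions)`.
* **Cellular prevalence** — fraction of cells carrying a variant:
  `CP = min(1, VAF × copies / multiplicity)`.
* **Subclone clustering** — a 1-D Gaussian mixture over prevalences with
  per-variant standard deviations fixed at their binomial counting error
  and the number of subclones selected by BIC (a fixed-bandwidth KDE
  engine is also provided).
* **Clone-tree reconstruction** — clusters are nested by the pigeonhole
  sum rule into a clones × mutations incidence matrix; ancestry follows by
  recursive subset containment (the clone whose mutations appear first is
  the father; clones carrying those mutations plus new ones attach below,
  recursively). Branch lengths count novel variants; node labels count the
  non-synonymous variants defining each sweep; Newick export included. An
  exhaustive-enumeration oracle verifies the recursion in the test suite.
* **ddPCR quantification** — Poisson occupancy `λ = −ln(Nneg/N)` with
  delta-method 95% CIs, concentrations, fractional abundance
  `F.A.% = Nmut/(Nmut+Nwt) × 100` (raw and Poisson-corrected), and
  mixed-population detection for single-cell dilution clones.
* **Preclinical metrics** — xenograft tumour volume `V = d²D/2`, the 10%
  randomisation-validity rule, TOP/FOP reporter ratios, growth-curve
  summaries.
* **Synthetic-data module** — generates ground-truth clone trees, read
  counts, depth profiles, droplet counts and single-cell wells with known
  parameters, so every stage of the pipeline is validated end to end
  without external sequencing data.

## Worked example

Simulate a five-clone resistant population at 300× depth and run the full
pipeline — subtraction, copy number, clustering, tree:

```r
library(clonescape)

run <- run_pipeline(list(
  seed = 10L, outdir = "demo",
  simulate = list(n_clones = 5, mean_depth = 300,
                  min_prevalence_gap = 0.15, sequencing_error_rate = 0)))
print(run)
#> Pipeline run (seed 10): 87 acquired variants -> 5 subclones
#> tree: ((((C5_sweep9:17)C4_sweep11:13)C3_sweep12:17)C2_sweep9:14)C1_sweep17:26;
#> vs truth: RF = 0, prevalence RMSE = 0.0197, acquired Jaccard = 1.000

print(run$clusters)
#> Subclone clusters: 5 populations (0 variants filtered out)
#>  cluster prevalence n_total n_nonsynonymous
#>       C1  0.9947169      26              17
#>       C2  0.8035598      14               9
#>       C3  0.6120924      17              12
#>       C4  0.4434096      13              11
#>       C5  0.2599269      17               9
```

The report reads: 87 acquired variants survived parental subtraction
(exactly the simulated truth — Jaccard 1.0), they cluster into five
subclonal populations whose cellular prevalences (0.99 … 0.26) are
recovered to RMSE 0.02, and the containment recursion reconstructs the
true linear sweep topology (Robinson–Foulds distance 0). In the Newick
string, `C3_sweep12:17` is a clone whose sweep is defined by 12
non-synonymous variants among the 17 it newly acquired.

A ddPCR well is quantified directly from droplet counts:

```r
q <- quantify_well(ddpcr_well("A01", n_droplets = 15000,
                              pos_mut = 1200, neg_mut = 13800,
                              pos_wt = 9000, neg_wt = 6000))
print(q)
#> ddPCR well A01: lambda mut 0.0834, wt 0.9163; F.A. 8.34% (95% CI 7.88-8.80)

tumour_volume(7.5, 12)
#> [1] 337.5
```

All intermediate files (`parental.vcf`, `acquired.tsv`, `gcn.tsv`,
`clone_matrix.tsv`, `tree.nwk`, `report.json`, …) are plain text under the
output directory, and identical configurations produce byte-identical
reports.

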