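---
title: "Reconstructing clonal evolution in drug-resistant cancer cell populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing clonal evolution in drug-resistant cancer cell populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonescape)
```

## The problem

When a drug-sensitive cancer cell population is kept under continuous drug
exposure until resistant derivatives emerge, the resistant population is
rarely a single clone. It is a mixture of subclonal populations related by
descent: a founder clone carrying the mutations that swept first, and
descendant clones that accumulated further alterations in branched or
linear succession. Reconstructing that architecture from bulk exome
sequencing of the paired parental and resistant lines requires a chain of
small, individually simple computations:

1. **Somatic subtraction** — the acquired-mutation catalogue of a resistant
   derivative is every variant present in the resistant sample but absent
   from its parental line, identified purely by `(chrom, pos, ref, alt)`.
2. **Gene copy number** — per-gene depth ratios from exome target regions:
   the median of a gene's per-region median depths divided by the global
   median over all regions.
3. **Cellular prevalence** — the fraction of cells carrying each acquired
   variant, from its allele fraction adjusted by local copy number and
   multiplicity.
4. **Subclone clustering** — variants that swept together share a cellular
   prevalence; 1-D clustering of prevalences yields the subclonal
   populations and their sizes.
5. **Clone-tree reconstruction** — clones are nested by the pigeonhole
   (sum) rule into a clones-by-mutations incidence matrix, and ancestry is
   read off the matrix by recursive subset containment: the clone whose
   mutations appear first is the father; clones containing those mutations
   plus new ones attach below it, recursively.
6. **ddPCR quantification** — clone-specific point mutations are tracked by
   droplet digital PCR: Poisson occupancy statistics convert droplet counts
   to concentrations with 95% confidence intervals and to the fractional
   abundance of the mutant allele.

Every stage is validated against a synthetic-data module that generates
ground-truth clonal structures and all downstream raw inputs with known
parameters.

## The generative model behind the simulator

`simulate_clone_tree()` draws a rooted tree over `n_clones` subclones: the
root is the founder of the resistant population and every later clone
attaches uniformly at random to an earlier one. Each clone acquires a
Poisson-distributed number of novel variants (minimum one — a clone is only
observable if something defines it). Subtree-exclusive population fractions
come from symmetric stick-breaking, normalised to sum to one; the
*cellular prevalence* of a clone — the fraction of cells carrying its
mutations — is its subtree fraction sum. Cumulative mutation sets are
unions of novel sets along root paths, so they form a laminar family by
construction (the infinite-sites assumption).

`simulate_read_counts()` turns the truth into sequencing-like tables.
Depth per variant site and per capture target is negative-binomial with
mean `mean_depth` and size `depth_dispersion` (`Inf` degenerates to
Poisson). Alternate reads are binomial with success probability equal to
the expected VAF:

$$\mathrm{VAF} = \frac{f \cdot m}{c}$$

with $f$ the carrying cell fraction, $m$ the variant multiplicity (1 by
default) and $c$ the local total copy number. Germline variants appear in
both samples at expected VAF 0.5; trunk variants (somatic but already
present in the parental line) appear in both; acquired variants only in
the resistant sample. These are clonal cell populations, so no purity term
appears anywhere.

Key defaults, chosen once as realistic working values:

| parameter | default | why |
|---|---|---|
| `mean_depth` | 150 | matches the ~145x median depth typical of current exome screens of cell lines |
| `depth_dispersion` | 100 | ~10–13% coefficient of variation of target-level median depth, the uniformity of a well-behaved capture after duplicate removal |
| `regions_per_gene` | 16 | capture designs split genes into many small targets; the per-gene median needs a dozen or more to be stable |
| `mean_novel_variants_per_clone` | 20 | tens of variants per sweep, the scale seen in resistant-line exomes |
| `n_trunk_variants` / `n_germline_variants` | 40 / 100 | enough shared background to make subtraction a real workload |
| `nonsynonymous_fraction` | 0.7 | roughly the coding-exome ratio after capture |
| `droplet_count` / `droplet_volume` | 15000 / 0.85 nL | instrument-typical droplet generation |

`cn_events` assigns genes an *absolute total copy number* against the
diploid baseline: a threefold-amplified gene (depth ratio 3) is simulated
as six copies. This keeps the depth profile, the expected-VAF formula and
the prevalence estimator mutually consistent.

`min_prevalence_gap` optionally constrains the drawn clone prevalences to
be pairwise separated by at least a given gap (and bounded away from
zero). Because star-like topologies cannot satisfy a pairwise gap — their
children's prevalences would have to sum past the parent's — the rejection
loop redraws topology and fractions *jointly*. This is the switch that
defines the "easy regime" used throughout validation (depth 300x, no
sequencing error, gaps of at least 0.15, five clones).

What the simulator deliberately does **not** model: read-level artefacts
(no FASTQ/BAM), alignment and duplicate-marking noise, mappability
blacklists, subclonal copy number (copy number is clonal per gene), purity
or stromal contamination, and indel realignment effects. Tests passing on
this simulator therefore say the *algorithms* are correct under their
stated model; they do not certify robustness to upstream artefacts of real
pipelines.

## Subclone inference

`cellular_prevalence()` implements
$\mathrm{CP} = \min(1,\ \mathrm{VAF} \cdot c / m)$, with a `capped` flag
when the raw value exceeds 1. The raw (uncapped) value is retained
because clustering behaves better on it: truncating first piles clonal
variants into an atom at exactly 1.0 and can split the truncal cluster in
two.

`cluster_prevalences()` supports two engines behind one interface:

* **`method = "gmm"` (default).** A 1-D Gaussian mixture in which each
  variant's standard deviation is *fixed at its known binomial counting
  error*, $\sigma_i = (c_i/m_i)\sqrt{\hat p_i(1-\hat p_i)/d_i}$ with $d_i$
  the depth — only the component means and weights are free, and the
  number of subclones is selected by BIC. Means are initialised at
  quantiles, so the fit is deterministic. Fixing the variances matters: a
  mixture allowed to estimate its own variances happily widens one
  component to absorb two neighbouring subclones, and the likelihood
  rewards it; the physics of counting noise says it should not be allowed
  to.
* **`method = "kde"`.** Local maxima of a fixed-bandwidth
  (`bandwidth = 0.05`) Gaussian kernel density — the classical quick look
  at a VAF histogram. It is retained for exploration; its fixed kernel
  resolves only generously separated clusters.

Both engines share the post-processing: assignment to the nearest centre
(ties toward the higher prevalence), merging of centres closer than
`min_separation` (member-weighted), and dissolution of clusters below
`min_cluster_size` into the nearest surviving centre. Variants enter
clustering only with depth at least `min_depth` (20) and `min_alt` (3)
alternate reads. Cluster prevalence is the mean member prevalence, capped
at 1.

`build_incidence_matrix()` nests the clusters by the pigeonhole sum rule,
processing in descending prevalence: a cluster's parent is the
already-placed cluster with the *smallest* prevalence whose unallocated
capacity (own prevalence minus already-attached children) still
accommodates it, within `nesting_tolerance` (0.05). Ties prefer fewer
children, then id. Because clusters are processed in descending order, the
most recently placed cluster is always childless and can always
accommodate the next one, so the rule is total; a conflict flag exists for
robustness but is unreachable on sorted input. A clone's incidence row is
the union of member sets along its path to the top.

## Clone-tree reconstruction and its oracle

`assign_ancestry()` implements the containment recursion directly: the
root is the clone whose mutation set is contained in every other clone's
set; each remaining clone's parent is the inclusion-maximal proper subset
of its own set. Ties between equally maximal candidate fathers are broken
toward larger set size, then higher prevalence, then lexicographic id, and
flagged. Input violating containment — no valid root, or a variant arising
novel on two branches — raises a structure error; `force = TRUE` instead
attaches offending clones by maximal Jaccard containment and flags every
forced edge, for real data that violate infinite sites.

`brute_force_ancestry()` is the test oracle: it enumerates *every* rooted
spanning tree over the clones (vectorised over parent assignments, in
chunks) and keeps those in which each child strictly contains its parent,
each parent is inclusion-maximal, the root has no proper subset, and novel
sets are disjoint. It exists so the recursion can be checked exhaustively
on thousands of random laminar systems; it is never used in the pipeline.

Branch semantics follow the field's display conventions:
`branch_length` is the count of novel variants a clone acquires
(synonymous plus non-synonymous), `sweep_label` counts the non-synonymous
novel variants defining the clonal sweep, and `colour_group` is the
child-of-root ancestor so that each top-level branch defines the main
colour of its subclones. Newick export labels nodes `<clone>_sweep<N>`
with branch lengths equal to novel-variant counts, children ordered by
descending prevalence then id.

### What is identifiable from one bulk sample

A single bulk sample constrains the tree only through the sum rule: any
nesting in which every parent's prevalence covers its children's is
consistent with the data. The greedy rule therefore returns a *canonical*
nesting — the deepest one — and the true topology is recovered exactly
when the truth coincides with it, which for uniformly attached truths is
essentially the linear (chain) topologies. This is not a weakness of the
implementation but an identifiability limit: no single-sample method can
distinguish sibling subclones from nested ones when both satisfy the sum
rule. The validation suite therefore reports topology recovery twice:
over all simulated truths, and over the sum-rule-identifiable subset,
where recovery is expected to be essentially complete. Resolving the
remaining ambiguity requires longitudinal samples, single-cell dilution
(supported by the ddPCR module), or multi-region data — all outside a
single-sample reconstruction.

## ddPCR statistics

With $N$ droplets of which $N_{pos}$ are positive, Poisson occupancy gives
the mean copies per droplet
$\lambda = -\ln\!\big((N - N_{pos})/N\big)$, concentration
$\lambda$ / droplet volume, and a delta-method 95% confidence interval
$\lambda \pm 1.96\sqrt{(1-\hat p)/(N\hat p)}$ with $\hat p$ the negative
fraction, floored at zero. A channel with no negative droplets carries no
information about $\lambda$ and raises a saturation error advising
dilution.

Fractional abundance is reported twice: `fa_raw` applies
$\mathrm{F.A.\%} = N_{mut}/(N_{mut}+N_{wt}) \times 100$ to positive-droplet
counts directly, and `fa_corrected` (the default) applies it to the
Poisson-corrected copy estimates, matching instrument software. The two
converge at low occupancy; at high occupancy only the corrected value is
unbiased. The FA confidence interval propagates the per-channel $\lambda$
uncertainties through the ratio and is clipped to [0, 100].

`detect_mixed_clone()` encodes the single-cell-dilution logic: a clone
grown from a single cell carries its marker mutations heterozygously, so
every detected marker should sit near the expected heterozygous FA (50% at
diploid loci). A well with a detected marker clearly below
`expected_het_fa - tolerance` (default 50 − 15) must contain a mixture of
cells — imperfect single cloning; wells whose detected markers all sit
within tolerance are pure; anything else (including wells with nothing
detected above `detect_limit`) is ambiguous.

## Preclinical computations

Tumour volume from caliper axes is $V = d^2 D / 2$ (mm³, $d \le D$; a
lenient mode swaps misordered axes with a warning). Randomisation into two
arms is valid when the relative difference of the mean volumes is below
10%; the denominator of that fraction is not standardised, so the midpoint
of the two means is the default with `first` and `max` selectable. The
TOP/FOP luciferase ratio is a validated quotient measuring
beta-catenin-driven transcription.

## Numerical and design choices

* **Determinism.** Every simulation function seeds the RNG from its
  configuration; the pipeline is a pure function of its config, and the
  one global seed fans out to stages by fixed offsets. Reports are
  byte-identical across reruns.
* **Medians** use the midpoint convention for even counts; the global
  depth median is taken over region-level medians (the only structure a
  region table offers).
* **Integer copies.** `absolute_copies()` rounds to the nearest integer
  copy number by default — DNA comes in whole copies, and rounding keeps
  diploid depth noise out of prevalence estimates. The raw ratio scale is
  available with `round = FALSE`.
* **Ties** are always broken deterministically (documented per function);
  every non-obvious resolution leaves a flag in the output rather than
  failing.
* **Degenerate inputs** raise typed conditions (`cs_config_error`,
  `cs_data_error`, `cs_inference_error`) that the command-line wrapper
  maps to exit codes 2/3/4.

## Validation problem sizes

The shipped test-suite and the acceptance script validate at these sizes,
chosen to exercise each claim meaningfully while staying desk-scale: 1000
random laminar systems (up to six clones) for the exhaustive tree oracle;
50 independent easy-regime pipelines (five clones, depth 300x) for
end-to-end recovery, prevalence RMSE and subtraction exactness; 20 seeds
for copy-number recovery of an amplified gene at 150x; 1000 replicates per
occupancy level for confidence-interval coverage; and 200 simulated
single-cell wells at 20% mixing for mixed-clone detection.

## Known limitations

* Topology beyond the sum-rule canonical nesting is unidentifiable from a
  single bulk sample (see above); trees over non-chain truths are
  plausible nestings, not certainties.
* Copy number is treated as clonal per gene; subclonal amplifications
  bias prevalences of the variants they cover.
* Quality-aware subtraction (weighting parental evidence by depth or base
  quality) is not implemented; subtraction is exact key difference.
* The ddPCR module starts from gated droplet counts; fluorescence gating
  itself is upstream and out of scope.
* No confidence measure is attached to the reconstructed topology.
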