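---
title: "Models and methods behind ironomics"
author: "ironomics maintainers"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Models and methods behind ironomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironomics)
```

# Scope

`ironomics` implements the computational core of a multi-omics
characterization of the low-iron response in the oceanic diatom
*Thalassiosira oceanica*: digital differential gene expression from two
pyrosequenced cDNA libraries, quantitative ^14^N/^15^N metabolic-labeling
proteomics, positional promoter-motif screening, sister-clade detection of
laterally acquired genes, cylinder-model cell morphometry, ΔΔC~T~ for
RT-qPCR, and assembly summary statistics. Upstream wet-lab and heavy
bioinformatics steps (sequencing, assembly, gene prediction, database
search, alignment, tree inference, image segmentation) are out of scope:
their *outputs* — count tables, PSM tables, gene trees, best-hit tables,
measurement tables — are this package's inputs.

Because the original inputs are external deposits, every stage comes with a
seeded synthetic-data generator that emulates the corresponding input with
known planted parameters. The generators are first-class, tested code;
recovery of the planted truth is what the test suite and the acceptance
script measure.

# Digital differential expression

For a gene with read counts $x_i$ in libraries of total size $N_i$, the
heterogeneity statistic is the log-likelihood ratio

$$R \;=\; \sum_i x_i \,\ln\!\frac{x_i}{\hat x_i},
\qquad \hat x_i = N_i\,\hat p,\quad
\hat p = \frac{\sum_i x_i}{\sum_i N_i},$$

with $0\ln 0 = 0$. $R$ is zero exactly when all per-library proportions
agree and is invariant to library permutation. For rare genes
($x_i \ll N_i$) $2R$ coincides with the 2×2 *G*-statistic (gene vs
remainder × library) to within 1% relative, which the tests verify against
a brute-force contingency computation.

The source study cites the statistic but not a significance procedure, so
null calibration was a genuinely open design point. The default here is a
parametric bootstrap: counts are redrawn per library as
$\mathrm{Binomial}(N_i, \hat p)$ and the p-value is the fraction of
replicates with $R^* \ge R$, with the $(k+1)/(n+1)$ correction. A
$\chi^2_{m-1}$ approximation evaluated at $2R$ is available as a fast
alternative; it is anticonservative at the small counts typical of
two-library EST data, which is why it is not the default. Multiple testing
uses Benjamini–Hochberg (the original analysis reported roughly 300
significant genes without stating a procedure; no attempt is made to
reproduce that count,
which depends on the real assembly). Genes with a zero count in one library
are kept — absence from a library is exactly the signal of interest. The
orientation convention throughout is Fe(−)/Fe(+): the first library is the
iron-limited one, and `up_at_low_iron` means its read proportion is larger.

The count generator draws each library as one multinomial with per-gene
probabilities proportional to baseline weights, times the planted fold
change for the Fe(−) library. This is an idealization: no overdispersion
model is offered, and none is claimed to match the real libraries. The
multinomial renormalization is real, though — planting large fold changes
on genes carrying a substantial share of the library shifts every other
gene's proportion, as in real compositional count data.

Default study conditions: two libraries of 95,000 reads, matching the
sequenced depth. Calibration checks use 2,000 null genes (type-I error
within [0.03, 0.07] at nominal 0.05) and 100 simulations of a 5-fold change
planted at baseline proportion $10^{-3}$ (≥ 99% power at adjusted
p < 0.01). These sizes keep the full calibration under a minute on one CPU
while leaving Monte-Carlo error well inside the asserted bands.

# Proteomics quantification

Peptide–spectrum matches pass a fixed-order filter cascade:

1. **Hit distinctiveness** (threshold 2): the second-best candidate's
   E-value must be at least twice the best one's. The original pipeline
   does not define its distinctiveness score; the second-best/best E-value
   ratio is the simplest monotone reading of a distinctiveness threshold
   of 2 and is the documented convention here. Records with no second
   candidate pass.
2. **Target-decoy FDR** (1%): the largest E-value threshold $t$ with
   $\#\text{decoys}(E \le t) / \#\text{targets}(E \le t) \le 0.01$ is
   selected; decoys never reach the output. The estimate is the plain
   count ratio — no +1 correction, no $\pi_0$.
3. **Precursor mass accuracy**: matches with $|\Delta| > 5$ ppm are
   discarded; the boundary is inclusive at 5 ppm since the original rule
   discards deviations strictly greater than 5 ppm.

The order is part of the contract: an ambiguous decoy removed by the
distinctiveness step never inflates the FDR estimate, and the tests pin
this down by showing that swapping the steps changes the survivor set.

Proteins with identical surviving peptide sets merge into one group;
strict-subset proteins are absorbed (parsimony). Quantification groups
spectra by (peptide, SDS-PAGE band, charge) — the PBC — forms one
light/heavy ratio per PBC from mean intensities, and aggregates PBC ratios
per protein group as median with first/third quartiles under the
linear-interpolation convention (`stats::quantile` type 7, fixed so
quartiles are bit-reproducible). Labeling orientation is a flag; the
default takes ^15^N-heavy as the iron-replete channel. Equal-protein ratios
convert to per-cell ratios by multiplying with the Fe(−)/Fe(+) protein
biomass ratio (0.5 under the study's BCA measurement: iron-limited cells
hold half the protein).

The PSM generator plants per-protein ratios with lognormal pair-ratio noise
whose log-mean is zero, so the *median* estimator is unbiased by
construction; decoy E-values are drawn stochastically larger than target
E-values (the study does not describe its decoy construction, so the
generator only promises that thresholding is informative). Recovery checks
use planted ratios {0.25, 0.5, 1, 2, 4} with 5 PBCs and 15% CV over 20
seeded runs, asserting $|\Delta\log_2| < 0.3$ in ≥ 95% of cases and a
decoy-estimated FDR never above the 1% target.

# Promoter motif screening

Promoter windows are read 5'→3' on the coding strand with the last base
adjacent to the start codon; minus-strand genes take the reverse complement
of the downstream genomic flank. Offsets anchor at the translation start:
offset $n$ means the motif occupies positions $-n \ldots -n+|m|-1$. The
screen reports perfect matches whose 5' end lies in the inclusive window
150–250, matching the published screen of the ACACGTGC element near
position −200; the published convention is not base-exact about whether
−200 refers to the motif's start, center or end, so the 5'-end anchor is
fixed here and documented. Matching is coding-strand-only by default
because the 8-mer is not its own reverse complement and the published count
refers to perfect matches; a both-strands flag exists. Positions with
ambiguity codes never match.

The motif report exposes the base composition (A₂T₁C₃G₂ for the screened
8-mer) and the longest self-reverse-complementary core. The full 8-mer is
*not* a palindrome in the strict sense; its CACGTG core — an E-box — is.
The report states both facts and adjudicates nothing.

The cross-promoter comparison that discovered the motif used dot-plots and
probabilistic motif discovery; those tools are out of scope, and the
package instead provides a defined exact-k-mer stand-in: k-mers present in
every input promoter with one occurrence per promoter selectable within a
position tolerance of a common center inside the window, ranked by minimal
positional spread (computed by a sliding-window minimal-range scan). Tests
compare it against an exhaustive center-enumeration oracle.

The genome generator guarantees a clean false-positive surface: non-planted
promoters are resampled until they contain no occurrence of the motif
(overlapping occurrences included), and planted promoters are resampled
until the planted occurrence is the only one. Planted-motif recall is
therefore exactly 100% and the false-hit count exactly 0 on synthetic
genomes — the tests assert both, plus strand symmetry under full genome
reverse complementation.

# Lateral gene transfer

The census tier filters best-hit tables at the conservative E ≤ 10⁻³⁰
cutoff and splits genes into vertical candidates (stramenopile best hit)
and LGT candidates. The tree tier classifies each query gene from its gene
tree: after rooting (midpoint by default — the original rooting procedure
lives in an unavailable supplement; outgroup rooting is available),
conspecific paralogs of the query are merged into the query clade so
recent duplicates cannot mask the donor signal, and the sister clade is
inspected. No stramenopile in the sister gives `lgt_confirmed`; a pure
stramenopile sister gives `vertical`; a mixed sister gives `unresolved`,
mirroring the published heterogeneous-mix category without guessing the
unstated rule behind its 18 cases. Sister taxa missing from the lineage map
also give `unresolved` — the conservative choice. The summary reports
confirmed transfers as a percentage of the conserved gene set (180 of
198 examined trees over 10,109 conserved models → 1.8%).

The tree generator plants sister-clade compositions directly and chooses
branch lengths so the midpoint root lands on the internal edge, which keeps
the planted sister relation intact under rooting; classification accuracy
on generated trees is asserted to be exact. Verdicts are checked to be
invariant under leaf rotations and newick re-encoding, and midpoint rooting
is idempotent up to leaf order.

# Cell morphometry and RT-qPCR

Cells are modeled as closed regular cylinders (both caps — the
valve-plus-girdle geometry of a centric diatom):
$V = \pi (d/2)^2 h$, $S = 2\pi (d/2)^2 + \pi d h$. Growth proceeds by a
gradual two-fold height increase at constant diameter, so an
unsynchronized population spans a factor-2 range of any size-like
parameter. Back-calculation to the "cellular unit" (a freshly divided
cell) places a range $[L, 2L]$ around the population mean; under the
default `arithmetic_center` convention the mean is the arithmetic center,
giving $L = \text{mean}/1.5$. This convention was chosen because it
reproduces *both* published unit volumes (100 and 80 µm³) from the
published mean dimensions (5.9 × 5.5 and 4.7 × 7.0 µm); a
`geometric_center` option ($L = \text{mean}/\sqrt 2$) is provided but
non-default.

The published unit *surfaces* are internally inconsistent with any single
back-calculation rule: the iron-limited 140 µm² matches the raw mean
surface of the published dimensions (138.1), while the iron-replete
122 µm² matches a surface re-derived from the unit volume at the mean
diameter (122.6). `unitCellFromPopulation()` therefore reports the raw
mean, the mean/1.5, and the volume-re-derived surface side by side and
adjudicates nothing. Whether the published diameters and lengths are raw
means or themselves back-calculated is equally unstated; the package
treats them as means, which is the reading that reproduces the volumes.

The cell generator's default population model is `uniform_phase` (length
factor uniform on [1, 2]); an `exponential_age` model (age density
$2\ln 2\cdot 2^{-a}$, the steady-state age structure of an exponentially
growing population) is available because the true age structure of the
imaged cultures is unknown. With noise off, the uniform model's mean
length is 1.5 × the unit length, and the unit volume round-trips within
1% — both asserted.

ΔΔC~T~ follows the threshold-cycle formula with
$\Delta C_T = C_T(\text{gene}) - C_T(\text{housekeeping})$ per condition
and $\Delta\Delta C_T = \Delta C_T^{Fe(+)} - \Delta C_T^{Fe(-)}$; positive
values mean induction at low iron. Replicates average; per-condition plate
offsets cancel, which the tests assert explicitly. Any reference gene id is
accepted (the study used 18S rRNA and RPB1).

# Assembly statistics

N50 is the largest $L$ such that contigs of length ≥ $L$ hold at least half
the assembly (ties break with "≥ half", the definition the study itself
spells out). The genome-size estimate divides total sequenced bases by the
median coverage of long contigs (≥ 10 kb by default), the least collapsed
part of an assembly. Applied to the study's printed inputs — 725 Mb of
reads at a median 8.7-fold long-contig coverage — the estimator gives
83.3 Mb where the study prints 81.6 Mb; the arithmetic behind the printed
value is not shown, and the package reports the computed number without
forcing agreement. An option to restrict the numerator to bases mapped to
long contigs is the most plausible source of the gap.

# Numerical and degenerate-input choices

* Bootstrap p-values compare $R^* \ge R - 10^{-12}$ to absorb float noise;
  all-zero count rows return $R = 0$ with a warning; negative counts are
  rejected.
* The FDR threshold is evaluated at the last index of each distinct
  E-value, so ties are atomic; when no threshold achieves the target the
  result is an empty table plus a warning, not an error.
* Quantiles are type 7 everywhere, direction calls treat proportion
  differences below 4 machine epsilons as flat, and empty compartments
  aggregate to zero totals with an undefined (NA) ratio.
* Promoter windows truncated by a contig edge are flagged and kept;
  single-cell unit back-calculation warns that the /1.5 convention is
  biased for $n = 1$ but applies the definition verbatim.
* All generators draw from one seeded stream per call and record the seed
  in their truth tables; the pipeline derives per-stage seeds from one
  global seed by fixed offsets.

# What passing tests do and do not show

The synthetic generators emulate the *structure* of the study's inputs —
library sizes, planted effect sizes, decoy/target E-value separation,
band/charge multiplicity, sister-clade composition, the factor-2 growth
range — not their full messiness: no overdispersion beyond multinomial
noise, no chimeric contigs, no peptide-to-genome mapping errors, no
misrooted trees beyond what midpoint rooting produces. Green property
suites therefore certify the correctness and calibration of the
implementations under the stated models, and the published desk-scale
quantities (geometry ratios, 1.8% LGT, motif composition, organellar read
ratios) are reproduced exactly from the published values as inputs; they do
not certify the genome-scale counts (45 motif genes, 1,695 peptides, the
best-hit taxon breakdown), which depend on the real assembly and external
databases and are explicitly out of scope.
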