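---
title: "Methods: regulatory-network inference and the synthetic study design"
author: "nitronet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulatory-network inference and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nitronet` infers a typed lncRNA–miRNA–mRNA regulatory network from
replicated expression profiles collected under contrasting nitrogen
regimes, and ships a simulator with planted ground truth so that the
whole chain of inference rules is testable. This vignette explains the
statistical model behind each stage, the parameters that matter, the
design choices made where the design was genuinely open, and what the
synthetic study does and does not establish about real data.

## The inference model

The pipeline treats regulation as a set of testable pairwise claims,
each with its own evidence type:

* **TF → gene** (`tf_binding`): the TF and the gene are coexpressed
  (|Pearson correlation| > 0.8, two-sided p < 0.05 from
  $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ degrees of freedom) *and* the
  TF's binding element occurs at least once in the gene's promoter.
  Correlation sign is deliberately not restricted, so repressive TFs are
  representable; the edge record carries the sign.
* **miRNA → transcript** (`mirna_cleavage`): the transcript contains a
  complementarity site under the plant targeting rule (below), and both
  members are differentially expressed; the pair is labelled *coherent*
  when their directions are opposite (consistent with miRNA-guided
  repression) and *noncoherent* otherwise.
* **lncRNA → gene in cis** (`lnc_cis`): the gene lies within 10 kb of
  the lncRNA locus. Distance is measured between transcript spans (gap
  0 for overlap), on either side, strand-agnostic. We read the 10 kb
  rule as locus proximity rather than TSS-to-TSS distance; the window is
  configurable (`cis_window_bp`).
* **lncRNA → gene in trans** (`lnc_trans`): the two expression profiles
  are strongly anticorrelated (PCC ≤ −0.9 on `log2(FPKM+1)` across
  shared samples) and their DE calls disagree in at least one shared
  contrast. "Opposite expression with correlation ≥ 0.9" is contradictory
  if read literally, so the default mode `anticorrelated` resolves it as
  PCC ≤ −0.9; mode `absolute` (|PCC| ≥ 0.9, with call concordance
  required to match the correlation sign) is available because the
  intended reading cannot be recovered from the rule's usual phrasing.

Both lncRNA target rules are applied only to differentially expressed
lncRNA–gene pairs (DEL–DEG pairs), and the miRNA rule to DEM–DEG pairs,
mirroring how such studies report their pair counts.

### Differential expression

Abundances are normalized to FPKM (length- and depth-normalized, for
mRNA/TF/lncRNA) or TPM (depth only, for miRNAs — reads are the
molecules, so no length term). Calling uses a Welch unequal-variance
t-test on `log2(normalized + 1)` per pairwise condition contrast,
Benjamini–Hochberg step-up adjustment within each contrast, and the
canonical thresholds |FC| ≥ 2 with FDR < 0.05. Boundary semantics are
exact: a fold change of exactly 2 qualifies (≥), an FDR of exactly 0.05
does not (<). Fold changes are computed from group means of normalized
abundance with a pseudocount (default 1.0) guarding zeros; the estimator
behind a printed "|FC| ≥ 2" is rarely stated in publications, so both
the pseudocount and the normalized scale are configuration, not dogma.

A dispersion-shrinkage NB model (DESeq2-style) would be the method of
choice on genome-scale data; at the desk scale this package targets, the
Welch test is assumption-light, transparent, and adequate — and the
thresholds, which are what define the calls, are preserved exactly.
Features constant in both groups get p = 1 by convention (no evidence of
signal), or p = 0 if the two constants differ.

### The miRNA complementarity score

The miRNA is aligned antiparallel to a candidate site. Counting
positions from the miRNA 5′ end (1-based), each aligned position costs
0 for a Watson–Crick pair, 0.5 for a G:U wobble, 1.0 for a mismatch;
each inserted or deleted base costs 2.0; and penalties falling at
positions 2–13 are doubled, encoding the empirical intolerance of plant
miRNA targeting to central/5′ disruptions. The site score is the
minimum over alignments with at most one contiguous bulge, and sites
with penalty ≤ 4.0 are reported (best site per miRNA–transcript pair,
leftmost on ties, shorter window on residual ties). All weights, the
doubled region, the bulge allowance, and the cutoff are configuration
keys. The scanner evaluates windows of length `len(miRNA) ± max_bulge`
at every offset; an exhaustive enumeration of admissible alignments
serves as the reference implementation in the test suite.

### Promoters and binding elements

Promoters are the `promoter_length` (default 2000 bp) bases immediately
upstream of the gene start, strand-aware (downstream and
reverse-complemented for minus-strand genes), truncated with a warning
at chromosome edges. Element scanning supports IUPAC consensus strings
(every exact degenerate match on either strand is a hit) and position
weight matrices (hit iff window score ≥ `score_fraction_threshold` ×
maximal attainable score, both strands). Offsets are reported 0-based on
the promoter. The TF → element assignment is user input: binding-element
content is evidence the user supplies (from a motif database or their
own analysis), never something the package invents.

### Network assembly and scoring

Accepted pairs become directed typed edges carrying their evidence
(correlation, p, element hits, site penalty, coherence). Duplicate
(source, target, mechanism) triples collapse to the single
strongest-evidence record (lowest p, then lowest penalty) — one
interpretable record per edge rather than a merged blur. TF targets may
themselves be sources, so indirect chains (lncRNA → TF → gene) are
representable. Exports: edge TSV (round-trips exactly), SIF, GraphML
with node roles and edge evidence as attributes. Recovery against a
planted truth counts an edge as correct iff the full (source, target,
mechanism) triple was planted; precision, recall, and F1 are reported
per mechanism and overall, with the 0-precision convention for empty
predictions.

## Coordinates

All interval logic runs on 1-based inclusive coordinates — the native
convention of GFF3 and of the IRanges/GenomicRanges machinery used for
overlap, containment, and gap computations. Keeping the file convention
internally means the GFF3 round-trip is the identity and there is no
conversion boundary to get wrong; `IRanges::distance()` supplies exactly
the gap semantics the cis rule needs (0 for overlapping or abutting
loci, else the inter-interval base count, so "gap ≤ 10000" admits a
10 kb separation and rejects 10001).

## The synthetic study

`sim_config()` defaults describe one concrete study: 3 nitrate
conditions × 3 replicates (labelled N0/N6/N18), 130 protein-coding
genes, 30 TFs, 40 lncRNAs, 40 miRNAs, with 30 planted TF edges, 20
miRNA edges, 10 cis and 10 trans lncRNA edges; the 100 features beyond
the planted sets (60 genes, 20 lncRNAs, 20 miRNAs) are decoys. These
sizes keep a full end-to-end run in tens of seconds while leaving every
rule with real positives and real negatives to discriminate.

### Genome and sequences

One chromosome, with every locus in its own ~24 kb slot so inter-locus
gaps far exceed the 10 kb cis window — by construction the only gene
within cis range of a planted cis-lncRNA is its partner. The ten
cis-planted lncRNAs cycle through the four positional classes: lincRNA
partners sit 2.5–5 kb from their host gene, intronic ones inside a host
intron, antisense and sense ones overlap the host on the opposite/same
strand. Genes are two-exon; targets of planted miRNA edges carry an
exact reverse-complement site of their miRNA inside exon 1, so the
planted site survives splicing. Promoter sequences are drawn from a
uniform background, rejection-sampled (bounded retries) so that no
promoter contains any TF's element by chance; then one exact element
instance is implanted at a random offset and strand in each planted
target's promoter. Element presence is therefore *equivalent* to
planted regulation, which is what makes TF-edge precision a clean
construction-level guarantee. Each TF receives a distinct element (the
configured IUPAC core plus a TF-specific flank): with a single shared
element, any coexpressed TF would pass the element gate at another TF's
target and precision would no longer measure anything.

### Expression: trajectories, correlation, and noise

Counts are negative-binomial with mean `2^(baseline + trajectory +
noise)` and a single shared dispersion (`nb_dispersion`, default 0.05,
variance `mu + mu^2 · dispersion`). Condition trajectories — not
per-sample draws — carry the planted structure, mirroring
treatment-driven coexpression in a 3 × 3 design.

With three conditions, centered condition profiles live in a
two-dimensional space, so a profile is a direction (an angle) and an
amplitude. Planted regulators get exact directions: the coexpressed
block (TF pairs, miRNA targets, cis pairs) shares one direction; miRNA
regulators run exactly opposite their targets; trans-lncRNA pairs
occupy four axes placed ≥ 36° from the block and from each other, two
pairs per axis in mirrored orientation (lnc at the axis angle with its
gene opposite, and vice versa — their cross-correlations are positive
and therefore invisible to the anticorrelation rule). Pairs beyond the
eight that fit on well-separated axes share their axis's target gene,
the many-to-one targeting regularly reported for lncRNA–gene relations.
This geometry is the study's answer to a hard fact: in a 2-D profile
space one cannot plant arbitrarily many mutually-distinguishable
anticorrelated pairs under a |PCC| ≥ 0.9 rule, so the design spends its
angular budget where the rule needs it.

`target_correlation` (ρ, default 0.95) sets the attainable sample-level
correlation of a planted pair. Writing $S^2$ for the trajectory
variance across samples and $v$ for per-feature noise variance, the
pair correlation is $S^2/(S^2+v)$, so the generator solves
$v = S^2(1/\rho - 1)$, subtracts the expected NB contribution
(≈ dispersion/ln²2 on the log2 scale), and injects the remainder as
Gaussian log-noise split evenly between regulator and target. The
injected noise is *centered within each condition*: it attenuates the
nine-sample correlation exactly as replicate scatter does, but leaves
realized condition means untouched, so planted directions do not rotate.
At ρ = 1 no noise is injected and pair correlations approach ±1 as the
dispersion shrinks; at ρ = 0 the target receives no signal at all and
behaves as a null feature, which makes the null-control study (no
accepted TF pairs, no trans pairs at default thresholds) a structural
property rather than a statistical accident.

Decoys get weak random-direction trajectories (norm ≤ `decoy_amplitude`
= 0.5 log2, below the 2-fold calling threshold) plus fixed
replicate-level centered noise (`replicate_noise_sd` = 0.7 log2). The
replicate noise matters: null genes in real data are null because their
drift is buried in biological replicate variability, and without it a
decoy whose NB noise happens to drift monotonically is both called
differential and almost noise-free, i.e. indistinguishable from a real
signal by any expression-based rule.

Two background pools (120 genes, 30 miRNAs) with high stable abundance
(2^15–2^16.5 counts) emulate the bulk of a real library. They exist
because FPKM/TPM divide by per-sample totals: with only ~200 simulated
features, planted up-swings would dominate the totals and normalization
would inject a spurious anticorrelated common mode into every profile
(composition bias). The stable mass keeps totals nearly
condition-invariant, as the 49,000-gene transcriptome does in a real
experiment.

`signal_amplitude` (default 5.5 log2) gives planted features
between-condition swings of up to ~90-fold — strong but within the range
reported for nitrate transporters — chosen so the Welch test at n = 3
calls planted features decisively and NB shot noise cannot rotate
realized profiles across the angular margins. `baseline_mean_log_range`
(2^9–2^11) keeps even fully repressed conditions above ~50 counts,
where dispersion rather than shot noise dominates.

### What the simulation does not emulate

Read-level artifacts (FASTQ, mapping ambiguity, positional bias),
hairpin structure and miRNA biogenesis, isoform complexity (one
transcript per gene), genuine motif degeneracy beyond IUPAC codes,
multi-chromosome structure, and — importantly — the correlational
ambiguity of real regulatory networks, where confounded coexpression is
pervasive and precision against "truth" is not measurable. Passing the
recovery study shows the rules are implemented correctly and can
separate signal from noise under the stated conditions; it does not
show the thresholds would achieve comparable precision on a real
transcriptome.

## Numerical choices and degenerate inputs

* BH adjustment is the exact step-up (`min_{j ≥ i} p_(j)·m/j`, capped at
  1); the suite checks it against a brute-force oracle and
  `p.adjust(method = "BH")` to 1e-12.
* `pearson_with_p` returns p = 0 at |r| = 1 and refuses constant
  vectors; callers (trans and TF stages) skip zero-variance profiles
  with a warning instead of propagating NaN.
* The miRNA scorer requires a clean A/C/G/T(U) alphabet and errors
  otherwise; scoring is invariant to case and U/T representation.
* Ties in site prediction break to the leftmost site, then the shorter
  window; duplicate-edge resolution keeps lowest p, then lowest penalty.
* TPM columns sum to 10⁶ within floating tolerance by construction;
  zero-total samples and zero-length features are errors, not silent
  zeros.
* The pipeline manifest contains no timestamps, and all generator
  randomness flows from `config$seed` (annotation at seed, elements at
  seed+1, expression at seed+2), so identical config + seed reproduces
  every output byte for byte.
* ORF scanning for lncRNA filtering covers the three forward frames,
  counts the start codon, excludes the stop, and counts an ORF running
  off the 3′ end as open. The filter is exercised as a standalone
  operation; `run_pipeline()` trusts the input role labels by default
  (`filter_lncrna: true` enables it), since curated role labels are part
  of the declared inputs and random-background lncRNA loci can contain
  chance ORFs.

## Problem sizes in the test suite

Unit tests run a compact study (20 genes, 4 TFs, 8 lncRNAs, 6 miRNAs
plus background) so each simulation takes a couple of seconds; the
acceptance tests run the full default study (seed 1, documented above)
end to end, its null control, and a byte-identity rerun. Oracle suites
use 1000 random p-vectors (length ≤ 500), 1000 random correlation pairs
(n ∈ {6, 9, 12}), and 200 random miRNA/window pairs. These sizes are
the package's chosen balance between coverage and a suite that runs in
a few minutes.

## Known limitations

The Welch test at three replicates is conservative; borderline planted
features can miss the strict FDR gate, which is visible as recall
slightly below 1 in the recovery study. The trans rule inherits the
fundamental 2-D limit of three-condition designs discussed above: with
many more planted trans pairs than the angular budget allows, false
positives among planted-by-construction anticorrelated cross-pairs
would be unavoidable — a property of the rule and the design, not of
the implementation. GO/KEGG enrichment is implemented as a generic
hypergeometric over-representation test against user-supplied term
maps; real ontology databases are out of scope.
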