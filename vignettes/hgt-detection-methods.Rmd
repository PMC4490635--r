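---
title: "Detecting horizontal gene transfer by phylogenetic incongruence"
author: "hgtscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontal gene transfer by phylogenetic incongruence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In a small, well-sampled microbial community — the motivating case is an
acid mine drainage (AMD) biofilm with a handful of bacterial and archaeal
members, supplemented by reference isolate genomes — horizontally
transferred genes betray themselves by phylogenetic incongruence: the gene's
tree places the recipient lineage inside the donor's clade instead of where
the organism (species) tree puts it. `hgtscan` implements this detection
funnel as a reproducible pipeline: ortholog families by strict reciprocal
best hits, per-family maximum-likelihood gene trees, an approximately
unbiased (AU) test of the organism-tree topology, a rate-artifact exclusion
filter, and automated donor/recipient/direction calls with detection of
operon-like transferred blocks.

Every stage is validated against a forward simulator that plants transfer
events with known donors, recipients and block structure, so sensitivity
and recipient accuracy are measured against ground truth rather than
asserted.

## Ortholog families

All proteins of every genome pair are compared with an in-package
Smith–Waterman aligner (affine gaps; BLOSUM62 with gap open 11 and extend 1,
a gap of length $L$ costing $11 + L$). Raw scores are converted to bit
scores and E-values with fixed gapped Karlin–Altschul constants
($\lambda = 0.267$, $K = 0.041$, the BLOSUM62 11/1 regime):
$E = K m n e^{-\lambda S}$. Fixed constants rather than per-search
calibration keep desk-scale runs deterministic; the constants are recorded
in every output header via the configuration hash.

A pair of proteins in different genomes is a reciprocal best hit (RBH) iff
each is the other's *unique* highest-bit-score hit (ties disqualify — the
"strict" criterion) and the alignment passes `evalue <= 1e-5`,
`identity > 0.25` and `alignment columns > 0.60` of the shorter sequence.
Identity counts identical residue pairs over all alignment columns, gap
columns included in the denominator. The length criterion's denominator is
the shorter sequence — the commonest convention for RBH filters; the
choice is a package convention, not an inference about any particular
published protocol. Families are connected components of the RBH graph;
components holding two proteins of one genome are split by deleting their
lowest-bit-score edges (ties broken lexicographically) until one gene per
genome holds. Families present in at least 8 genomes with at least one
community member enter the phylogenetic stages.

## Alignment and gene trees

Each family is aligned progressively: 3-mer distances, a UPGMA guide tree
with deterministic tie-breaks, and profile–profile global alignment under
the same BLOSUM62/11/1 scoring as the search (one scoring scheme simplifies
auditing). No iterative refinement is applied.

Gene trees are inferred under the Dayhoff substitution model throughout —
simulation, pairwise distances, and tree likelihoods share bit-identical
rates and stationary frequencies (harvested from phangorn's model tables),
which is what lets the test suite compare the pruning algorithm against
exhaustive summation at $10^{-10}$ tolerance. No among-site rate variation
is modelled by default. The search is neighbor joining on ML pairwise
distances followed by NNI hill climbing with branch-length re-optimization
(phangorn's `optim.pml` provides the standard machinery behind this
surface). Branch support comes from 100 nonparametric bootstrap replicates
(columns resampled i.i.d. at original length, full ML search per
replicate, majority-rule consensus with bipartition frequencies as
supports).

## The AU test

For each family the species-tree topology is restricted to the family's
taxa and its branch lengths re-optimized on the family alignment; the test
contrasts this constrained fit with the family's ML gene tree. This
two-item candidate set is the minimal faithful formulation of the
hypothesis "the family evolved along the organism tree"; testing a larger
candidate set of plausible topologies is a possible extension, not
implemented.

Per-site log-likelihood vectors for the two topologies are resampled by
RELL at ten scales $r \in \{0.5, 0.6, \dots, 1.4\}$ (resample size
$\lceil n r \rfloor$, $B = 1000$ per scale by default, an independent
seeded RNG stream per scale). The bootstrap proportion $BP(r)$ is the
fraction of resamples in which the species topology's total is at least
the gene tree's — ties count for the species topology, a deliberately
conservative rule (fewer transfer calls). The multiscale model is
$$\psi(\sigma^2) \;=\; \sigma\,\Phi^{-1}\!\big(1 - BP\big) \;=\; d + c\,\sigma^2,
\qquad \sigma^2 = 1/r,$$
fitted by one-pass weighted least squares with weights
$B\,\phi(z)^2 / (BP(1-BP))$ after clamping $BP$ into
$[1/2B,\, 1 - 1/2B]$; then $p_{AU} = 1 - \Phi(d - c)$. The sanity anchor
for the parametrization is the half-space case, which the two-tree RELL
contrast realizes exactly: resampling gives $BP(\sigma) = \Phi(y/\sigma)$
for the observed standardized likelihood difference $y$, so $\psi$ is
constant in $\sigma^2$ — pure signed distance $d = -y$, zero curvature —
and $p_{AU}$ reduces to the one-sided normal p-value. A parametrization
with the roles of $\sigma$ and $1/\sigma$ exchanged would push all signal
into curvature and make the test blind under exactly this null, which is
observable as a point mass of p-values near 1 in null simulations.

When fewer than three scales have $BP$ strictly inside $(0,1)$ the fit is
degenerate and the naive proportion at scale 1 is reported with a flag.
When the gene ML topology equals the constrained topology the species tree
cannot be rejected and $p_{AU} = 1$ by construction. Families with
$p_{AU} < 0.05$ are "incongruent". No multiple-testing correction is
applied across families — the downstream filters are deliberately strict
instead, and the per-family p-values are all reported.

### Calibration regime

Null calibration is only informative where the ML gene tree actually errs:
on a deep, well-resolved organism tree every null family recovers the
species topology exactly and the rejection rate is trivially zero. The
calibration experiment therefore simulates 200-site null families on an
8-taxon tree with short internal branches (0.02 substitutions/site against
0.25 terminals), where roughly half the families yield a different ML
topology and the selection correction is genuinely stressed. Under these
conditions the empirical rejection rate at $\alpha = 0.05$ sits in the low
single percent — slightly conservative, as the tie rule intends.

## Rate-artifact exclusion

Apparent incongruence can come from lineage-specific rate variation and
finite-data resolution error rather than transfer. The filter
operationalizes this: collapse every gene-consensus-tree branch with
bootstrap support below 0.70; if the collapsed tree is compatible with the
species topology (every remaining bipartition occurs in it), the family is
excluded as an artifact. Supported conflict survives. The 0.70 threshold is
a configuration value; low-support rearrangements are the signature of
rate/resolution artifacts, which is the rationale for treating
compatibility-after-collapse as exclusion.

A finding from the simulations is worth stating plainly: when inference is
performed under the true substitution model, pure rate acceleration (5×
on one or two lineages, topology unchanged) almost never produces
*supported* topological incongruence — decoy families are absorbed at the
AU stage (gene ML topology equals the species topology, or the conflict is
unsupported) and none survive into calls. The filter's discriminating
behavior (excluding low-support conflict, keeping high-support conflict)
is therefore exercised by constructed fixtures in the test suite, while
the end-to-end simulations verify that no decoy leaks through to a call.
Real data, where the model is always misspecified, is expected to push
substantially more families into this filter, which is why it exists.

## Donor, recipient, direction, clusters

For each surviving family the recipients are the minimal leaf set whose
removal makes the gene tree compatible with the species topology, searched
over singletons, then pairs, then triples (larger events are flagged
"complex" and excluded from direction counts). Two refinements matter in
practice:

* **Support collapse first.** Recipient inference runs on the ML gene tree
  with branches below the support threshold collapsed. Raw ML trees carry
  incidental low-support conflicts (short species-tree branches are
  unresolvable at 200 sites) that would otherwise inflate the minimal
  removal set beyond the true recipients.
* **Displacement tie-break.** Minimal removal sets are not always unique:
  for a displaced cherry, removing either side restores compatibility.
  Candidates of the smallest working size are scored by the mean
  topological (unit-edge) species-tree distance between the candidate set
  and its gene-tree sister group, and the maximum wins — true recipients
  sit maximally far from the clade they were transferred into. In the
  planted-transfer simulations this raises exact-recipient identification
  from ~40% to ~80%.

The donor clade is the recipients' sister group in the rooted gene tree
(midpoint rooting by default; a user-designated conserved outgroup
family's leaves are used when present in the tree). Direction is read from
kingdom labels: donor-clade majority kingdom → recipient kingdom. A call is
"within-community" iff all recipients are community members and the donor
clade contains at least one. This flag rule is a reproducible automation
of a selection step that such analyses have traditionally done by manual
curation; it is one formalization, not the only defensible one.

Calls whose recipient genes lie on the same contig and strand with at most
`cluster_gap` (default 1) intervening genes are grouped into clusters —
the operon-block signature.

## The simulator

`sim_config()` defaults emulate the motivating community: 17 genomes
(7 bacteria, 10 archaea), 8 community members (2 + 6), 200-site protein
families present in every genome, transfers planted between kingdoms
inside the community (14 by default, including a 9-gene and a 2-gene
same-strand block mirroring the ribosomal-operon and two-gene-operon
cases), and rate decoys at 5× acceleration. Transfers are modelled as
replacement of the recipient's native copy, which keeps families
one-per-genome — additive transfers would create in-paralogs that the
one-gene-per-genome family model excludes by construction.

The tree height default of 1.5 substitutions/site is the **maximum
tip-to-tip divergence** (root depth 0.75). This is a deliberate reading:
under Dayhoff the expected residue identity at pairwise distance 2.0 is
24.5%, *below* the 25% search threshold, so deeper trees disconnect
cross-kingdom orthologs at the search stage and no funnel exists to
validate. At height 1.5 the deepest ortholog pairs sit near 32% expected
identity — diverged enough for phylogenetic power, shallow enough for the
search to reconstruct ≥95% of families.

What the simulator does *not* emulate: indels within families (families
are generated gap-free; the aligner is exercised separately on indel
fixtures), among-site rate variation, codon structure, gene gain/loss,
in-paralogs, and model misspecification. Passing the end-to-end checks
therefore demonstrates correctness of the machinery under matched-model
conditions, not performance on real proteomes.

## Validation problem sizes

The packaged validation uses: alignment kernels against an exhaustive
enumeration oracle (peptides ≤ 6) and an independent aligner (≤ 12,
hundreds of seeded pairs); likelihoods against exhaustive state summation
(≤ 5 taxa, $10^{-10}$); AU calibration on 100 null families (8 taxa,
200 sites, $B = 1000$ × 10 scales); and an end-to-end community of 10
genomes (5 + 5, 8 community members) × 100 families with 30 planted
transfers (blocks of 4 and 3, 23 singletons), 20 rate decoys and 50
nulls. These sizes were chosen once as a representative desk-scale
experiment; the 17-genome default remains available for larger runs.

## Numerical choices and edge cases

* Branch lengths are floored at $10^{-8}$; site log-likelihoods at
  $-10^9$ (relevant only for zero-length degenerate fixtures).
* ML pairwise distances are capped at 10 substitutions/site; boundary
  candidates (0 and the cap) are compared explicitly so identical
  sequences return exactly 0.
* X and the ambiguity codes B/Z/J/U/O are mapped to X and treated as
  missing data in likelihoods (contribution summed over states), matching
  common likelihood-software handling.
* UPGMA and NJ tie-breaks, family splitting and family ids are
  deterministic; one run seed expands into independent per-stage,
  per-family RNG streams, so stages can be re-run in any order with
  identical results and two runs with one seed are byte-identical.
* Genome labels are sanitized (whitespace and Newick-reserved characters
  to underscores) with the original names retained alongside.

## Limitations

Detection is capped by the orthology stage: transfers accompanied by
extreme divergence (or any family falling below the prevalence filter)
never reach the AU test. The two-tree AU contrast tests only the organism
tree against the family's best tree. Donor resolution is limited to the
sister group — transfers from extinct or unsampled lineages will name the
nearest sampled relative. Direction calls assume the kingdom labels are
correct and the recipients' displacement is the transfer (not a loss +
duplication scenario). The within-community flag is an automated proxy for
what is ultimately an evidentiary judgement.
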