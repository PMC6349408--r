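---
title: "Constructing transcriptional events and mapping usage QTLs with txevents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing transcriptional events and mapping usage QTLs with txevents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

RNA-seq quantification at the whole-transcript level entangles three largely
independent transcriptional choices — which promoter a transcript starts
from, which internal exons it includes, and where it ends — and is fragile
when the annotation is incomplete: reads from an unannotated transcript are
redistributed across annotated ones, producing spurious associations at
exons the reads never touched. txevents addresses this by stratifying a
reference annotation into *independent transcriptional events*: for each
gene, up to two groups of transcripts are selected, the exons shared by all
members of a group form a *scaffold*, and every member's non-shared exons
are assigned to one of three event types relative to that scaffold —
alternative promoters (`upstream`), internal exons (`contained`) and
alternative 3' ends (`downstream`). Each event is written out as a
transcript-like annotation, so any standard quantifier can estimate its
abundance, and the *relative usage* of the events of one type within one
group is a clean phenotype for QTL mapping.

## Event construction

### Coordinates

Internally all exons are 0-based half-open intervals sorted by start; GTF
input/output converts to and from the 1-based inclusive convention at the
boundary. Half-open intervals make containment, adjacency and union
arithmetic free of off-by-one cases; the boundary conversion is tested as
its own inverse.

### Truncation repair

A large fraction of reference transcripts are truncated: tagged
`cds_start_NF`/`cds_end_NF`, or of a biotype (`retained_intron`,
`processed_transcript`, `nonsense_mediated_decay`) whose models routinely
stop inside exons — these biotypes are treated as truncated at *both* ends.
Left alone, truncated 5'/3' ends would masquerade as alternative promoters
and 3' ends with no experimental support. `extend_transcript()` repairs a
truncated end from the gene's template — the longest transcript carrying the
GENCODE `basic` tag (falling back to all transcripts; ties to the
lexicographically smallest id) — by copying every template exon strictly
beyond the truncated terminus and, when the terminal exon lies inside a
template exon, stretching its outer boundary to the template exon's
boundary. Internal boundaries are never touched, so the original chain
survives as a subsequence, and the operation is idempotent. Two deliberate
edge policies: if the template is itself truncated at the required end the
transcript passes through unchanged with a warning (never trimming), and a
terminal exon that only partially overlaps a template exon keeps its own
outer boundary (flagged with a warning). After repair the truncation tags
are dropped and a truncation-marking biotype is reset to `protein_coding`,
so a repaired transcript classifies as complete.

### Transcript grouping

Exon sharing means *exact coordinate identity* of both boundaries, not
overlap: overlap-based sharing would make the scaffold ill-defined (two
members could "share" different parts of an exon). Because the intersection
of exon sets can only shrink as a group grows, the largest attainable
scaffold is always realised by some transcript pair. The grouping therefore
seeds with the pair of maximal exon-set intersection and then absorbs every
remaining transcript that contains the whole scaffold — attaining the
maximal shared-exon count with as many members as possible. Transcripts that
would shrink the scaffold (for example by skipping a scaffold exon) are left
for group 2, which is built the same way from the leftovers; this also
serves genes with two non-overlapping transcript clusters, which yield two
groups with disjoint scaffolds. All ties break to lexicographically smallest
transcript ids, making the procedure invariant to input order. An exhaustive
reference (`scaffold_optimum()`, enumeration over all transcript subsets of
size at least two) is exported as a diagnostic; on the package's own
generator the greedy scaffold always matches it, and by construction it can
never exceed it.

### Event typing

With the scaffold fixed, each member's variable (non-scaffold) exons are
partitioned by position in transcript orientation: entirely 5' of the
5'-most scaffold exon is `upstream`, entirely 3' of the 3'-most scaffold
exon is `downstream`, everything else is `contained`. A variable exon that
partially overlaps a boundary scaffold exon is deliberately `contained`: an
event whose "promoter" differs only by an internal splice-site shift would
be misleading. An event of a type is the scaffold plus the member's variable
exons of that type. Members with identical chains collapse to one event
(represented by the smallest transcript id), and an event set is emitted
only when at least two distinct events remain — a singleton's relative usage
would be constantly one. On the minus strand `upstream` is the promoter
side, i.e. the highest genomic coordinates; building events on a
coordinate-mirrored gene yields exactly mirrored events.

### Masking

Promoter and 3'-end events may still differ at exons other than their
terminal one, in which case their usage would also tag splicing changes.
`mask_internal_variation()` therefore keeps each event's terminal exon (the
first exon in transcript orientation for upstream events, the last for
downstream) and replaces every other position by the positional union of the
non-terminal exons across the set's events, so the masked events are
exon-identical away from their terminal exon. The union — rather than
deletion — preserves read-assignment territory for quantification. The rule
is positional by design: only the terminal exon is exempt, so an internal
exon adjacent to an alternative first exon is still masked (its union is
inserted into events that lacked it). A consequence worth knowing: the
non-first exons of a multi-exonic alternative promoter are shared with the
other events of the set after masking. Masking can merge events; duplicates
are collapsed again afterwards, and sets reduced below two events are
dropped. The step is idempotent and is applied only to upstream/downstream
sets — internal-exon sets pass through untouched. It can be skipped
(`build_gene_events(..., mask = FALSE)`) to discover more associations at
the cost of interpretability. A known limitation: masking assumes each
event's terminal exon is terminal in the masked event too; a promoter lying
3' of another event's internal upstream exons would violate this, a
configuration the generator does not produce and real annotations rarely do.

## Relative usage

Event abundances (TPM) are imported from per-sample quantifier tables
(`Name Length EffectiveLength TPM NumReads`) and normalised within each
(gene, group, event type) block and sample: usage = TPM / block total. The
value is the relative usage of one event compared with the other events of
the same type sharing the same scaffold, which is exactly what makes the
association phenotype interpretable. Block-samples with zero total TPM have
no defined usage; they are marked `NA` and excluded pairwise downstream
rather than imputed — imputation at zero expression would manufacture
phenotype values with no data behind them. The expression filter retains
genes whose mean gene-level TPM exceeds 1 in at least one condition (strict
inequality); gene-level TPM is approximated as the summed TPM of one
event-type block (`contained` when present), since the events of one block
partition the gene's transcripts — an approximation to filtering on gene
counts, documented as such. Before association testing, usage values are
rank-transformed to normal quantiles (`qnorm((rank - 0.5)/n)`, ties
averaged, centred) because raw proportions violate the normality assumptions
of the linear tests; the transform can be disabled by simply passing
untransformed usage.

## QTL mapping

The nominal pass regresses each feature on each variant's dosage (plus
covariates, typically the leading phenotype principal components) by
ordinary least squares with a two-sided t-test, within a ±500 kb window
around the feature's anchor — the 5'-most genomic position of the gene,
chosen strand-independently and documented because any single anchor is a
convention. The permutation pass works on a *scope* — all features of one
gene and event type, pooling the two construction groups — in a ±100 kb
window: the observed statistic is the minimal nominal p over all (variant,
feature) pairs, sample labels are shuffled jointly across the scope's
features (preserving their correlation, which is what makes the
scope-minimum correction valid), and the empirical p-value is the direct
estimator with pseudocount, `(1 + #{permuted min <= observed})/(n_perm + 1)`.
The direct estimator is preferred over a beta-distribution approximation
because it is simple, exactly testable, and adequate at
`n_perm = 1000–10000`; its floor `1/(n_perm + 1)` is a feature, not a bug.
When covariates are supplied, phenotypes and dosages are residualised once
and the residuals are permuted — exact with no covariates, the standard
approximation otherwise. Scope-level empirical p-values receive
Benjamini–Hochberg correction (10% FDR by default); the lead variant is the
argmin of the nominal p, ties broken by position then id. Secondary
(conditional) associations are out of scope. Cross-method replication takes
the query method's significant gene-level leads (smallest p across the
gene's events) and asks whether the reference method's lead for the same
gene is in high LD (r² > 0.8, squared Pearson correlation of dosages,
allele-flip invariant); genes with no reference lead count as
non-replicated — the conservative reading, switchable via `drop_missing`.
The measure is asymmetric between methods by construction.

## Response QTLs

A QTL detected in a stimulated condition is tested for context-specificity
against its paired naive condition with a likelihood-ratio test between two
donor-random-intercept mixed models (lme4), H0 with genotype and condition
main effects and H1 adding the genotype-by-condition interaction, both
fitted by maximum likelihood — not REML — because the compared models differ
in fixed effects. The statistic is referred to χ² with `conditions − 1`
degrees of freedom (1 for the usual two-condition contrast; the
multi-condition generalisation exists but is not the default). Singular fits
(zero donor variance) degrade both models to plain regressions and are
flagged. Donors observed in a single condition are retained — the mixed
model handles unbalancedness.

Significance alone admits interactions of negligible size, so effect-size
relevance is assessed by a random-effects decomposition,
`phenotype ~ (1|genotype) + (1|condition) + (1|genotype:condition)`, with
genotype entering as an unordered factor of dosage levels. This coding
ignores the expected linear dose–response and is acknowledged as suboptimal;
it is kept because the decomposition is only a filter, and an
additive-coding alternative (`additive = TRUE`) is provided for sensitivity
analysis. The reported quantity is
`sigma2_relative = sigma2_interaction / (sigma2_interaction + sigma2_genotype)`,
bounded in [0, 1] and scale-invariant; when both genetic components are
estimated at zero it is defined as 0 and flagged. A *response QTL* is a
candidate with interaction FDR < 10% (BH within condition) *and*
`sigma2_relative > 0.5`.

## Colocalisation filtering

The package consumes precomputed colocalisation posteriors (PP0–PP4; the
priors used for the external computation in this line of work are
`p1 = 1e-4, p2 = 1e-4, p12 = 1e-5`) and applies four rules: keep records
with `PP3 + PP4 >= 0.8` (the boundary is inclusive, matching the convention
of removing cases strictly below 0.8), `PP4/(PP3+PP4) > 0.9` (strict),
region not overlapping the MHC (GRCh38 chr6:28,510,120–33,480,577, excluded
for its LD complexity), and minimal GWAS p strictly below 1e-6. The filter
preserves order and is idempotent. Candidate regions for colocalisation are
400 kb windows centred on lead variants that lie within 100 kb of a GWAS
variant with p < 1e-5.

## The simulators, and what passing tests do and do not show

The generators define the conditions under which the package's claims are
tested:

* `make_gene()` realises multi-transcript genes around a core exon chain
  with per-transcript alternative first/last exons (shared "slots"), extra
  terminal-region exons (to exercise masking), skipped internal exons, and
  deliberate truncations (cut halfway into the adjacent exon, tagged
  `cds_start_NF`/`cds_end_NF`). Exon lengths are drawn from 80–200 bp and
  introns from 200–1000 bp — compact but shaped like real genes. Ground
  truth is computed symbolically on locus labels, independently of the
  coordinate implementation.
* `simulate_usage_qtl()` plants a per-allele usage shift of 0.10 on one
  event (baseline usage 0.6/0.4) in 84 samples at MAF 0.3 — the worked
  two-transcript promoter example — with optional Gaussian usage noise and
  complementary renormalisation that keeps usage a proper composition by
  construction. With zero noise, least squares recovers the planted slope
  exactly.
* `simulate_conditions()` draws donor (variance 0.5), condition (0.5),
  genotype (1), genotype-by-condition (1) and residual (0.5) contributions
  for 40 donors in two conditions at MAF 0.3, with genotype effects drawn
  per dosage level to match the fitted decomposition exactly (an additive
  mode mirrors the sensitivity flag).

What they deliberately do not emulate: linkage disequilibrium between
variants (each simulated variant is independent), read-level sampling noise
and coverage-dependent quantification error, GC/sequence bias, batch
structure, and overlapping alternative promoters. Calibration and recovery
results on these simulations therefore validate the statistical machinery
and the construction logic, not robustness to quantifier artefacts or LD —
on real data, lead variants are LD proxies of causal ones and usage noise is
heteroscedastic in depth.

## Problem sizes and numerical choices

The test suite asserts: exact recovery of the planted 10%-per-allele slope
(tolerance 1e-12); greedy-vs-exhaustive grouping agreement, masked terminal
variation and strand symmetry on 1000 generated genes; block sums within
1e-9 of one over 10,000 random blocks; permutation-p uniformity over 500
null scopes at `n_perm = 1000`; interaction-LRT type-I error within
[0.03, 0.07] over 1000 null replicates; zero BH-10% discoveries in at least
95% of 100 null scans of 200 scopes; planted-QTL detection above 90% over
100 replicates; mean `sigma2_relative` within 0.5 ± 0.1 over 500
equal-variance replicates and below 0.1 over 200 null replicates. The
reproduction script (`scripts/acceptance.R`) recomputes the same quantities
at moderately reduced replicate counts (300 genes, 300 scopes, 500 LRT
replicates, 60 power replicates) — sizes chosen so a single-core run
finishes in about a minute while keeping Monte-Carlo error well inside the
asserted margins. Empirical p-values are never zero by construction; BH is
`stats::p.adjust`; mixed models use lme4 with singular-fit checks ignored at
fit time and handled explicitly afterwards.

## Known limitations

Exact-coordinate exon sharing makes grouping sensitive to minor annotation
jitter in exon boundaries (a single-base difference breaks sharing);
upstream of the package, harmonised annotations are assumed. Genes with
transcripts on both strands or on multiple chromosomes, and transcript ids
reused across genes (pseudo-autosomal copies), are rejected rather than
split. The expression filter approximates gene-level TPM from one event
block. The permutation residualisation is approximate under covariates. The
variance decomposition treats genotype as a factor; with few samples per
dosage level its components are noisy, which is why it is used only jointly
with the interaction test.
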