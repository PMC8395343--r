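---
title: "Methods: downstream alternative-splicing analysis with psikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downstream alternative-splicing analysis with psikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`psikit` implements the downstream half of a two-group alternative-
splicing study: everything that happens after junction counts,
annotation, variants and expression matrices exist. This vignette
explains the models and the choices behind them — what is estimated,
under which assumptions, which knobs matter, and what the synthetic
validation does and does not demonstrate.

## The PSI model

For one splicing event, each sample contributes inclusion and exclusion
junction read counts. Within a group we pool counts across samples and
estimate percent spliced in as

$$\widehat{\Psi} = \frac{\sum_s \mathrm{inc}_s}{\sum_s \mathrm{inc}_s + \sum_s \mathrm{exc}_s}.$$

Pooling was chosen over averaging per-sample ratios because per-sample
PSI is unstable when a sample happens to have few junction reads for an
event; pooling weights samples by their evidence. The cost is that
between-animal variability is absorbed rather than modelled — with five
animals per group and events pre-filtered for coverage this is a
reasonable trade, but the per-sample route is kept available
(`per_sample_mean_psi()`) where sample-level resolution matters, e.g.
the expression–inclusion correlation.

The group contrast is `delta_psi = psi_g1 - psi_g2`, reported to three
decimals, matching the precision at which such tables are printed.

### The posterior probability

Upstream splice-graph quantifiers report a posterior probability that an
event's PSI differs between conditions. We do not reproduce any
particular tool's expectation–maximisation machinery; instead the
package uses a transparent conjugate substitute with the same filter
semantics: each group's PSI receives an independent Beta posterior under
a Jeffreys prior,

$$\Psi_g \mid \text{counts} \sim \mathrm{Beta}\!\left(\textstyle\sum \mathrm{inc} + \tfrac12,\; \sum \mathrm{exc} + \tfrac12\right),$$

and `dpsi_probability()` reports the Monte-Carlo fraction of posterior
draws (default 10,000, seeded) in which the difference has the sign of
the point estimate. This is P(ΔΨ > 0) in the estimated direction; a
minimal-effect threshold is exposed (`threshold`, default 0) for users
who prefer P(|ΔΨ| > 0.1), since conventions differ between tools. Tests
verify the Monte-Carlo estimate against direct numerical integration of
the Beta-difference distribution to within 0.01.

The significance filter is `|dPSI| > 0.1` and `probability > 0.9`
(strict inequalities). Significant events are labelled
strong/moderate inclusion/exclusion with the strong boundary at
`|dPSI| >= 0.5`; the boundary was inferred from published example rows
(0.510 labelled strong, 0.410 moderate) and is configurable
(`strong_cutoff`).

## Event topology and consequences

`classify_event_type()` types the alternative segment purely from
isoform structure: a cassette exon is a whole internal exon present in
one isoform and absent from another that shares flanking exons; intron
retention is a whole intron contained in another isoform's exon;
alternative 5′/3′ splice sites are exon pairs sharing one boundary. All
donor/acceptor vocabulary is in transcript orientation — on the minus
strand, genomic left/right flip. Internally every coordinate is 0-based
half-open; GTF (1-based closed) and VCF (1-based) conversions happen
only in the readers, which keeps off-by-one errors at one boundary.

Region calls (5′UTR/CDS/3′UTR) use the longest CDS-bearing transcript
of the gene; segments straddling a CDS boundary count as CDS, and genes
without CDS give NA. Frame consequence applies to CDS cassette exons:
skipping preserves frame iff length ≡ 0 (mod 3). Rescue groups —
frameshifting exons whose joint skipping restores frame — are
underdetermined as a combinatorial problem, so the package uses a
deterministic greedy rule: within a gene and ΔPSI direction, mod-3
residue-1 exons pair with residue-2 exons in genomic order, leftovers
form same-residue triples. Smallest groups first makes the output
auditable; an exon whose own length is a multiple of 3 never joins a
group.

The frameshift null is never hard-coded: `random_skipping_null()`
recomputes the fraction of internal CDS exons with length not divisible
by 3 from whatever annotation is supplied. On a mammalian annotation
this is about two thirds; the acceptance checks use a constructed
annotation with exon lengths uniform on 30–329 nt, where the rate is
exactly 2/3. The observed frameshift count is tested with the exact
two-sided binomial (minimum-likelihood convention, as in
`binom.test`).

Both event-level and gene-level summaries are emitted, because published
event counts and gene counts are often mixed in prose; percentages use
the count of frame-defined CDS cassette events as denominator.

## Microexons

Microexons are internal exons of 3–30 nt (inclusive, configurable).
Inclusion of a supplied curated target list is summarized per group, and
an event is called "preferentially skipped" in the group whose PSI is
lower, but only when the event passes the significance filter. The
expression–inclusion correlation is Spearman's rank correlation with a
seeded permutation p-value (10,000 permutations): rank-based because the
relationship across heterogeneous tissues/strains is monotone at best,
not linear, and the expression scale is arbitrary (FPKM-like).

## SNP windows

Positional classes around an alternative exon follow fixed windows:
splice-site adjacent within 15 nt of a splice site, intronic between 15
and 500 nt from the exon edge, exonic interior beyond 15 nt from both
edges, `outside` further away. Two conventions required a decision:

* the 15-nt splice-site window is applied on **both** the intronic and
  the exonic side of each splice site (the exonic-side width is a
  separate knob, `ss_exon_window`, default 15), reading the
  "within 15 nt up- or downstream of splice sites" convention
  symmetrically;
* distances count the first base on either side of an exon edge as
  distance 1, and intronic windows are measured from the exon edge.

Both are configuration, not constants, because the published wording
admits either reading. Densities are per 1000 nt; enrichment against
the genome-wide baseline (total SNPs / total genome length — the
simplest defensible normalization, since no baseline is standard) uses
a 2×2 χ² on SNP vs non-SNP positions with 1 df and no continuity
correction. CpG-loss calls use the genome forward strand only, which is
sufficient because CpG is strand-symmetric.

## RBP motifs

Motifs are named sets of degenerate IUPAC k-mers (5–8 nt), not PWMs: the
motif collections used by positional-enrichment tools are not
redistributable from the literature, so definitions are a user input
(`read_motifs()`) and the package ships only a two-motif demonstration
set (`demo_motifs()`) with SR-protein-like purine-rich and
poly-pyrimidine-like patterns. Enrichment is event-level
presence/absence of a hit in a region (exon, 250-nt upstream or
downstream intron flank, transcript-oriented) compared between
foreground and background event sets by Fisher's exact test with BH
adjustment across (motif, region) pairs. This deliberately replaces
sliding-window positional statistics: with dozens of events rather than
genome-scale sets, presence/absence is the statistic that has power. The
background is the non-significant event set, a pragmatic stand-in for
"all alternative exons". A positional hit-density profile is emitted for
plotting but carries no test.

SNP effect calls pad the scanned window by k−1 so matches overlapping
the edge are seen, and compare matches covering the SNP with the REF
versus the ALT allele: `disrupt` (covered with REF, not with ALT),
`create` (the reverse), else `none`. A REF allele disagreeing with the
genome is an error, not a silent skip, because it means the VCF and
FASTA are inconsistent.

## miRNA targeting

Candidate regulators of a splicing factor are miRNAs that (i) are
differential by Welch's t-test on log2(x+1) expression with BH
adjustment, (ii) change in the required direction, and (iii) have a
canonical seed site — 6mer (match to positions 2–7), 7mer-A1, 7mer-m8,
8mer — in the factor's 3′UTR, with 7mer-or-better required by default.
Canonical seed classes are used as a transparent stand-in for heavier
target-prediction frameworks; no thermodynamic or conservation scoring
is attempted.

## The synthetic study

`generate_study()` builds one contig per gene with a fixed geometry
(600-nt flanks, 150-nt constitutive exons, 800-nt introns around the
alternative segment) and two isoforms per gene realizing the planted
event type. Junction counts are drawn per sample as
`n ~ Poisson(depth)`, `inc ~ Binomial(n, PSI)` with depth 200 by default
— the simplest generative model consistent with count-ratio PSI
estimation and a typical well-covered junction. The default panel (38
events, two groups of 5) mixes strong/moderate/null effects in both
directions across all four event types, microexon targets planted at
PSI ≈ 0.2 vs 0.9 (skipped in group 1, mirroring reduced
microexon inclusion in the diabetes-susceptible strain), frame-preserving and
frameshifting exon lengths, and two genes with complementary
frameshifting exon pairs.

Planted features are recovered *exactly* by construction, for any seed:
positional SNPs and CpG-loss SNPs are written into neutral sequence
contexts (`T[A]T`, `TA[C]GT`) whose alleles cannot participate in any
demo-motif match or stray CpG, motif instances are flanked by scrubbed
bases that cannot extend a match, and the generator re-runs the
downstream classifiers at generation time and refuses to emit a bundle
whose truth tables would not hold. The miRNA 3′UTR uses an A/T-only
background with all seeds containing G or C, so seed sites exist exactly
where planted. Expression is log-normal (σ = 0.25 on the natural-log
scale) with planted log2 fold-changes split evenly between groups.

What passing these checks shows: the estimators are unbiased at the
simulated depth, the classifiers implement their window and matching
definitions exactly, and the pipeline is deterministic. What it does not
show: behaviour under overdispersed counts, mappability artefacts,
isoform complexity beyond two isoforms per gene, linked SNPs, or motif
statistics under realistic sequence composition — real background
sequence is not A/T-neutral, and real junction counts are noisier than
Poisson-binomial. Conclusions about real data rest on the method
definitions, not on the simulation.

## Numerical and engineering choices

* All randomness flows from one seed; stages derive independent
  sub-seeds, so re-running one stage reproduces its output without
  re-running the others. Posterior draws use an event-indexed seed so
  event order does not affect results.
* Unquantifiable events (all-zero counts in a group) get NA PSI and are
  excluded from downstream classification rather than imputed.
* Zero fractions in enrichment log-ratios are capped at ±20 rather than
  reported as infinities, keeping the TSV numeric.
* Degenerate Welch inputs follow fixed conventions: both groups constant
  and equal means to p = 1; constant but different to p = 0 with a
  degeneracy flag.
* Problem sizes in the test-suite were chosen to keep the full
  validation (576 assertions including 10⁵-position motif-scan oracle
  comparisons and 2×10⁵-draw posterior checks) under a minute: the
  bundle uses 38 events at depth 200, which is already in the regime
  where planted-PSI recovery saturates.

## Known limitations

* The posterior is a pooled-count approximation; it ignores biological
  replication, so its probabilities are sharper than a hierarchical
  model would give. The 0.9 cutoff should be read as a ranking filter,
  not a calibrated error rate.
* Event typing requires the annotation to contain both isoforms; novel
  junctions absent from the GTF are typed NA.
* Rescue grouping is one deterministic choice among several defensible
  partitions; alternative groupings with equal sums are not enumerated.
* The GWAS-overlap step treats the ortholog map as given and performs
  case-insensitive symbol matching only.
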