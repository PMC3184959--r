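---
title: "Classifying the phytocyanin gene family: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the phytocyanin gene family: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcfam)
```

## The biology in brief

Phytocyanins (PCs) are plant blue copper proteins built around a
plastocyanin-like domain (PCLD) that binds a single copper atom through four
conserved residues: two histidines, a cysteine, and an axial methionine or
glutamine. The family splits into three subfamilies by that ligand set:
uclacyanin-like proteins (UCL, axial Met), stellacyanin-like proteins (SCL,
axial Gln), and early-nodulin-like proteins (ENODL), whose PCLD has lost one
or more key ligands and presumably functions without copper.

Many PCs are also chimeric arabinogalactan proteins (AGPs): besides the
folded PCLD they carry an N-terminal secretion signal peptide (SP), a
Pro-rich AGP-like region (ALR) decorated with arabinogalactan glycomodules,
and a C-terminal GPI-anchor signal (GAS). The combination of those parts
defines six architecture types:

| Type | SP | PCLDs | ALR | GAS |
|------|----|-------|-----|-----|
| I    | +  | 1     | +   | +   |
| II   | +  | 1     | +   | -   |
| III  | +  | 1     | -   | +   |
| IV   | +  | 1     | -   | -   |
| V    | -  | 1     | -   | -   |
| VI   | +  | 2     | -   | -   |

Types I and II — an SP plus glycomodules — are the chimeric AGPs; types I
and III are the GPI-anchored forms. Every other flag combination is reported
as `UNCLASSIFIED` rather than forced into a type.

## Sequence features: PAST bias, Pro-rich regions, glycomodules

AGP backbones are biased toward Pro, Ala, Ser and Thr; `past_fraction()`
reports that share (a value above 0.35 is the conventional AGP flag; we
report it but never gate a call on it, since the threshold's original scope
— whole mature protein versus linker — is a matter of convention).

`find_pro_rich_regions()` implements the hydroxylation-context rule: a
region is a maximal chain of Pro residues with at most 11 residues between
consecutive Pro, keeping only chains of two or more. Pro inside excluded
intervals (domains, signal regions) never seeds a region. Note the context
alphabet for Pro-rich regions is Ala/Gly/Ser/Thr, but glycomodule *heads*
are Ala/Ser/Thr only — Gly marks hydroxylation context, not an
arabinosylation site — so the region scanner is alphabet-agnostic (it chains
Pro alone) while the glycomodule scanner is strict about heads.

`find_glycomodules()` finds `[AST]P` dipeptides whose Pro is noncontiguous
(not adjacent to another Pro — this is what distinguishes AG sites from
extensin-like `SP2-4` blocks, and makes a sequence such as `SPPSPP` yield
nothing), then clusters kept dipeptides whose starts lie within 13 positions
of each other — the 11-residue spacing rule plus the two residues of the
dipeptide itself. Clusters of at least two dipeptides are glycomodules.

`call_alr()` masks the PCLD(s), the SP region (residues 1–25 when an SP is
present) and the GPI omega-region (last 25 residues when a GAS is present),
and calls an ALR when at least three qualifying dipeptides remain. The
three-dipeptide floor is our choice — the field accepts proteins "with
several" such motifs as AGPs but states no minimum — and the synthetic
fixtures therefore plant either zero or six-plus dipeptides so no
fixture-level result depends on the exact floor.

## Subfamily calling through a reference domain

Family-scale surveys usually align every PCLD in one multiple alignment and
read the ligand columns off it. We replace the MSA with pairwise global
alignment (BLOSUM62, affine gaps, opening 10 / extension 0.5) of each query
domain against a packaged 60-residue reference PCLD whose four ligand
columns (12, 25, 40, 45) carry H, C, H, M and whose disulfide Cys sit at
columns 6 and 52. The reference is synthetic and deliberately artificial:
its background is polar and Pro-free (so it can never contain a glycomodule
or a hydrophobic signal cassette), and every ligand residue differs from
both neighbors, so deleting a ligand produces a unique optimal alignment
with the gap exactly at the ligand column. `extract_ligand_sites()` maps the
annotated columns through the alignment; a column opposite a gap reads as
absent (`-`).

The subfamily rule is then exact: `(H,C,H,M)` is UCL, `(H,C,H,Q)` is SCL
(the single Met-to-Gln shuffle separates the two), anything else — a wrong
residue or a gap at any key site — is ENODL. Alignments scoring below a
confidence floor (40% of the reference self-score) raise a typed condition;
`classify_protein()` converts that into an ENODL call with a warning, since
an unalignable domain by definition lacks the conserved ligand set. When a
protein carries two PCLDs (type VI), the subfamily comes from the
N-terminal domain.

When no PCLD interval is supplied, `locate_pclds()` scans the protein by
repeated best local alignment against the reference, masking each accepted
hit with `X` before the next pass; hits must reach 50% of the reference
self-score. On real proteomes one would instead pass intervals from
InterProScan/Pfam — the scanner exists so that the pipeline can run from
bare sequences.

## Duplication rules

Two family genes are tandem duplicates when they lie on the same chromosome
separated by at most five intervening genes (genes of *any* family, counted
in the chromosome-wide ordinal order that `gene_loci()` assigns by ascending
start). Groups are the transitive closure of that relation — a chain of
near-neighbors is one group — and singletons are never reported.

Segmental duplicates are family genes lying in paired collinear blocks.
Within a block pair, a gene in block A pairs with a gene in block B when
their offsets from their respective block starts differ by at most 500 kb.
The offset rule is our operationalization of "collinear gene pairs" below
the block level, which genome-database tools resolve internally with anchor
chains; it is symmetric under swapping the blocks and is documented as a
stand-in, not a synteny algorithm.

## Expression rules

* **EST specificity** (`est_specific_tissue()`): a gene is specifically
  expressed in the unique tissue contributing strictly more than half of
  its total EST count; an exact half, or a zero total, yields no call.
* **MPSS tiers** (`mpss_tier()`): below 50 tpm is low, 50–500 tpm
  (boundaries inclusive — we read the dash as inclusive) is moderate, above
  500 tpm is strong. The three tiers partition the nonnegative line.
* **Microarray display normalization** (`normalize_microarray()`): absolute
  signals divided by the grand mean of the matrix, then log2. We pick base 2
  because fold-change gates in the same analysis are 2 and 0.5. Zeros are
  floored at half the smallest positive value (configurable) before
  division; by construction the mean of the back-transformed matrix is 1.
* **Clustering** (`cluster_genes()`): centered-correlation distance
  (1 − Pearson r) with average linkage, the classic heat-map combination.
  A zero-variance gene has no defined correlation and receives the maximal
  distance (2) to every other gene rather than an error.
* **Stress calls** (`call_stress_de()`): fold change is the ratio of
  linear-scale arm means; significance is a two-sided Welch t-test on log2
  signals (the original analysis states only a p-threshold and a desktop
  statistics package, so the exact test is our documented choice); a call
  requires both fold > 2 (or < 0.5) and p < 0.05, with at least two
  replicates per arm.

## qRT-PCR quantification

`qpcr_standard_curve()` fits Ct against log10(amount) over a three-fold
dilution series (amounts 10, 30, 90, 270, 810, 2430). At 100% efficiency
the Ct drops by log2(3) per step, so the slope is −log2(3)/log10(3) =
−ln 10/ln 2 ≈ −3.3219 — a closed form the tests pin to 10⁻⁶.
`qpcr_relative_expression()` averages technical replicates on the Ct scale,
converts Ct to template quantity through each gene's curve, normalizes by
the geometric mean of four housekeeping references, and summarizes
biological replicates as mean ± sd. A sample with an undetected reference
is excluded and flagged, never silently imputed.

## Phylogeny

`nj_tree()` is a from-scratch Saitou–Nei neighbor-joining implementation:
Q-criterion agglomeration, standard branch-length formulas, ties broken by
the smallest index pair so output is deterministic, negative branch
estimates clamped to zero and flagged. Distances come from `p_distance()`
(proportion of differing sites with pairwise deletion of gapped columns) —
simpler and more transparent than a Kimura-type correction, and exact for
the consistency property that matters: on additive matrices NJ provably
recovers the generating topology, which the tests verify on random trees of
up to 12 taxa (Robinson–Foulds distance 0) alongside an independent
cross-check against `ape::nj`. `bootstrap_support()` resamples alignment
columns, rebuilds the tree per replicate, and annotates each split of the
full-data tree with its replicate percentage; supports annotate the
full-data tree (no majority-rule consensus), matching how family trees are
usually drawn.

## What the synthetic data emulates — and what it does not

The generators produce inputs whose *structure* matches the pipeline's
contracts and whose *truth* is known by construction:

* `gen_pc_protein()` concatenates cassettes — a 25-residue SP satisfying the
  toy hydrophobic-stretch rule, the reference PCLD with the subfamily's
  ligand edits (ENODLs lose a random key site by substitution or deletion),
  an ALR of `APSG` repeats (8 noncontiguous AP dipeptides by default, well
  above the 3-dipeptide floor), and a 25-residue GAS tail. Linkers are
  polar and Pro-free, so planted features are the only features.
* `gen_family_fixture()` builds the 62-member rice-family composition
  (19/1/18 type I, 3/1/4 type III, 11/1/2 type IV, 2/0/0 type V across
  UCL/SCL/ENODL) by default; classification from sequence alone recovers
  every planted label.
* `gen_genome_layout()` plants tandem clusters with chosen intervening-gene
  gaps and block pairs with chosen collinear offsets, always strictly inside
  or outside the rule bounds (never *at* a boundary unless a test is about
  the boundary).
* `gen_expression_data()` plants tissue-specific genes (three quarters of
  EST mass on one tissue), stress folds of 4 and 0.25 under log-normal
  noise of 0.2 on the log2 scale with 4 replicates per arm, MPSS tiers
  drawn strictly inside tier intervals, and qPCR plates generated from
  known quantities at efficiency 2.

What passing these fixtures shows is that every *rule* is implemented
exactly; what it cannot show is performance on real data, where domain
boundaries are fuzzy, signal-peptide prediction is a learned model rather
than a regular expression, expression noise is not log-normal, and the
family census itself depends on database searches that are out of scope
here. The SP/GAS heuristics in particular are toy stand-ins: on real
proteomes, supply predictor outputs through `read_annotation_table()` and
the heuristics are never consulted.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout; converters to 0-based
  half-open exist only at the I/O boundary. Strand is carried but ignored —
  none of the duplication rules conditions on it.
* Non-standard residues are rejected by default; `nonstandard = "mask"`
  maps them to `X`.
* Generators take a `seed` and restore the caller's RNG state, so the same
  seed always yields byte-identical output without clobbering a session.
* Simulation sizes in the test-suite (1,000-sequence scanner comparisons,
  50-layout and 50-tree property loops, a 1,000-gene null for the type-I
  error check) were chosen as the smallest sizes at which the binomial /
  combinatorial margins in the assertions are meaningful.
* Degenerate cases are typed, not papered over: an all-zero expression
  matrix, a flat dilution series, a pair of alignment rows with no shared
  ungapped column, or a protein without a detectable PCLD each produce a
  specific error or warning.

## Worked example

```{r example}
fix <- gen_family_fixture(seed = 42)
fam <- classify_family(fix$records)
summary(fam)
```

The summary reproduces the family composition: 38 type-I proteins, of which
19 UCL and 18 ENODL chimeric AGPs, 46 GPI-anchored proteins (types I + III),
and 60 SP-bearing proteins out of 62.
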