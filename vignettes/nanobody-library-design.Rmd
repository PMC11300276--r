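---
title: "Designing a synthetic humanized nanobody library in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing a synthetic humanized nanobody library in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoforge)
```

## The problem

Nanobodies (VHH, sdAb) are the ~15 kDa antigen-binding domains of camelid
heavy-chain-only antibodies. A synthetic phage-display library replaces
animal immunization: a single stable, humanized scaffold is fixed, and
sequence diversity is written into the three CDR loops with degenerate
primers. `nanoforge` implements the in-silico half of that workflow —
everything from repertoire statistics to primer-level codon design and
quality-control simulation — together with the curve fits used to
characterise selected binders.

The pipeline, end to end:

1. **Annotation** (`annotate_regions`). Sequences are numbered in IMGT
   coordinates by alignment to a framework anchor of known numbering. Region
   spans are FR1 1–26, CDR1 27–38, FR2 39–55, CDR2 56–66, FR3 67–104, CDR3
   105–117, FR4 118–128; position 66 is counted inside CDR2.
2. **Repertoire curation and statistics** (`dedup_cluster`,
   `curate_complex_dataset`, `positional_profile`, `distill_consensus`,
   `hallmark_cdr3_association`).
3. **Scaffold humanization** (`propose_hallmark_humanization`,
   `propose_consensus_substitutions`, `apply_design`).
4. **Diversity design** (`build_diversity_spec`,
   `optimize_degenerate_codon`, `plan_codons`, `spec_summary`).
5. **Library build and QC** (`design_primers`, `assemble_in_silico`,
   `sample_library`, `simulate_synthesis_errors`, `classify_clone`,
   `qc_report`, `titer_from_dilution`).
6. **Assay analysis** (`fit_two_state_melt`, `reversibility`,
   `fit_binding_curve`, `absorbance_ratio`, `wound_healing_rate`).

## Annotation model and the CDR gap rule

Full HMM-based numbering of arbitrary antibody chains is out of scope: every
sequence this toolkit handles shares one scaffold, so anchored annotation —
a global alignment to a reference whose numbering is known, with framework
regions required to align at full span length and above a minimum identity
(default 0.7) — is sufficient and auditable. Failures name the worst
framework region.

CDR loops shorter than their IMGT span lose positions symmetrically from the
loop apex outward; when the split is uneven the extra residue goes to the
N-terminal half (IMGT convention). An 8-aa CDR3 in the 13-position span
105–117 therefore occupies 105–108 and 114–117. Loops longer than the span
(the 14-aa CDR3 class) gain inserted positions at the apex, labelled
`111.1`, `112.1`, `111.2`, … with the first extra on the N-terminal side;
only the deletion rule is externally fixed, the insertion rule extends the
same apex/N-preference convention.

Alignment is Needleman–Wunsch with match +1, mismatch 0, linear gap −1
(configurable), and identity is matches over alignment columns, gaps
included. That denominator approximates CD-HIT behaviour closely enough at
the 90% threshold used for redundancy removal; CD-HIT's word-filter
heuristics are deliberately not reproduced — exactness beats speed at desk
scale. The clustering join condition is strictly `identity > threshold`,
mirroring the "similarity > 90%" curation rule.

## Scaffold humanization

The four FR2 hallmarks (IMGT 42, 49, 50, 52) separate VHH frameworks from
human VH3. Partial humanization of 49/50 toward the nearest human germline
is the first step (Q49G, R50L on the packaged demo template); substitutions
to leucine at position 50 carry a caution flag, because R50 belongs to the
highly conserved consensus framework and its loss trades thermostability for
aggregation at high concentration. Three further substitutions are drawn
from a distilled framework consensus, ranked by conservation (descending),
then germline agreement, then ascending position — the source material does
not identify its three consensus positions, so this deterministic, auditable
ranking is the package's own design choice. Humanness is scored as
framework-only germline identity by default (CDRs are diversified anyway).

The packaged `nf_template()`/`nf_germline()`/`demo_consensus()` fixtures are
**synthetic stand-ins**: no template or germline sequence is printed in the
source material. They are constructed so the canonical design events occur
(2 hallmark + 3 consensus = 5 substitutions, humanness 0.913 → 0.967) and
are named accordingly in their documentation.

## Diversity design

CDR1 and CDR2 use a constant length of 8 aa; CDR3 comes in three classes (8,
11, 14 aa, uniform weights by default). Hydrophobic-core anchors (I29, I56,
T65, Y117) and loop-flexibility anchors (G27, A35, G63, A105) are "retained
or slightly randomized": their target distribution is `anchor_floor`
(default 0.5) of mass on the anchor residue plus the renormalized natural
distribution on the rest. The floor is a package choice — no number is
published for "slightly" — and is configurable. All other CDR positions
mimic the natural positional profile. Cysteine mass is always removed and
redistributed proportionally, and stop codons are penalised, reflecting
"avoided as much as possible" rather than forbidden.

Degenerate codon choice is an exhaustive search over all 15³ = 3375 IUPAC
triplets minimizing total-variation distance to the target (stop codons are
a 21st category with zero target mass) plus soft penalties
`stop_penalty * stop_fraction + cys_penalty * cys_fraction` (defaults 10 and
5). TV was chosen over KL because targets routinely have zero support.
Ties break by lexicographic triplet order, which is why a uniform
{D,A,Y,S} target returns `KMC` rather than the equally optimal `KMT`. A
single triplet per position mirrors degenerate-primer synthesis; exact
trinucleotide mixes (divergence 0 by construction) would be the natural
upgrade and the target distributions emitted here are exactly what such a
synthesis would order.

## Library build and QC

The coding sequence is split mid-FR3: an upstream fragment carries CDR1/CDR2
degeneracy (primer pair F-2/R-2), a downstream fragment per CDR3 length
class carries CDR3 (F-3/R-3), and the flanking pair adds an SfiI site
upstream and NotI downstream. Fragments share a non-degenerate ≥15-nt
overlap and `assemble_in_silico` re-joins them, erroring at the first
mismatched junction base.

`sample_library` instantiates every degenerate base uniformly over its
expansion, which is exactly the distribution a degenerate primer pool
realises. The error simulator applies per-clone no-insert (default 0.04)
and large-deletion (0.03, 15–100 nt) events, then per-base substitutions
(10⁻³), insertions and deletions (3 × 10⁻⁴ each) — rates typical of
multi-cycle PCR assembly. With the resulting defect spectrum, simulated
correctness rates land near the ~70% observed when sequencing real
assemblies, without any parameter having been fitted to do so.

Clone classification follows a fixed priority: `no_insert` (reference
coverage < 0.5) → `large_region_missing` (≥15 nt contiguous loss, or an
equal net loss, since degenerate reference positions can absorb gap-run
edges) → `base_shifting` (net indel not divisible by 3) → `base_missing`
(in-frame indel) → `stop_codon` → `correct`. "Base missing" versus "base
shifting" is not defined in the source taxonomy; in-frame deletion versus
frameshift is this package's fixed interpretation. Missense point
substitutions do **not** demote a clone: the taxonomy has no missense
category, and at degenerate positions a missense is indistinguishable from
design diversity. This also makes classification invariant to synonymous
substitutions by construction.

`titer_from_dilution` uses the standard 30–300 countable-colony convention
by default; the range is an argument because published worked examples
(e.g. 370 colonies at 10⁷-fold dilution → 3.7 × 10⁹ cfu) sit outside it.

## Assay models

* **CD melt**: mean-residue molar ellipticity
  (`raw / (10 · path · conc · residues)`; the convention is recorded in the
  output because the source says only "molar ellipticity"). The melt model
  is a two-state sigmoid with linear baselines,
  `θ(T) = (aF + bF·T)·f + (aU + bU·T)·(1 − f)`,
  `f = 1/(1 + exp((T − Tm)/w))`, fitted by `nls` (port) with a
  deterministic initialization (Tm₀ at the steepest numerical gradient,
  baselines from the outer temperature quartiles) and a Nelder–Mead fallback
  on the same start. A transition is declared only when the signal change
  exceeds `min_snr` (default 5) times the point-to-point noise. A van't
  Hoff ΔH is emitted but is not part of the contract.
* **Reversibility** is the baseline-corrected folded-amplitude ratio after
  melt-and-cool, in percent.
* **Binding**: a four-parameter logistic; the fitted EC50 is reported as the
  apparent KD of an indirect ELISA — no kinetic (SPR-style) model is
  implied. A seeded residual bootstrap (199 replicates) gives a percentile
  CI; fits are flagged unreliable for flat responses, non-saturating series
  or EC50 outside the concentration range.
* **Positivity** uses the strict rule ratio > 2 (a ratio of exactly 2 is
  negative), and the wound-healing rate is exactly
  `(area₀ − areaₜ)/area₀ × 100`, with negative values (wound growth)
  flagged rather than clipped.

## What the synthetic generators do and do not emulate

`gen_repertoire` draws sequences position-wise: weakly conserved non-anchor
CDR positions (scaffold residue kept with probability 0.35), strongly
conserved anchors (0.9), a small framework substitution rate (0.02), and
optional length-conditional hallmark distributions for planting
hallmark–CDR3-length associations. These choices emulate the *marginal*
positional statistics of a curated natural repertoire. They deliberately do
not emulate: phylogenetic correlation between positions, indels inside
frameworks, CDR3 length distributions beyond the configured classes, or
selection-driven covariation between loops. A green test against generated
data therefore establishes that the statistics and fits recover what was
planted — not that the generator is a faithful model of any real repertoire,
and not any wet-lab quantity (measured library size, hit counts, measured
Tm/affinity), which are out of reach at desk scale by construction.

`gen_melt_curve` and `gen_binding_series` evaluate the same parametric
models the fitters assume, plus Gaussian noise; recovery tests are therefore
self-consistency checks with known ground truth, exactly as intended by the
acceptance contract (median Tm error ≤ 0.5 °C over 100 replicates at 2%
noise; EC50 bootstrap CI covering the generating 22.16 nM value).

## Numerical and degenerate-input choices

* Frequencies are renormalized exactly; profile rows sum to 1 within 1e−9,
  and zero-support positions are `NA`-marked rather than invented.
* Consensus ties break alphabetically and are flagged.
* Empty curation survivor sets are flagged, not errors; empty repertoires
  are errors.
* All simulation, sampling and bootstrap paths take explicit seeds and
  restore the caller's RNG state.
* Back-translation uses one fixed codon per residue, so
  `translate_nt(back_translate(x)) == x` exactly.

## Known limitations

* The identity definition (matches over columns) differs slightly from
  CD-HIT's shorter-sequence denominator; at the 0.9 threshold on
  full-length VHHs the clusterings agree in practice.
* Single-triplet codon design cannot hit arbitrary targets (typical TV
  divergence 0.2–0.5 at hypervariable positions); the divergence table in
  `spec_summary` quantifies this per position.
* The in-silico insert-positivity call (coverage ≥ 50%) is a stand-in for a
  colony-PCR band call and has no biological calibration.
* `annotate_regions` requires full-span frameworks; framework indels fail
  annotation rather than being gapped.
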