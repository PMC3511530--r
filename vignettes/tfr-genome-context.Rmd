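---
title: "Predicting TetR-family regulator targets from genome context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting TetR-family regulator targets from genome context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfrctx)
```

## The problem and the model

TetR-family transcriptional regulators (TFRs) are among the most abundant
one-component regulators in bacteria: a conserved N-terminal helix-turn-helix
DNA-binding domain (Pfam PF00440) coupled to a variable C-terminal
ligand-sensing domain. The handful of well-characterized members — TetR
itself, QacR, SimR, EthR — overwhelmingly follow one architecture: the
regulator is transcribed head-to-head (divergently) with its target gene, the
shared intergenic DNA carries the promoters of both genes, and the TFR dimer
represses the target (and usually itself) by binding a palindromic operator in
that shared DNA. tfrctx operationalizes this paradigm as a predictive method
that needs nothing but a genome annotation:

1. **Context classification.** Every TFR gene is assigned to exactly one of
   three groups by the orientation of its immediate neighbors in coordinate
   order. *DIVERGENT*: the neighbor on the TFR's 5′ side is transcribed
   head-to-head with it, at any distance. *OPERONIC*: no divergent partner,
   but an immediate same-strand neighbor lies within a small ORF-to-ORF gap
   (default 35 bp, overlaps included), so the two genes are probably
   co-transcribed. *OTHER*: neither relationship. A TFR with a divergent
   partner on one side and a co-transcribed neighbor on the other stays in
   the divergent group, flagged `mixed_flag`.
2. **Separation.** For each divergent pair the separation is the number of
   bases strictly between the first bases of the two start codons.
   Transcription start sites are unknown for nearly all of these genes, so
   translational starts are the only coordinates available genome-wide.
   Annotated start codons occasionally overlap; the raw signed value is kept
   for diagnostics and clamped at 0 for reporting.
3. **The distance rule.** A divergent neighbor within 200 bp of its TFR is
   predicted to be directly regulated by it. Experimentally, every tested
   TFR at < 200 bp repressed its neighbor, while pairs at 212–601 bp showed
   no repression (one, at 425 bp, is an activator — correctly a
   non-prediction under the rule, which claims a regulatory relationship
   only for close pairs).
4. **Operator discovery.** Because TFRs bind as dimers, operators are
   inverted repeats. The scanner enumerates candidate centers and grows
   arms outward under a mismatch budget, reporting maximal sites.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `operon_gap_max` | 35 | bp | ORF-to-ORF gap below which same-strand neighbors are treated as co-transcribed; negative (overlapping) gaps qualify |
| `target_distance_max` | 200 | bp | the distance rule's threshold between translational starts |
| `threshold_inclusive` | TRUE | — | ≤ vs <; no characterized pair sits exactly at 200 bp, so the two readings are indistinguishable on real data. We default to inclusive and expose the flag |
| `min_arm` | 5 | bp | shortest operator half-site worth reporting; characterized TFR operators have arms of 5–8 bp |
| `max_loop` | 6 | bp | loop (spacer) between arms; observed loops vary freely in content and length |
| `max_mismatch` | 2 | — | non-complementary arm pairs tolerated; real operators deviate from perfect palindromy at up to a few positions |

The scan defaults were chosen so that every one of the fourteen packaged
footprint-derived operator sequences from seven characterized TFRs is
recovered (`operator_site_fixtures()`), and they are regression-tested
against that panel.

## Semantics worth stating precisely

**Orientation test.** For a `+`-strand TFR only the left neighbor can face
it head-to-head; for a `-`-strand TFR only the right one. Geometry therefore
guarantees at most one divergent partner per TFR, and the three groups
partition any TFR set.

**Operon gap vs separation.** Co-transcription concerns ribosome
re-initiation and shared transcripts, so the operonic test measures the gap
between ORF extremes (stop of one gene to start of the next). The distance
rule instead measures between translational starts, because the shared IGR
of a divergent pair is delimited by the two start codons.

**Inverted-repeat maximality.** For each center (a gap position widened by a
loop of 0..`max_loop` bases) the arm is extended outward while the mismatch
budget holds, `N` never matching. Only the longest arm per center is
reported, and a site spanned by a reported site with a strictly longer arm
and no more mismatches is suppressed. This matters because one DNA segment
can read as a palindrome in several arm/loop decompositions — a 15-mer
operator reads both as arm 7/loop 1 and arm 6/loop 3 — and only the maximal
rendering is useful. Sites are ordered by offset, then decreasing arm, then
loop, making output deterministic.

**Placement zones.** Site midpoints are expressed as a fraction of IGR
length measured from the TFR's translational start; thirds (`cut_low` = 1/3,
`cut_high` = 2/3) bucket sites into TFR-proximal, central and
target-proximal zones. The cut points are conventional, not biological
constants, and are exposed as arguments.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` builds annotated linear replicons in which every TFR's
context is planted and recorded: divergent partners at sampled separations
(default uniform on 0–1123 bp, the observed range in the three surveyed
streptomycete genomes), operonic neighbors at gaps of 0–35 bp, background
sequence i.i.d. at GC 0.72 (streptomycete-like), group proportions
defaulting to the observed survey mix (67.2% divergent, 14.8% operonic, 18%
other), and perfect inverted-repeat operators written into divergent IGRs at
recorded offsets. Start codons are always rendered ATG.

Deliberate simplifications: no codon structure, no promoter elements beyond
the planted operators, no gene-length or gap-length realism beyond ranges,
no phylogenetic signal. Planted operators receive non-complementary
flanking bases and loops whose symmetric positions never complement, so the
planted geometry is the unique maximal rendering at its center and exact
offset/arm recovery is well-defined. Incidental background palindromes are
permitted and do occur (they are more frequent at high GC); the recovery
metric counts planted-offset hits only. Consequently, passing recovery
tests demonstrates that the classification and scanning machinery is
internally correct — not that the distance rule itself is biologically
valid on an arbitrary genome, which rests on the published experimental
evidence summarized in `tfr_reference_panel()`.

## Numerical and design choices

- Coordinates are 1-based inclusive throughout the gene model (GenBank/GFF3
  native); BED output converts to 0-based half-open at write time. Site and
  match offsets within scanned sequences are 0-based.
- Compound (joined) CDS locations collapse to their extremes; bacterial CDS
  joins are rare and the method uses only gene bounds.
- Only CDS features become genes by default (`cds_only = TRUE`); whether RNA
  genes should count as neighbors is unsettled, so a flag admits all
  feature kinds.
- Missing topology metadata defaults to linear, matching the actinomycete
  chromosomes the method was developed on; terminal genes of linear
  replicons have absent outward neighbors, circular replicons wrap.
- Exact-coordinate duplicate annotations of a query gene are ignored during
  neighbor search; ordering ties break by locus tag for determinism.
- Consensus building has two modes: the default emits `N` at any
  disagreeing column (matching how degenerate operator consensi are usually
  written), strict-IUPAC mode emits the minimal covering code.
- In the built-in product-category rules, transporter rules outrank enzyme
  rules: ABC pumps carry nucleotide-binding domains that look enzymatic but
  are counted as membrane transporters. EC classes come from explicit
  "EC n" tokens or mapped domain superfamilies only; no four-digit EC
  inference. A target matching no rule is UNKNOWN — the category system
  does not guess from uninformative text.
- Annotation releases drift: bundles record the input file's MD5 checksum
  rather than assuming a database version.
- Report bin edges are [0,100], (100,200], …, so the ≤200 bp count equals
  the sum of the first two bins; bin width is a parameter.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely from generated or
packaged desk inputs: recovery is verified on twenty 10-TFR replicons
(seed-derived), the scanner is checked against a brute-force
enumerate-every-triple oracle on 500 (tests) / 150 (script) random 60-mers,
and survey-scale behavior on a single 250-TFR replicon. These sizes keep
the whole suite in the minutes range while exercising every code path; the
pipeline itself handles full bacterial chromosomes (the classification is
linear in gene count).

## Known limitations

- The distance rule claims a *regulatory relationship*, not a mechanism:
  activation versus repression is not predicted, and the published
  exception (an activator at 425 bp) shows distant pairs can still be
  functional.
- Pairs slightly above threshold (e.g. 212 bp) sometimes bind in vitro
  without measurable regulation; no "near-threshold" band is modeled
  because none is defined operationally.
- Direct (tandem) repeats, which co-occur with palindromes in some real
  operators, are not detected — only inverted repeats are.
- Real-genome validation requires the public annotations (EMBL/GenBank
  AL645882, AP009493, BA000030), which are too large to redistribute with
  the package; the corresponding checks look for user-supplied copies under
  `inst/extdata/real/` and fail with an explanatory message otherwise.

## A worked example

```{r example}
fx <- generate_fixture(fixture_spec(n_tfr = 12, seed = 101))
calls <- classify_context(fx$bundle, fx$truth$locus_tag)
preds <- predict_targets(calls)
igrs <- extract_igr(fx$bundle, calls)
sites <- scan_igrs(igrs, max_mismatch = 0)
evaluate_recovery(fx$truth, calls, sites)

summary <- summarize_tfr_context(calls, preds)
glance(summary)
```

```{r plot, fig.width = 6, fig.height = 3.5}
autoplot(summary)
```
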