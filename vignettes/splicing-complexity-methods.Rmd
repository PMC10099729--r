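---
title: "Methods: splicing complexity on contiguous splice graphs"
author: "splicentropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splicing complexity on contiguous splice graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicentropy)
```

## The model

A gene's transcript annotation is collapsed into non-overlapping exonic
*nodes*: the coordinate line is cut at every exon boundary of every
transcript, and the maximal covered segments between cuts become nodes,
numbered 1..N in transcription order (reverse of genomic order on the minus
strand). Two edge kinds connect nodes: *adjacency* edges between genomically
contiguous nodes that co-occur inside one exon, and *junction* edges for
splice junctions. Every annotated transcript is then exactly a path through
this contiguous splice graph, and every exon is an exact concatenation of
nodes — both properties are asserted in the test suite against a brute-force
interval-partition oracle.

Each node defines a local *event*. Its anchors are the nearest upstream and
downstream nodes traversed by every transcript spanning the node's position;
all distinct edge paths between the anchors are enumerated by depth-first
search. For terminal events (alternative first/last exons, tandem
start/polyadenylation sites) one anchor may not exist, and enumeration
starts from (or ends at) the distinct terminal nodes of the spanning
transcripts. Single-exon genes and single-transcript genes still build
graphs; their nodes carry one-path events, which is what makes constitutive
calls possible.

Given per-sample edge read counts, path abundances are estimated by EM:
the E-step distributes each edge's count over the paths containing the edge
proportionally to current abundances; the M-step averages each path's
assigned reads over its number of edges and renormalises. The per-edge
averaging matters: a two-junction inclusion route supported by 30 reads per
junction and a one-junction skip route with 20 reads must yield
Ψ(inclusion) = 30/(30+20) = 0.6, not 60/80. This estimator is also the
exact fixed point under the read model used by the simulator, where an
edge's expected intensity is the summed abundance of the paths containing
it.

Three per-event summaries follow:

- node Ψ: summed abundance of node-containing paths;
- splicing entropy `E = −Σ Ψᵢ log₂ Ψᵢ` (bits), with `0·log₂0 = 0`;
- complexity bin `K(n)`, `n = ⌈log₂(path count)⌉`, so `E ≤ n` (one path is
  K0).

## Thresholds and their defaults

All thresholds are the canonical values of this analysis family and are
configurable at each call site:

| parameter | default | meaning |
|---|---|---|
| constitutive Ψ | 0.97 | alternative iff 0 < Ψ < 0.97, constitutive iff Ψ ≥ 0.97 |
| expressed gene | TPM ≥ 1 | host-gene expression filter |
| event support | ≥ 10 reads | total reads on the event's edges |
| high complexity | entropy ≥ 1.0 bits | ≥ two effective outcomes (1.5 as stricter variant) |
| ΔΨ call | \|ΔΨ\| ≥ 0.1, posterior ≥ 0.85 | differential splicing vs the reference stage |
| Dev event | ≥ 5 significant stages | developmental regulation |
| entropy dynamic | range ≥ 0.5 bits | over ≥ 5 stages with > 20 reads and > 10 TPM |
| tau split | 0.3 | low vs high tissue specificity |
| expression split | TPM 50 | low vs high expression genes |
| dN/dS split | 0.0993 | slow vs fast evolving genes |

The `K{n}_{m}` ten-class scheme bins Ψ as Low (0, 0.2], Middle (0.2, 0.8)
and High [0.8, 0.97), crossed with K1/K2/K3; the printed boundaries place
Ψ = 0.2 in Low and Ψ = 0.8 in High, and we implement them exactly as
printed. K ≥ 4 events are folded into the K3 classes for the ten-class
scheme (the full bin is kept in the event table); whether the original
figure scheme folds or drops them is not stated, and folding preserves
events. An event quantifiable in one tissue but not alternative-quantified
in the other (no reads, Ψ = 0, or constitutive Ψ ≥ 0.97) is "Others";
events unquantifiable in both tissues of a pair are dropped.

## Node typing

The eight node types are assigned by an ordered rule cascade (first match
wins): RI → AF → AL → TS → TE → AA → AD → CE.

- **RI**: adjacency to both transcription-order neighbours in some
  transcript while a junction connects those neighbours directly (the node
  spans exactly the retained intron).
- **AF/AL**: a node that is terminal in every transcript containing it,
  attached by a junction, in a gene with ≥ 2 distinct terminal nodes on
  that side.
- **TS/TE**: terminal nodes attached only by adjacency (tandem start /
  polyadenylation extensions).
- **AA/AD**: internal extension nodes contiguous with a neighbour that
  other transcripts junction into (acceptor side) or out of (donor side)
  directly.
- **CE** is the fallback for internal junction-flanked nodes; nodes joined
  only by adjacency everywhere are **NONE**.

The typing cascade is a deterministic operationalisation of type names that
are commonly used without formal definitions; it is tested on constructed
examples of each type and on the simulator's round trips, and we make no
claim of bit-equivalence with any external quantifier's typing.

## Parsimony ages

Orthologous events (the orthology map is consumed as input; first and last
transcript exons are excluded upstream) get one state per species: A if
alternative in ≥ 1 tissue, C if constitutive in all quantifiable tissues,
NA otherwise. On the rooted species tree, every single-change scenario —
one gain or one loss on one branch — is enumerated exhaustively. Uniform
patterns give the conserved classes (VCA/VCC). Root-split patterns matching
the designated outgroup receive the dedicated mammal-conserved labels
(MCA/MCC); these are exactly the patterns with two scenarios (ingroup gain
or outgroup loss), which is why they carry their own labels rather than a
branch label. Other single-change patterns are labelled by the smaller
changed clade (`human_gain`, `human-chimpanzee_gain`, ...), with every
consistent scenario recorded; how equally parsimonious non-root ties should
be labelled is not specified anywhere we know of, so we record all
scenarios and label deterministically by the smaller clade. Patterns with
no single-change explanation are `complex`. Multi-leaf clades are named by
their two outermost members in tree order. By default events with any NA
state are `unassignable` (the canonical complete-data analysis); a tolerant
mode drops NA leaves and runs on the induced subtree, and is explicitly
non-canonical.

The implementation is verified against an independent brute-force
enumerator on all 2⁷ = 128 complete leaf patterns and against planted
single-change histories (100% branch recovery required).

## Developmental calls

The posterior ΔΨ model is a design choice of this package: inclusion and
exclusion reads of each condition define a Beta(incl + 0.5, excl + 0.5)
posterior (Jeffreys prior), and the posterior probability of change is the
fraction of paired draws with |Ψₐ − Ψᵦ| ≥ 0.1 (2,000 draws by default,
checked against a 10⁶-draw oracle within Monte-Carlo error). The underlying
published pipeline names its thresholds but not its estimator, so the model
here is stated openly and kept configurable. For multi-path events the
binary inclusion/exclusion split sums reads on node-containing versus other
paths; entropy always uses the full path distribution.

## The synthetic-data generator

The generator emulates a comparative study design — six tissues, seven
species with chicken outgroup, ten developmental stages — and is the
package's test bed. What it does and does not capture:

- **Gene models**: 200 genes by default, 4–8 exons, one alternative
  isoform per gene instantiating a configured event-type mix; half of the
  cassette genes also carry an acceptor-extended inclusion isoform, giving
  three local paths (K2) — without this, cassette events are capped at
  1 bit of entropy and high-complexity analyses would be degenerate.
  Every intended event is verified to appear in the built graph.
- **Abundances**: symmetric Dirichlet draws. The two-regime schedule
  (concentration 0.15 with probability 0.65, 10 otherwise) produces the
  bimodal entropy landscape seen in real tissue data: a near-one-hot mode
  and a near-uniform mode with a trough between. The low concentration was
  chosen so that the low mode puts substantial mass below 0.5 bits for
  typical 3–4 path events.
- **Reads**: one multinomial draw per event over the event's edges, with
  edge intensity the summed abundance of paths containing the edge; reads
  are simulated at edge level, not as sequences — alignment is out of
  scope and edge counts are the quantification input contract. No
  length, GC or positional bias is modelled; a real library's biases are
  absent, so passing tests demonstrate correctness of the estimators, not
  robustness to alignment artefacts.
- **Evolution**: per-branch gain/loss flips from a root state, with a
  rejection-sampled single-change mode recording the flipped branch. In
  the full study, each event's true age rank (species-specific < clade <
  mammal-conserved < vertebrate-conserved) sets the Dirichlet
  concentration of its base abundances (0.25 / 0.5 / 0.9 / 1.8), coupling
  entropy to age; tissues jitter around the event's base with precision
  40, because events have an intrinsic splicing character that tissues
  modulate. These concentrations were calibrated once so that the
  per-rank probability of a ≥ 1-bit maximum entropy spans a dynamic range
  comparable to published age-group ratios (roughly 0.4 to 0.95).
- **Development**: Dev-true events follow a logistic Ψ sweep with midpoint
  at one third of the series and slope 1.5 per stage — an
  early-development switch, which is where most developmental splicing
  transitions concentrate; with amplitude 0.3 at depth 200 this yields
  ≥ 90% call power while constant-Ψ nulls stay under the 5% false-call
  bound. Entropy-dynamic events sweep the within-route split from 0.97 to
  0.5, changing entropy by ~0.8 bits while leaving Ψ untouched — the
  factorised abundance construction makes "entropy change without Ψ
  change" exactly true, which is the phenomenon the dynamic flag isolates.
- **What is not emulated**: cell-type composition (bulk series only),
  annotation incompleteness, read errors, GC bias, expression-level
  variation across genes within a sample (host TPM is an input, not a
  simulated quantity).

## Numerical choices

- EM: uniform initialisation, L1 tolerance 1e-6, 1,000 iteration cap;
  all-zero counts return uniform abundances flagged `no_data`; events
  whose path count exceeds `max_paths = 128` are flagged truncated and
  excluded from quantification.
- `complexity_bin` subtracts 1e-12 before `ceiling` so exact powers of two
  are never pushed into the next bin by floating-point error.
- Down-sampling is multivariate hypergeometric (sequential `rhyper`),
  preserving the target total exactly and reproducibly.
- Cross-validated regression metrics: PCC/SCC are averaged over held-out
  folds rather than computed on pooled predictions — pooled correlations
  acquire a spurious negative bias under the null from fold-mean shifts —
  while R² is pooled. Importance is permutation importance on held-out
  data (increase in pooled MSE), identical across model families.
- Splice-site PWMs are trained from the annotation's own splice sites
  (donor 3 exonic + 6 intronic nt; acceptor 20 intronic + 3 exonic nt)
  with pseudocount 1 and scored as log₂ odds against a uniform
  background; `N` bases contribute 0.
- All generator outputs are pure functions of (configuration, seed); seeds
  are kept below 2³¹.

## Problem sizes

The default test and acceptance workloads use 200-gene studies (seven
species × six tissues), 200-event developmental subsets, 500-replicate
null calibrations, 200-replicate EM/power checks, the full 128-pattern
parsimony enumeration and 1,000 planted histories. These sizes give stable
Monte-Carlo estimates (binomial standard errors below ~2 percentage
points on the reported rates) while keeping a full run in the low minutes
on one CPU.

## Known limitations

- The node-typing cascade and anchor semantics are a stated approximation
  of informally defined type vocabularies; corner cases (nested events,
  overlapping terminal structures) resolve deterministically but possibly
  differently from other tools.
- The feature set for entropy regression is a documented ~17-feature
  subset of the much larger catalogues used by dedicated exon-profiling
  tools; the reader for external feature tables accepts drop-in
  replacements.
- Orthology is consumed, not computed; coordinate lifting quality directly
  bounds the evolution module's usefulness on real data.
- The Beta-posterior ΔΨ model is a stand-in for unpublished estimators in
  the tools whose thresholds it shares; calls at the 0.85/0.1 boundary
  should not be over-interpreted.
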