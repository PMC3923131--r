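---
title: "Scanning transcripts for coupled termination–reinitiation candidates"
author: "reinitScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning transcripts for coupled termination–reinitiation candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reinitScan)
```

## The biological problem

Most eukaryotic mRNAs are treated as monocistronic, yet a 3′ UTR can hide a
second open reading frame. One route into such an ORF is coupled translation
termination–reinitiation: a ribosome that finishes a long 5′ ORF (ORF-1)
relocates a short distance — here upstream — and reinitiates at an AUG of an
overlapping second ORF (ORF-2) held in a different reading frame. The process
is distance-dependent, favouring ORF-2 start codons close to the ORF-1 stop,
and in the cellular transcripts where it has been demonstrated it depends on
a run of aspartate codons at the ORF-1 carboxyl terminus: in a +1 frame
offset, GAU-GAU aspartate repeats in ORF-1 read as AUG-AUG in ORF-2's frame,
so a single nucleotide stretch simultaneously encodes the terminal aspartates
of one protein and the initiation codons of the next.

`reinitScan` implements the transcript screen for this configuration as a
reusable library: ORF-pair scanning, a four-factor joint-probability ranking
score, homology-based rejection, overlap-motif analytics, and designers for
the mutant constructs used to probe the mechanism experimentally.

## The pair criteria and their geometry

A candidate is a pair of AUG-initiated, stop-terminated ORFs in different
frames of the same (forward-strand) transcript, each at least `minOrfLen`
(default 150 nt, stop codon included), overlapping by `overlapMin` to
`overlapMax` nt (default 4–120). Every AUG upstream of an in-frame stop is an
ORF start; per (frame, stop) group the 5′-most AUG represents ORF-1,
mirroring annotated-CDS convention. Among ORF-2-frame AUGs that begin within
`window` (default 120) nt of the ORF-1 end, the one giving the *smallest*
overlap still at or above `overlapMin` is the canonical ORF-2 start; the
5′-most sets `overlap_len_max`. An AUG closer to the ORF-1 end than
`overlapMin` does not promote a more 5′ AUG to canonical status: the strict
reading of the bounds rejects the configuration.

Two arithmetic facts shape reported lengths, and both follow from the frame
offset. With ORF-2 in the +1 frame, the distance from an ORF-2 AUG to the
ORF-1 end is always ≡ 2 (mod 3) (≡ 1 for a +2 offset); it can never be a
multiple of 3, and an overlap of exactly 5 nt is impossible outright (the
AUG's G would have to be the first base of the stop codon, which is U).
Display conventions for overlap regions, however, quote whole ORF-1 codons
from the codon that supplies the 5′-most ORF-2 AUG through the stop — one or
two nucleotides more than the AUG-to-end distance. `overlapRegionLen()`
returns this codon-aligned length (`overlap_len_max + frame_offset`); for the
CASQ2-like fixture it is 81 nt while `overlap_len_max` is 80. The synthetic
generator enforces the same feasibility rules and refuses overlap lengths
divisible by 3 (or equal to 5) before drawing any random numbers.

ORF-2 must terminate at a stop codon inside the transcript by default
(`requireOrf2Stop`); the screen looks for bona fide second proteins, not
fragments running off a truncated model. ORFs spanning an ambiguous N are
suppressed because the screen depends on exact codon identity. Coordinates
are 0-based half-open throughout the API; only presentation layers convert.

## The ranking score

Candidates are ranked by the product of four tail probabilities; the less
probable the observed features under a background model, the stronger the
candidate. The null model is deliberately the simplest one consistent with
"probability of at least the observed count": bases are i.i.d. with
composition-derived frequencies \(f_A, f_C, f_G, f_U\) (per transcript by
default; corpus-wide or uniform by option), codons are independent, and

* `p_starts` — \(P(X \ge k)\) for \(X \sim \mathrm{Bin}(n, f_A f_U f_G)\),
  with \(k\) the ORF-2-frame AUG count in the 120-nt window abutting the
  ORF-1 end and \(n\) the number of complete ORF-2-frame codon positions in
  that window. The window is anchored at the end of ORF-1, the only anchoring
  consistent with counting reinitiation codons upstream of the ORF-1 stop.
* `p_trailing` — \(P(Y \ge m)\) for \(Y \sim \mathrm{Bin}(k, f_A + f_C)\),
  with \(m\) the number of those AUGs immediately followed by A or C (a
  favourable-context feature); defined as 1 when \(k = 0\). Conditioning on
  the observed \(k\) (rather than on the window size) was an open choice;
  conditioning keeps the two factors closer to independent.
* `p_orf2_len` — the probability of an ORF at least as long under the
  i.i.d.-codon null: \((1 - p_{stop})^{c}\) with \(c\) the number of internal
  sense codons (length/3 − 2; start and stop excluded) and
  \(p_{stop} = f_U f_A f_A + f_U f_A f_G + f_U f_G f_A\).
* `p_overlap` — the probability of an overlap no longer than observed, an
  inclusive discrete-uniform CDF over the allowed range:
  \((\ell - 4 + 1)/(120 - 4 + 1)\), so the minimum overlap scores
  \(1/117\) rather than 0. A zero factor would collapse the product and make
  ranking degenerate, which is why the CDF is inclusive.

The factors are combined by plain product (no weighting information exists to
justify anything else) and candidates are ordered by ascending joint score,
ties broken by transcript id then ORF-1 start. The binomial tails are
computed by explicit exact summation of log-space terms, summed smallest
first; tests require agreement with `pbinom` to 1e−12 relative for
\(n \le 64\), the regime the 40-codon window actually occupies. Degenerate
compositions are handled at the boundary: \(p_{AUG} = 0\) with zero observed
starts scores 1, and with a positive count it is an error, because the
observation is impossible under the model.

## Homology rejection

The screen consumes 12-column tabular BLAST output rather than running BLAST.
Two rules, threshold \(E < 10^{-5}\) (strict), applied with rule 1 first:
a pair whose ORF-1 and ORF-2 both hit the *same* subject is rejected as a
likely misannotation of a single protein; a pair whose ORF-1 hits nothing is
rejected as a misidentified first ORF. "Same protein" means same subject
identifier — no cluster expansion — and ORF-2-only matches carry no weight.
Hit queries follow the package's own `"<transcript>:ORF1|ORF2"` id
convention, since the upstream literature defines none.

## Construct designers

Each designer returns a `MutantConstruct` whose validity proves the edit
list reproduces the mutant from its parent, with every design constraint
evaluated in an attached report:

* **STOP mutant** — substitutes U→C at the first base of the ORF-1 stop
  (UAA→CAA, UAG→CAG, UGA→CGA). One deterministic rule abolishes all three
  stops; the exact bases used in the published wet-lab constructs are not
  printed, so this canonical choice is the package's own. The reported
  next-stop distance is divisible by 3 by construction; the bundled
  reporter-context fixture reproduces the published 36-nt displacement.
* **Synonymous de-AUG** — rewrites GAU→GAC wherever the U anchors a non-kept
  ORF-2-frame AUG, leaving the ORF-1 protein untouched. An AUG not backed by
  a GAU codon cannot be removed synonymously; the design aborts rather than
  emit a partial construct.
* **AUG knockout** — verbatim codon replacement by ordinal (ACG/AGC/AGA in
  the published series), for probing which reinitiation codon is used.
* **Constrained scramble** — seeded rejection sampling over permutations of
  the region with the ORF-1 stop and the termination-proximal AUG pinned in
  place; accepted permutations preserve the nucleotide multiset, introduce
  no premature ORF-1 stop, leave no aspartate run of ≥ 2 and no surplus
  ORF-2 AUG. Rejection sampling over full permutations was chosen over
  constraint-directed construction because every accepted output is trivially
  verifiable; the CASQ2-like region accepts within a handful of iterations.
* **Residue swap** — replaces non-kept occurrences of one residue with
  minimal-edit codons of another (ties to the alphabetically smallest codon,
  so D→E rewrites GAU to GAA), covering the D/E and D/E-plus designs and the
  serine variant.

## Fixtures and the synthetic generator

The published figures print the overlap sequences of the five coupled genes
and the CASQ2 mutant series; those figure sequences are not redistributed in
this package. The bundled regions under `inst/extdata/synthetic_overlaps/`
are **synthetic stand-ins** constructed to satisfy every property the text
states — the CASQ2-like region is 81 nt with 15 ORF-2-frame AUGs in three
clusters (6, 5, 4) written as GAU repeats; its A/G mutant differs at exactly
27 positions, all A↔G transitions; the GAU/GAC mutant is ORF-1-synonymous and
keeps the first, one central and the last AUG; NT5C2- and TMEM97-like
regions are glutamate- and lysine-rich with no aspartate motif. Checksums are
committed so a drifted file fails loudly. Conclusions that depend on the
true base-for-base sequences (and all wet-lab quantities) are out of reach of
these fixtures by design.

`plantCandidate()` builds transcripts with one planted pair and full ground
truth. ORF interiors use GC-only filler — which can form no AUG or stop in
any frame — so planted AUG counts are exact by construction, while the UTRs
are i.i.d. draws from the requested composition, re-rolled (bounded, seeded)
until no incidental ≥ 150-nt ORF survives outside the planted groups. The
generator emulates the geometry and composition of real candidates, not
their full biology: no splice structure, no codon-usage bias inside ORFs, no
Kozak-context variation beyond the trailing base. Passing recovery tests
therefore demonstrates scanner and scorer correctness on known ground truth,
not performance on real transcriptomes.

## Validation scale and numerical choices

The test suite checks the scanner against a naive cubic-time oracle on 200
random transcripts of 0.3–2 kb (plus 80 more in unit tests), recovers 20
planted geometries spanning overlaps 4–119 nt and 1–15 AUGs, verifies the
binomial tails at 1e−12 relative over \(n \le 64\), and exercises 100 random
GAU-rich regions for the synonymous designer and 20 scramble seeds. These
sizes keep the default suite in the minutes range on one CPU while covering
every feasibility class of the geometry (both frame offsets, the 4-nt
UGA-straddling minimum, the 119-nt maximum).

## Limitations

The screen scans mRNA models, not genomes: forward strand only, no
exon-awareness, no IRES or leaky-scanning prediction, and no attempt to
classify coupling competence from motif content — the aspartate motif is
reported, not scored, because its necessity has been shown for one gene
only. Score calibration against a full-transcriptome distribution and
multiple-testing control are likewise out of scope: the score ranks, it does
not test.
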