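---
title: "Designing guides and quantifying outcomes for CRISPR base editors"
author: "baseEditR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing guides and quantifying outcomes for CRISPR base editors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baseEditR)
```

# Scope and model

Base editors couple a catalytically impaired Cas protein to a deaminase:
cytosine base editors (CBEs, e.g. BE3 or Target-AID) convert C to T (with
occasional C→G / C→A products), adenine base editors (ABEs) convert A to
G. Deamination is efficient only within an *editing window*, a short
stretch of the protospacer conventionally indexed as nucleotides upstream
of the PAM. This package implements the two computations such experiments
need — enumerating candidate guides with their editable bases, and
quantifying editing outcomes from targeted amplicon sequencing — plus a
ground-truth simulator that makes both testable without external data.

# The guide designer

`enumerateTargets()` scans the query sequence and its reverse complement
for PAM matches of the chosen nuclease profile and emits every position
where a full-length spacer fits on the correct side of the PAM (3' of the
protospacer for Cas9-family enzymes, 5' for Cpf1/Cas12a). PAM matching is
degenerate over the 15 IUPAC codes; when the query itself contains
degenerate codes, a PAM position matches when the degeneracy sets
intersect, while a candidate whose spacer or PAM contains a non-ACGT code
is skipped with a warning — such a guide could not be synthesized
unambiguously.

Coordinate conventions, since these are perennial sources of confusion:
internally and in the `start`/`end` columns, protospacer intervals are
0-based half-open on the input forward strand; `relative_position` is the
1-based position of the protospacer 5' end (for a minus-strand candidate
this is the interval's right edge). A window position "d nt upstream of
the PAM" maps to the 0-based spacer offset `spacer_length - d` for a
3'-PAM enzyme. For 5'-PAM enzymes the window is read as nt downstream of
the PAM, i.e. offset `d - 1` counted from the PAM-proximal end of the
spacer; the convention is stated here because no published one exists for
Cpf1-based editors.

Candidates with no editable base in the window are reported and flagged
(`has_editable = FALSE`) rather than dropped — the designer's job is to
show all possible targets and let `filterCandidates(..., requireEditable
= TRUE)` or the CLI's `--require-editable` gate them. Overlapping
matches of short PAMs (xCas9's NG) are all reported, without
deduplication.

The registry holds twelve profiles: SpCas9 (NGG) and its VQR/EQR/VRER
PAM variants, xCas9 3.7 registered once per PAM (NGR and NG) so PAM
semantics stay unambiguous, StCas9 (NNAGAAW), CjCas9 (NNNVRYAC), SaCas9
(NNGRRT), SaCas9-KKH (NNNRRT), and the two Cas12a orthologs AsCpf1 and
LbCpf1 (TTTV, 5'). Spacer length is configurable from 15 to 25 nt with a
default of 20 (22 for CjCas9, 23 for Cpf1, the literature-standard
values). Editor presets: BE3 (window 13–17), Target-AID (15–19), ABE.
An ABE's window is not standardized; the preset defaults to 13–17 (the
BE3 span) and users targeting a specific ABE generation should override
it via `windowOverride`.

# The off-target scan

`findOffTargets()` reports every position on either strand of a genome
FASTA where the PAM pattern matches exactly (degenerately, zero PAM
tolerance) and the adjacent protospacer is within `maxMismatches`
(default 2) Hamming distance of the query spacer — mismatches are counted
over the spacer only, the semantics of the mismatch-bounded scanners this
field uses. Sites overlapping any non-ACGT genome base are excluded: a
mismatch against N is undefined, and exclusion is the conservative
choice. Bulges are out of scope; the algorithm is a sliding scan (PAM
candidates from a degenerate pattern match, then vectorized spacer
comparison) with no index structure, intended for desk-scale genomes —
the tests verify it against a brute-force positionwise oracle up to
100 kb, where it runs in seconds.

# The amplicon analyzer

## Read preparation

FASTQ input (plain or gzip, Phred+33; Phred+64 is out of scope) is parsed
with Biostrings. Paired-end mates are merged by overlap consensus:
read 2 is reverse-complemented, every overlap length from `minOverlap`
(default 6) up to the shorter read is scored by mismatch fraction, and
the best overlap (ties to the longest) is accepted when its fraction is
at most `maxMismatchFrac` (default 0.08) — the defaults of the
overlap-join tools this mirrors. At disagreeing positions the
higher-quality base wins (ties to read 1) and the consensus quality is
the maximum of the two. A rejected pair is dropped and counted, with
reason `mismatch` when the best overlap looks like a genuine overlap
ruined by errors (fraction below 0.5) and `no_overlap` when no candidate
overlap exists or the best one is indistinguishable from chance
(fraction ≥ 0.5, the identity of two random sequences being 25%); the
0.5 boundary is a reporting heuristic only — acceptance is always the
0.08 test. No adapter or quality trimming is performed.

## Indicator filtering

The first and last 15 nt of the reference are its *indicator* sequences.
A read is kept when both indicators occur — left before right — with at
most `maxMm = 1` mismatches each; both the read and its reverse
complement are tried, the orientation with fewer total indicator
mismatches winning (ties to the forward read, a fixed choice since
orientation handling is otherwise unspecified). Retained reads are
trimmed to the span from the left indicator's start through the right
indicator's end, so every query aligned downstream covers the full
reference. Within one orientation the left indicator takes its
minimum-mismatch, leftmost occurrence and the right its
minimum-mismatch, rightmost occurrence after it — a greedy rule that is
exact for amplicon reads, where each indicator occurs once.

## Tally, alignment, classification

Unique queries are counted, sorted by descending count (ties broken
lexicographically so output order is deterministic), and those below
`minFrequency` are discarded. The default is 1 — keep everything —
because a sensible cutoff depends on sequencing depth and error rate,
and silently discarding reads is worse than asking the user to choose.

Each unique sequence is aligned to the reference with a global
Needleman–Wunsch / Gotoh affine-gap aligner (Rcpp): match +5, mismatch
−4, gap opening 10, gap extension 0.5, a length-L gap costing
10 + 0.5 L, end gaps penalized. These are the classic DNA defaults of
the EMBOSS global aligner; all four are exposed as arguments. The
traceback tie-break is fixed (diagonal, then gap-in-query, then
gap-in-reference), making alignments — and therefore entire reports —
byte-reproducible. The test suite checks the scores against two
independent routes: a plain-R DP oracle and `Biostrings::pairwiseAlignment`.

Classification is scoped to the editing window plus the user's flanks
(defaults 5 nt each side; flanks exist because deaminases occasionally
act outside the window, and the profile table spans the same region).
Within that scope: any gap column makes the read an insertion (excess
gaps in the reference row) or deletion (excess in the query row; an
equal-count tie is called deletion — some fixed rule is needed for
conservation, and a tie implies at least one deleted base); otherwise at
least one mismatch column makes it a substitution; otherwise it is wild
type. Gaps or mismatches entirely outside the scope leave a read wild
type — the flanks are the instrument for widening the calling region,
and a practical consequence worth knowing is that nuclease-type indels
at the cut site (3 bp from the PAM-proximal protospacer edge) are only
called when the flanks reach them. A substitution read is *intended*
when at least one window-proper column converts the edited base into a
product base (C→A/G/T for a CBE, A→G for an ABE), strand-adjusted for
minus-strand targets.

## Summary and profiles

The run summary has the nine canonical fields — total reads, reads with
both indicators, reads above minimum frequency, the four class counts,
intended reads, and the intended substitution rate
`intended_in_window / above_min_frequency` — and conservation
(`wt + insertions + deletions + substitutions = above_min_frequency`)
holds by construction and is asserted in the tests. Because a CBE's
intended set is C→D, per-product rates (C→T, C→G, C→A) are reported
alongside so the conventional "C to T substitution rate" is directly
recoverable.

The substitution profile tabulates, per reference position across the
scope, the percentage of each nucleotide among substitution-class reads
covering the position gap-free (weighted by read count), the same over
all classified reads (the heat-map denominator), and at edited-base
positions the per-product transition rate. A control run, when given, is
analyzed with the identical configuration and attached as
negative-signed display rates; positions where the control rate is
positive and at least the treated rate are flagged as background. No
count subtraction is performed — the overlay is a visual comparison, and
subtracting noisy small rates would manufacture certainty.

Amino-acid translations of the scope region are provided for all three
frame offsets (trailing partial codons dropped, stops as `*`), for the
reference sequence; `frameOffset` marks the user's frame in the output.

# The simulator

`simulateEditedReads()` draws each read from the reference with
independent Bernoulli events: the intended conversion at each editable
window position (`intendedProb`), bystander conversions at editable
flank positions (`bystanderProb`), one indel per read with probability
`indelProb` at the nominal cut site with geometric length (editors
produce few indels, but the classifier must be exercised on them), and
uniform per-base errors (`errorRate`, default 0). Qualities are constant
Phred 30 by default so golden outputs stay stable. Paired mode emits the
two amplicon ends read inward with a guaranteed overlap, and merges back
losslessly at zero error. The per-read truth table records what the
analyzer should report — including the scoping rule above, so an
out-of-scope indel is labelled `wt` — and identical seeds give identical
bytes (R's Mersenne-Twister, caller's RNG state restored).
`makeToyGenome()` similarly plants off-target sites with exact mismatch
counts at recorded coordinates in random records.

What the simulator does *not* model: quality-dependent miscall spectra,
PCR chimeras and duplicates, position-dependent error, or real indel
spectra. Passing tests therefore demonstrate correctness of the
computation on its stated model, not robustness to every artefact of
real libraries.

# Problem sizes and numerical choices

The shipped tests run the off-target scan against a brute-force oracle
on a 100-kb seeded genome, the aligner against an exhaustive DP oracle
on 500 random pairs up to length 30, and parameter recovery on 2,000
simulated reads at a 30% edit rate (recovered within three binomial
standard errors, ±0.031); these sizes keep the whole suite under a
minute on one core while still exercising every code path at scale.
Scores are plain doubles (all inputs are halves; no tolerance games are
needed), percentages sum to 100 within 0.01 by construction, and empty
cases — no candidates, no surviving reads, no substitution-class reads —
are exercised explicitly: the first two are errors with counted reasons,
the last an empty-flagged profile.

# Known limitations

- Off-target search is mismatch-only (no bulges) and unindexed; whole
  mammalian genomes are out of scope.
- The indicator search is greedy per orientation (exact for amplicons,
  not for reads with repeated indicator-like motifs).
- The merge rejection-reason boundary at 50% identity is heuristic.
- ABE window defaults are a stand-in; override per editor generation.
- No on-target activity or off-target scoring models; the designer lists
  and annotates, it does not rank.
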