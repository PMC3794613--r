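---
title: "Selecting tRNA pairs by dicodon enrichment: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting tRNA pairs by dicodon enrichment: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dicodon)
```

## The model

During elongation, the ribosome's P and A sites hold the tRNAs decoding two
adjacent codons — a *dicodon*. If both isoacceptors of a pair carry
complementary fluorophores, translation of their cognate dicodon produces a
FRET event. The signal attributable to one protein of interest (POI) versus
the rest of the translatome is estimated by an enrichment factor computed
entirely from sequence:

$$E(\text{pair}) \;=\; \frac{f_{\mathrm{POI}}(\text{pair})}{f_{\mathrm{bg}}(\text{pair})},$$

where $f$ is the frequency of the unordered isoacceptor pair among the
overlapping dicodons of the POI's CDS (numerator) or of a pooled background
transcriptome (denominator). Two strong simplifying assumptions are
inherited from the experimental rationale and kept deliberately:

* **uniform transcript levels** — every CDS in the background FASTA counts
  once, regardless of expression;
* **uniform translation levels** — every dicodon of a CDS is translated at
  the same rate, so frequencies are plain window counts.

Both could be relaxed by weighting records with expression estimates, but
that changes the question being asked; the data model permits the extension
without implementing it.

### From codons to isoacceptors

The frequency calculation needs a total map from the 61 sense codons to one
decoding isoacceptor each. No single published convention fixes this map, so
it is built from declared, overridable rules:

* Watson–Crick pairing at all three positions is always a valid reading.
* At the codon 3rd / anticodon 34 (wobble) position the defaults follow the
  classical scheme: G34 → {C, U}, U34 → {A, G}, C34 → {G}, and A34 is
  interpreted as inosine, I34 → {U, C, A}. Anticodon positions 35 and 36
  must pair Watson–Crick.
* An isoacceptor only decodes codons of its own amino acid. Without this
  constraint U34 wobble would let Ile-UAU "read" AUG (Met) — chemically
  conceivable pairing, biologically wrong decoding. Disable with
  `decoding_rules(require_amino_acid_match = FALSE)`.
* When several isoacceptors can read a codon: exact Watson–Crick beats
  wobble; remaining ties go to the higher gene count, then the
  lexicographically smaller anticodon. The rule is deterministic and favors
  the presumptive dominant decoder; every wobble-resolved codon is logged.
* Explicit per-codon overrides (TSV `codon<TAB>isoacceptor_id`) take
  absolute precedence, so a user with species-specific knowledge can pin any
  assignment.

Codons no set member can decode are reported `unassignable`; dicodons that
touch them are counted into `dropped`, never silently discarded, so
`pair total + dropped == dicodon total` is an enforced invariant.

### Pair universe and ranking

For $n$ isoacceptors the universe has $(n^2-n)/2 + n$ unordered pairs
(heterotypic plus homotypic). The packaged synthetic mammalian-like table
has 48 members, hence 1176 pairs, and covers all 61 codons under the default
rules. E-factor tables carry one row per universe pair; pairs observed
nowhere get $f_{\mathrm{POI}} = f_{\mathrm{bg}} = 0$ and $E = 0$. The
background rarity rank (1 = rarest) uses competition ranking so tied
frequencies share the minimum rank, which makes "k-th rarest of 1176"
statements reproducible.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `mode` (background) | `"pooled"` | pool all dicodon counts, normalize once; `"mean"` averages per-record frequency vectors with equal weight per transcript. Both are defensible readings of "average frequency under uniform transcript levels"; the choice is stamped into every result and export rather than silently resolved. |
| `zero_policy` | `"sentinel"` | a pair present in the POI but absent from the background gets $E = +\infty$, explicitly flagged. In a full transcriptome this is rare; on toy inputs it is constant, so the alternative `"pseudocount"` adds `alpha` (default 1) to every background pair count and renormalizes, flagging all rows `pseudocounted`. |
| `min_bg_multiple` | 2 | negative-control pairs must have $f_{\mathrm{bg}} \ge$ this multiple of the uniform frequency $1/|U|$, and $f_{\mathrm{POI}} = 0$. |
| survey thresholds | 100 / 20 / 10 | fraction of transcripts with leading $E > 100$ (strict), $\ge 20$ (non-strict), $< 10$ (strict) — the strictness pattern follows the convention of the survey statistics this mirrors. |
| survey self-inclusion | on | each surveyed transcript stays in the background pool ("relative to the entire transcriptome"); `leave_one_out = TRUE` exists for sensitivity analysis and guarantees nothing about leading $E \ge 1$. |
| `denominator` (codon usage) | `"all_codons"` | relative usage of a codon against all sense codons; `"synonymous_family"` restricts to its amino-acid family, since "relative usage of the isoleucine-coding AUA codon" is ambiguous between the two. |

## The synthetic generator

`generate_background()` draws each record i.i.d. codon-by-codon from a
configurable weight vector (stop codons are forced to zero weight), with
fixed or range-sampled lengths, fully reproducible from one seed. This
emulates exactly the regime the E-factor estimate assumes — uniform
expression, no codon autocorrelation — and deliberately **not** real mRNA:
no amino-acid composition bias, no codon-pair bias, no GC gradients, no
isoform structure. Passing recovery tests on this generator therefore
demonstrates correctness of the estimator under its own assumptions, not
robustness to real transcriptome structure.

`generate_spiked_poi()` is constructive rather than rejection-based: to hit
a target enrichment $E_{\mathrm{true}}$ it computes the needed POI pair
frequency $f = E_{\mathrm{true}} \cdot f_{\mathrm{bg}}$, converts it to an
integer occurrence count $k = \mathrm{round}(f \cdot (L-1))$ for a
length-$L$ CDS, plants exactly $k$ occurrences (homotypic targets as one run
of $k+1$ identical codons, heterotypic ones as $k$ isolated two-codon
blocks), and fills the rest by sampling background weights under rejection
so that **no accidental dicodon decodes to the target pair** — the realized
count is asserted, and the achievable enrichment after rounding is reported
as an attribute. Requests that cannot fit error with the minimum length
($k+1$ codons for homotypic targets, $3k-1$ for heterotypic ones).

Because $f_{\mathrm{POI}}$ is built from the same background estimate it is
later divided by, recovery error comes only from rounding $k$: the relative
error is bounded by $0.5/k$. Recovery checks therefore choose POI lengths
that keep $k \approx 10$ or more (4000 / 800 / 400 codons at
$E_{\mathrm{true}}$ = 10 / 50 / 100 against a 500-transcript × 300-codon
uniform background), a granularity argument made before running, not a
tuning knob. The shipped checks recover all three enrichments within a few
percent and a median error over 20 seeds near 2%.

`viral_like_fixture()` is a deterministic 10-record set mimicking a
segmented viral coding repertoire in which one rare dicodon (AUA:AUA)
occurs exactly four times — twice in the NS3-like record, once each in the
VP1- and NS1-like records — so end-to-end tests have a known answer by
construction.

## Numerical choices and degenerate inputs

* Frequencies are ratios of integer counts; normalization is checked to
  1 ± 1e-12 and oracle comparisons in the test suite are at 1e-12.
* Sorting of E-factor tables breaks ties by lower background frequency,
  then lexicographic pair id; $+\infty$ sentinels sort above all finite
  values. `leading_pair()` on an all-zero table returns the first pair under
  the same ordering, flagged `no_signal`.
* Single-codon records contribute zero dicodons (no error); a POI with
  fewer than two codons is an error. Codons containing ambiguity letters
  are masked and both dicodon windows overlapping them are excluded and
  logged.
* Strict FASTA policy rejects off-frame lengths and internal stops;
  lenient policy truncates at the first internal stop and skips emptied
  records with a warning — bulk CDS dumps commonly contain both artifacts.
* Initiator-Met and Sec rows of isoacceptor tables are excluded by default:
  only elongator tRNAs occupy adjacent P/A sites during the elongation
  cycles the FRET readout reports. The start codon's own dicodon (AUG at
  the P site during the first elongation cycle) *is* counted, as there is no
  principled reason to drop it.
* Fisher's exact test (two-sided, on the pooled 2×2 of codon vs
  rest-of-denominator) is the default usage test because it is exact at the
  small counts typical of single-CDS comparisons; a likelihood-ratio G-test
  is available as a flag. The test suite pins the Fisher p-value to an
  independent exhaustive hypergeometric tail summation.

## Known limitations

* The codon → isoacceptor map is a declared convention, not a reconstruction
  of any particular species' decoding; with gene-count-weighted wobble
  competition real decoding is more plural than a total single-decoder map.
* Uniform-expression backgrounds can misrank pairs whose background
  frequency is dominated by a few highly expressed genes.
* The "~N× average dicodon frequency" way of describing a control pair is
  sensitive to what "average" means (uniform over the pair universe vs
  observed mean); published figures of that form are not always internally
  consistent, which is why control selection here reports the explicit
  background frequency and the multiple of the uniform frequency instead.
* Tri-codon windows, ribosome dwell times, codon-pair-score statistics and
  FRET photophysics are out of scope.
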