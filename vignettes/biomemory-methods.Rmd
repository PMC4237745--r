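---
title: "Methods: simulating DNA-memory learning and associative recall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating DNA-memory learning and associative recall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomemory)
```

## The system being simulated

A DNA-based associative memory learns the sequence content of a genomic
sample without knowing its sequence. The hardware is a library of 40-nt
*memory tags*: a 5' chemical label (biotin or amine), a fixed 20-base
non-crosshybridizing (NCH) address tag, and a 20-base fully random probe
(R20, one draw from the $4^{20} \approx 1.1\times10^{12}$ design space).
Learning is four wet-lab steps, which this package simulates molecule by
molecule:

1. **A — annealing.** R20 probes pair, fully or partially, with
   complementary windows on denatured, DNase-I-digested input DNA.
2. **E — extension.** Klenow fragment trims each primer's unpaired 3' tail
   back to the duplex and then copies the template 5'-ward, producing a
   tagged single strand carrying the complement of a template prefix.
3. **D — digestion.** Exonuclease I removes single strands not engaged in a
   duplex (unused tags, unused input).
4. **Bead separation.** Streptavidin beads retain molecules whose 5' end
   carries the label: tags and everything derived from them. Input-input
   extension products carry no label and are lost here.

Recall prints learned pools as microarray spots and hybridizes fluorescently
labeled fragments of a query sample against them; similarity is read out as
background-subtracted intensity (BSI) and SNR per spot.

## Duplex thermodynamics

Every stability decision in the simulator runs through one two-state
nearest-neighbor model. For a perfect-match duplex of $N$ base pairs,

$$T_m^{1M} = \frac{\Delta H^\circ \times 1000}{\Delta S^\circ + R \ln C_T},$$

with stack-summed $\Delta H^\circ$ (kcal/mol) and $\Delta S^\circ$
(cal/mol/K) from the unified 1998 parameter table, initiation terms per
terminal base pair, and the symmetry entropy for self-complementary
sequences. Three conventions deserve comment:

* **Strand-concentration term.** We use the oligo-excess convention
  $R\ln C_T$ rather than $R\ln(C_T/4)$: in every reaction step the probe
  strand population vastly outnumbers any individual template site, which
  is also the assumption the vendor oligo calculators make. The two
  conventions differ by a uniform ~5 °C; the oligo-excess form reproduces
  the reference predictions for short random duplexes under the reaction
  conditions to within fractions of a degree.
* **Salt correction.** The 1 M Tm is corrected with the magnesium-dominated
  correction (the divalent branch of the standard 2008 treatment) because
  at the learning conditions (10 mM Na$^+$, 10 mM Mg$^{2+}$, 4 mM dNTP)
  the branch ratio $\sqrt{[\mathrm{Mg}^{2+}_{free}]}/[\mathrm{mon}^+]
  \approx 7.7$ is deep in the divalent regime. Free Mg$^{2+}$ is
  $\max(\mathrm{Mg} - \mathrm{dNTP}, 0)$ — dNTPs chelate Mg roughly
  stoichiometrically.
* **Population extremes.** Statistics over all $4^k$ k-mers are exhaustive
  for $k \le 10$. For larger $k$ the mean is estimated from seeded samples,
  while the minimum and maximum are computed *exactly* over the two-letter
  subspaces that attain them (A/T-only for the minimum, G/C-only for the
  maximum, $2^k$ sequences enumerated by bit arithmetic); the `method`
  column of `tm_population_stats()` records which route produced each
  number. Different vendors' proprietary salt models disagree by a couple
  of degrees, especially outside their calibration range (the correction
  was fitted mostly on duplexes of 10+ pairs with intermediate GC), so
  comparisons with calculator outputs are meaningful only at the ±2 °C
  level — and extreme A/T-only 20-mers sit outside that calibration range
  entirely.

The anchor-length query `min_stable_anchor_length(T, cond, stat)` returns
the smallest $k$ whose population mean (or max) Tm reaches $T$; at room
temperature under learning conditions the mean-stable anchor is 7 bases,
which is what makes short tag-tag duplexes a real by-product channel at
25 °C. Note the model has a floor: very short duplexes (2-3 bp) are never
stable at biologically relevant temperatures, so the anchor length at 0 °C
is set by where the mean Tm curve crosses 0 °C (4-5 bases), not by the
smallest representable duplex.

## Synthetic genomes and digestion

Real genomic DNA from two distant bacteria is emulated by two i.i.d. random
100-kb genomes at GC 0.50 and 0.43 drawn from disjoint seeds; at these
lengths two such genomes share essentially no 14-mers
($\mathbb{E}|A\cap B| \approx |A||B|/4^{14}$, a fraction well under 6%),
which is the property that matters for discrimination. What i.i.d. genomes
do **not** emulate: repeats, strand skew, codon structure, shared core genes
between real strains. Passing tests therefore demonstrate the protocol's
behavior on sequence-disjoint inputs, not its power against two genuinely
homologous genomes — with real assemblies the same pipeline applies, and
discrimination will degrade with k-mer sharing.

DNase I digestion nicks each strand independently and memorylessly
(per-base probability $1/\ell$, geometric inter-nick lengths with target
mean $\ell = 200$ bases); after denaturation every inter-nick interval is
one single-stranded fragment, so fragmentation is measure-preserving per
strand and the plus-strand fragments concatenate back to the genome — an
invariant the tests assert.

## The learning state machine

`run_learning()` executes A, then the remaining steps in the requested
order, with bead separation always last.

**Candidate sites.** Annealing admits *maximal* exact-complement windows of
length $\ge k_{\min} = 5$ (the shortest duplex whose strongest
representative is stable near room temperature) whose window Tm reaches the
annealing temperature; mismatched duplexes are out of scope. Searches are
seeded at the effective minimum admissible length for the temperature (no
shorter window can pass the Tm filter), so the seed-and-extend k-mer join
is exact, and on toy pools the candidate set equals a quadratic
dynamic-programming enumeration (tested).

**Channel competition.** A tag can prime on a template site or on another
tag. The two channels compete as equilibria: each tag commits to the
tag-tag channel with probability equal to its relative stability mass
(sum of Tm margins) there, and the rest enter template-site assignment —
a seeded, stability-weighted draw with exclusive occupancy (a template
interval hosts one primer). Without this competition a small simulated
library would bind template exhaustively at low temperature and the
tag-tag by-product channel would vanish, contradicting the observed
by-product band. With it, the by-product fraction falls from ~25% of
products at 25 °C to ~15% at 55-60 °C in the default workload, the trend
that motivates learning at 55 °C.

**Digestion-before-extension.** When D precedes E, Exo I destroys the
single-stranded template overhangs before the polymerase acts; the
subsequent extension step has nothing to copy, and annealed tags survive
only as intact 40-mers. This is the model reading of the observation that
digestion-first protocols yield no high-molecular-weight products, and it
is why `LP_H("ADE") = 0` exactly. A pure molecule-granularity
duplex-protection model would wrongly let bound templates extend after
digestion.

**Tag-tag by-product geometry.** For two antiparallel 40-mers pairing at
ungapped offset $c$ (0-based sum of paired indices), trim-to-duplex plus
copy-to-5'-end gives a product of length $c + 1$ regardless of where
within the overlap the duplex sits. Admissible offsets with at least a
$k_{\min}$-base stable window give the 5-80-base by-product envelope. The
enumeration allows windows anywhere on the 40-mer (the address region
included) because the envelope is a geometric bound; the NCH screen
(`nch_screen()`) separately guards that the address tag has no stable
complement in a given pool.

**Product classes.** Lengths bin as on a denaturing gel: 40 = intact tag,
41-80 = short products (the 50-80 sub-bin is the classic short-product
band), >80 = high-molecular-weight learned products. Sub-40 lengths arise
only from 3'-trimming (tag-tag by-products, or input-template events whose
trimmed primer plus short extension stays under 40); `classify_products()`
enforces this.

## The recall signal model

For each (learned product, labeled probe fragment) pair the best shared
exact-complement window of length $\ge k_{\min}^{hyb} = 7$ (the room-
temperature anchor length) with window Tm at or above the hybridization
temperature contributes a Boltzmann-like stability weight
$w = e^{\beta (T_m - T)}$ with $\beta = 0.4\,/°\mathrm{C}$, times the
fragment's label count (labels are Binomial over purines, rate 0.05,
roughly one dye per 20-25 nt). The spot's expected intensity saturates
Langmuir-style, $E = S_{\max}\, x/(x + K)$ with $S_{\max} = 65535$ (a
16-bit scanner) and half-saturation $K = 10^{16}$ chosen so the default
workload's full-strength flux ($\sim 4\times10^{15}$) sits in the
quasi-linear response — the in-silico analog of picking a PMT gain that
avoids saturating the brightest spots, and the regime in which expected
BSI is monotone in target abundance. Matched pools outrun unmatched ones
by four orders of magnitude in flux, so the conclusions are insensitive to
the exact $\beta$ or $K$; what matters is that long shared windows dominate
chance 7-8-mer matches exponentially.

Noise follows the scanner's bookkeeping: lognormal background pixels
(meanlog $\ln 100$, sdlog 0.3), measured local background = mean of 25
pixels, background SD = their sample SD, raw = expected $\times$ lognormal
measurement error (CV 0.15) + the spot's own background draw, BSI = raw −
background, SNR = BSI / background SD, detection at SNR > 3. Under this
model blank and negative-control spots exceed SNR 3 in well under 5% of
rescans (tested over 20 seeded noise replicates). PMT gain multiplies raw
and background equally and cancels from SNR.

## Problem sizes and runtime choices

The simulated workload uses two 100-kb genomes, mean fragment length 200,
a 30,000-tag library, 2,000 labeled probe fragments, 10 replicate spots,
and a 2,000-tag cap on the all-pairs tag-tag search (a seeded subsample;
by-product *fractions* are what matter, not absolute pair counts). A
30,000-tag library at 55 °C yields ~3,000 learning events on 200 kb of
single-stranded template — enough that a 10% admixture contributes
hundreds of products — while keeping a full nine-fraction titration in
minutes. The protocol-order and temperature-sweep experiments run at
25 °C with 1,000 tags, the regime where partial duplexes are permissive
and ordering effects are starkest.

## Known limitations

* No mismatched or bulged duplexes; pairing is exact-complement windows.
* Enzyme action is all-or-nothing per molecule: no processivity,
  polymerase errors, strand displacement, or partial digestion.
* Amplification during polymerization is a simple integer copy multiplier
  (default 1); thermal cycling is not simulated.
* The microarray model is spot-level (no pixels, gridding, or dye
  photophysics); absolute intensities are instrument-scale constants and
  only relative/threshold statements (BSI ordering, SNR > 3) transfer.
* i.i.d. synthetic genomes overstate the k-mer disjointness of real
  related strains, as discussed above.
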