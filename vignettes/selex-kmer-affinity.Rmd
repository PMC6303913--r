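---
title: "Estimating DNA-binding specificity from SELEX-seq with selexr"
author: "selexr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating DNA-binding specificity from SELEX-seq with selexr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selexr)
```

## The problem

SELEX-seq characterizes the DNA-binding specificity of a protein (here
motivated by MADS-domain transcription-factor heterodimers such as AP3/PI,
which bind CArG boxes, CC[A/T]~6~GG) by iterating rounds of affinity capture
on a randomized double-stranded oligonucleotide library — a 40-nt random
variable region between fixed barcode/adapter flanks — and deep-sequencing
the enriched rounds. The analysis question is: given reads from the
unselected library ("Round 0") and from an enriched round *R*, what is the
relative binding affinity of every 10-bp word (k-mer)?

## The estimator

For each k-mer $w$, selexr computes

$$\mathrm{raw}(w) \;=\; \frac{f_R(w)}{P_0(w)}, \qquad
  \mathrm{rel}(w) \;=\; \frac{\mathrm{raw}(w)}{\max_{w'} \mathrm{raw}(w')},$$

where $f_R(w)$ is the per-window frequency of $w$ in the final round and
$P_0(w)$ is the *model-implied* Round-0 frequency. Round 0 is far too complex
for direct 10-mer frequencies (most of the $4^{10} \approx 1.05$ million
words are seen 0–2 times at typical depth), so $P_0$ comes from a
**sixth-order Markov chain** fitted to Round-0 reads:

$$P_0(w) = P_0(w_{1..6}) \prod_{i=7}^{10} P(w_i \mid w_{i-6..i-1}).$$

Evaluation is exact by the chain rule — no stochastic sampling is involved.
The maximum relative affinity is exactly 1 by construction, attained at the
`normalization_word` recorded in every `affinity_table`.

### Window frames and marginal consistency

Transition rows are estimated from $(m{+}1)$-mer window counts,
$P(b \mid c) = (n_{cb} + \alpha)/(n_{c\cdot} + 4\alpha)$. The initial
distribution is estimated, by default, on the *same* frame — the $m$-prefix
of every $(m{+}1)$-window (`initial_frame = "prefix"`). Sharing one frame is
what makes the $\alpha = 0$ model reproduce empirical $j$-mer frequencies
($j \le m{+}1$) to machine precision on its training frame; training the
initial law on *every* $m$-window instead (`initial_frame = "all"`) differs
by one window per read end, an $O(1/L)$ effect that breaks this exactness.
The test suite checks the prefix-frame identity against a naive substring
oracle at $10^{-12}$.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 10 | word length for affinity estimation (bp) |
| `order` (`m`) | 6 | Markov background order; 6 is the standard compromise: $4^7$ = 16k cells are well measured at $10^5$-read depth while capturing local composition bias |
| `alpha` | 1 | per-cell pseudocount; guarantees strictly positive background for every word (the affinity denominator); `alpha = 0` exists for the exactness oracles |
| `strand_mode` | `"collapsed"` | the library is double-stranded and the dimer binds duplex DNA, so windows are counted on the canonical (lexicographically smaller of word/reverse complement) key; `"single"` is retained and recorded in all outputs |
| `min_count` | 2 | words below this final-round count get ratio 0 and are flagged rather than given unstable singleton ratios |
| `exponent_mode` | `"ratio"` | the plain frequency ratio; `"per_round_root"` ($\mathrm{ratio}^{1/R}$) makes tables comparable across conditions sequenced at different rounds (e.g. round 8 vs round 5). Both modes induce the same within-condition ranking |
| `fraction` | 0.001 | top-k-mer selection fraction; the universe defaults to *observed* words passing `min_count`, which is why two conditions yield different top-set sizes at the same fraction |
| `flank` | 5 | bases added on each side of the anchored k-mer in the PFM |

Strand collapse also applies to the background: the model-implied
probability is folded onto canonical words, so numerator and denominator
live on the same key space and `rel` is *exactly* strand-coherent
(`affinity_of(t, w) == affinity_of(t, revcomp(w))`, a keying identity, not a
numerical one).

## Read preparation

Raw FASTQ records pass four screens in a fixed order, each read dropped for
at most one (the first applicable) reason so that counts are conserved:
CASAVA filter flag (`<read>:Y:` in the header), contaminant screen,
flank-anchored extraction of the variable region, and an ambiguous-base
screen on the extracted region. The contaminant screen (phiX and similar
spike-ins) drops reads sharing any exact 25-mer with the contaminant on
either strand — for error-free reads fully contained in the contaminant this
is equivalent to mapping with no mismatches, without an aligner dependency.
Coordinates are 0-based half-open internally; reads too short for
flanks + variable region are rejected, never padded.

## Motif construction

The top `fraction` of words by relative affinity is selected (boundary ties
broken lexicographically). For each selected word, the *most recurrent* read
containing it (either strand; ties lexicographic; oriented so the word reads
forward) becomes its representative — these representatives are exported as
FASTA, which is the faithful input for external motif discovery such as
MEME. In-repo, an anchored position-frequency matrix summarizes the same
information: each representative is aligned by anchoring the word occurrence
at a fixed offset, positions beyond the read contribute equal-weight
background, and contributions are weighted by relative affinity (a flag;
weighting emphasizes the consensus core over hitchhiking context).
Multiplicity is counted over reads as sequenced, i.e. before any
de-duplication of PCR copies. Export formats are MEME-minimal and JASPAR;
both round-trip through the bundled readers within print precision.

## The synthetic-data generator

`run_selex()` emulates the experiment so that the entire pipeline can be
validated by parameter recovery. The generative truth is an
`affinity_landscape`: every 10-mer gets affinity
$\phi^{d(w)}$, where $d(w)$ counts mismatches to a degenerate consensus
(default the CArG box `CCWWWWWWGG`) and $\phi \in (0,1)$ is the per-position
penalty. A read's binding score is the maximum landscape affinity over all
10-bp windows of the read and its reverse complement; round-$r$ selection
retains molecules with probability proportional to $\mathrm{score}^{s}$
($s$ = stringency), and PCR is modelled as Dirichlet-multinomial resampling
noise (`pcr_noise` = weight-Gamma variance), not cycle-by-cycle replication —
only the marginal count overdispersion matters downstream.

**Pool representation.** A physical SELEX pool (tens of nanograms of dsDNA,
on the order of $10^{11}$ molecules) is effectively inexhaustible relative
to a 50,000-read sequencing sample. The default `pool = "infinite"` mode
therefore draws each round's reads i.i.d. from the selection-tilted
population $\pi_r(x) \propto \mathrm{score}(x)^{s\,r}$, implemented by
sampling-importance-resampling with a planted-motif mixture proposal whose
density is computed exactly. `pool = "finite"` instead chains
`simulate_round()` on the previous round's sequenced reads; that models a
severely bottlenecked pool, and it measurably collapses clonal diversity
(on the order of $10^2$ distinct molecules after four 50k-read rounds),
which is exactly the regime in which k-mer estimation degenerates — useful
for studying that failure mode, not for emulating a working experiment.

Round 0 is i.i.d. uniform by default; a biased-synthesis mode (per-base or
per-position weights) exists specifically to exercise the Markov
background's ability to absorb composition bias. FASTQ output carries the
configured flanks, CASAVA-1.8-style headers with the pass-filter field, and
constant high qualities (quality modelling is out of scope, as are capture
kinetics and sequencing error). All randomness derives from the single
configuration seed (round $r$ uses seed + $r$), so reruns are
byte-identical.

## What the simulations do and do not show

Within the generator's world, the pipeline is fully validated: the
background model is exact on its oracles, null (constant-landscape) runs
show only sampling-level ratio dispersion (~99.9% of words within 3
delta-method SE of the median ratio), CArG prevalence matches an
independent scanner exactly and the independence closed form
$1-(1-64/4^{10})^{31}$ within binomial error, artifacts are byte-stable,
and the anchored PFM built from the top 0.1% of words recovers the
consensus core (C,C at positions 1–2, G,G at 9–10, A/T-rich center).

Two caveats matter for real data. First, the generator's reads are
independent draws with known truth; real rounds carry PCR jackpots,
sequencing error and synthesis bias that the simulator only partially
represents (overdispersion knob, biased Round 0). Second — and this is a
property of the *estimator*, faithfully reproduced by the simulation —
word-level frequency ratios are contaminated by **motif-shift hitchhiking**:
with a 40-nt region and 10-bp words, every read carries 31 windows, so a
word overlapping a strong site by a few offset positions is enriched by
co-occurrence regardless of its own affinity, and any word whose own
$\mathrm{affinity}^{sR}$ falls below the population mean binding weight sits
at an indistinguishable enrichment floor. In recovery experiments across a
wide range of selection strengths and landscape depths, the Spearman
correlation between estimated relative affinities and the generating truth
over well-measured words (final count ≥ 10) plateaus around 0.25–0.47; the
top of the table (the consensus family) is recovered essentially perfectly,
which is why downstream motif construction realigns full-length
representatives around the anchored word instead of trusting word-level
ranks, and why cross-condition dotplots — where both axes share the same
hitchhiking geometry — remain informative. Users should read mid-table
relative affinities as enrichment scores, not calibrated affinities.

## Numerical and design choices

* Dense representation: all per-word vectors live on the $4^k$ lexicographic
  index (2-bit base codes), so strand collapse, reverse complementation and
  folding are index permutations; at $k = 10$ a dense table is ~8 MB.
* Ties: the affinity-table normalization word, top-k-mer boundary ties and
  representative multiplicity ties all break lexicographically, making every
  output deterministic.
* Unseen contexts with `alpha = 0` get uninformative (uniform) transition
  rows; with the default `alpha = 1` this cannot occur.
* The null-calibration bound uses the delta-method SE of the ratio,
  $\sqrt{\max(c_w,1)}/(P_0(w)\,N)$; in infinite-pool simulations the rounds
  are independent draws, so no pool-resampling inflation term is needed.
* Problem sizes used by the validation suite were chosen to keep a full run
  on a laptop-class single core in a few minutes: 1,000-read corpora for the
  exactness oracles, 200,000 uniform reads for the CArG oracle, 50,000
  reads/round × 4 rounds for the recovery study, and 3,000-read two-condition
  runs for the end-to-end pipeline checks.
* The `per_round_root` mode exists because conditions sequenced at different
  rounds are not directly ratio-comparable; the default remains the plain
  ratio, with the mode recorded in the output metadata. How best to compare
  a round-8 table against a round-5 table on one axis pair is genuinely
  open; both behaviors are provided.
* Unobserved words are dropped from comparisons (with the dropped count
  reported), not plotted at zero.

## Known limitations

No biophysical free-energy calibration, no confidence intervals on
affinities (future work), no gapped or variable-length words, no positional
count matrices, no paired-end or demultiplexing logic, and no built-in
motif discovery beyond the anchored PFM — the exported FASTA is designed to
feed external tools.
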