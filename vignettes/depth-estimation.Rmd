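---
title: "Estimating sequencing depth and error rate from marker k-mers"
author: "kmerdepth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sequencing depth and error rate from marker k-mers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(2024)
library(kmerdepth)
```

## The problem

Depth of coverage is the average number of times each nucleotide of the
source DNA appears in the sequencing output. Estimating it precisely is
harder than it sounds: simply counting nucleotides in the FASTQ files fails
when the sample is contaminated with foreign DNA (in ancient-DNA work the
target individual can be a few percent of the sample), and counting mapped
reads inherits every weakness of mapping — reference bias, genome-length
differences between individuals, contaminant reads that happen to map.

`kmerdepth` estimates depth and the per-nucleotide substitution error rate
without any mapping, from two purpose-built k-mer lists:

* **tag k-mers** — k-mers (default k = 25) that occur exactly once in the
  target assembly (and once in every additional assembly supplied), have no
  other genomic k-mer within Hamming distance 1, and lie at least 200 bp
  apart. Their mean observed count measures depth at the k-mer-window level.
* **error k-mers** — for each tag, up to four randomly drawn single-mismatch
  variants that are absent from the genome and not reachable by one
  substitution from any genomic k-mer except their parent. They are never
  sequenced intact; they are observed only when a sequencing error converts
  the parent into exactly that variant, so their mean count measures the
  error-capture rate.

Foreign DNA almost never contains a specific 25-mer from either list
(a random 25-mer matches a 335,000-entry list with probability
$\sim 3\times10^{-10}$ per window), which is what makes the estimates robust
to heavy contamination.

## The estimators

All counting is canonical: a k-mer and its reverse complement are the same
object, because reads come from both strands. Let $D_{tag}$ and $D_{err}$ be
the mean per-k-mer counts over the (cutoff-filtered) tag and error lists,
$N_{nucl}$ the total number of bases in the sample (N included) and
$N_{kmer}$ the total number of ACGT-only k-windows.

With unbiased errors, a window covering a tag survives intact with
probability $(1-P_e)^k$ and converts to one *specific* single-mismatch
variant with probability $(P_e/3)(1-P_e)^{k-1}$, so

$$\frac{D_{err}}{D_{tag}} = \frac{P_e/3}{1-P_e}
  \quad\Longleftrightarrow\quad
  P_e = \frac{D_{err}}{D_{err} + D_{tag}/3},$$

and depth follows by converting window counts back to nucleotides and
undoing the error thinning:

$$D = \frac{D_{tag}\, N_{nucl}}{(1-P_e)^k\, N_{kmer}}.$$

Two properties are worth spelling out because the test suite asserts them:

* **Exact inversion.** Plugging the exact expected counts
  $D_{tag}=\lambda(1-p)^k$, $D_{err}=\lambda(p/3)(1-p)^{k-1}$ into the two
  formulas returns $p$ and the true window depth *identically* (an algebraic
  identity, checked to 1e-12), so the estimator is unbiased up to sampling
  noise and the cutoff.
* **What $P_e$ converges to.** $P_e$ counts false nucleotides, not N calls.
  Under the simulator's error model (per base: N with probability $p_N$,
  substitution with probability $p_{sub}$, mutually exclusive) the estimate
  converges to $p_{sub}/(1-p_N)$ — the substitution rate among non-N bases.
  Conveniently $(1-P_e)(1-p_N) = 1-p_N-p_{sub}$, which is exactly why the
  depth estimate stays unbiased under both error channels: N-loss is absorbed
  by the $N_{kmer}$ deficit, substitution loss by $(1-P_e)^k$.

### The contamination cutoff

If a contaminant genome does share (or nearly share) a database k-mer, that
k-mer's count reflects the contaminant's abundance, not the target's. Before
averaging, each list gets a count cutoff chosen so that, under a Poisson
model with rate $\hat\lambda$, the probability of seeing even one k-mer of
the list at or above the cutoff is below $\alpha$ (union bound; default
$\alpha$ = 0.01): the smallest integer $c \ge 1$ with
$n \cdot P(X \ge c) < \alpha$. K-mers whose count exceeds $c$ are removed
from the counts *and* from the list denominator. $\hat\lambda$ is a trimmed
mean of the observed counts (top 1% dropped) so that the outliers being
hunted cannot inflate the cutoff that is supposed to catch them; the cutoff
is computed separately for tags and error k-mers since their rates differ by
a factor of roughly $P_e/3$. All-zero (or fully trimmed) counts degenerate to
$\hat\lambda=0$ and $c=1$, with a logged note. The rate is fitted in a single
pass; on clean samples the expected removal fraction stays below $\alpha$
(asserted empirically at $\le 2\alpha$), and the removal of a truly shared
k-mer is demonstrated in the test suite with a 300-fold-amplified shared tag.

## List building

`buildKmerDatabase()` applies three filters in order:

1. **Uniqueness/universality** — keep k-mers with count exactly 1 in the
   primary assembly and in every additional assembly supplied. The primary
   assembly provides coordinates and the isolation reference; additional
   assemblies only tighten the filter.
2. **Hamming isolation** — drop any candidate with another genomic k-mer
   within distance 1, tested by looking up all 3k canonical single-mismatch
   neighbors in the genome index (exact for threshold 1, and enormously
   cheaper than all-pairs comparison, against which it is verified on toy
   genomes). A neighbor that collapses onto the candidate's own canonical
   form (a near-palindrome) is the same k-mer family and is ignored.
3. **Spacing** — partition each record into 100 bp windows, let only every
   third window contribute, and keep the leftmost candidate per eligible
   window. Any two tags are then ≥ 200 bp apart, so a 100 bp read can hit at
   most one tag, which caps the per-read contribution to the tag total and
   reduces stochastic noise at low depth. "Leftmost" is a deterministic,
   order-independent tie-break; windows are indexed 0, 3, 6, … per record.

Error k-mers are then drawn per tag: mismatch position and substituted base
uniformly without replacement from the 3k possibilities, keeping a variant
only if it is absent from the primary genome, no non-parent genomic k-mer
lies within distance 1, and it collides with no tag or previously accepted
variant. Isolation of error k-mers is tested against the primary assembly
only. At k = 25 on non-repetitive sequence the acceptance rate is
essentially 100%, so the error list is almost exactly four times the tag
list. The draw is seedable and byte-reproducible.

The internal pipeline fuses steps 2 and 3 (isolation is tested left-to-right
only for candidates inside eligible windows, stopping at the first survivor
per window). This is provably the same result as running the exported
filters in sequence — the tests assert equality against both the composed
ops and an independent O(n²) brute-force pipeline — while testing ~30×
fewer candidates on genome-scale input.

## The read simulator

`simulateReads()` reproduces a deliberately simple shotgun model:
`round(depth × L / readLength)` reads (round-half-to-even) of fixed length
(default 100 bp), start positions uniform over the record, strand chosen
uniformly, and per base the mutually exclusive events N (probability `pN`,
default 0.01) or a uniform substitution to one of the other three bases
(probability `pSub`, default 0.01). `composeSample()` adds contaminant reads
simulated with the same model so that the target makes up a chosen fraction
of the sample's nucleotides, split equally among the contaminant genomes.
`sanitizeReference()` replaces assembly Ns with random bases first, so that
coverage is not biased around gaps.

What the simulator does *not* emulate — and therefore what passing tests do
not certify about real data: indels, quality-correlated or
position-dependent error profiles, GC-biased coverage, fragment-length and
paired-end structure, PCR duplicates, and ancient-DNA damage patterns. It
also draws genomes as i.i.d. uniform sequence, which understates how
repetitive real genomes are; the list-building filters are exercised against
engineered duplications and near-duplications in the tests instead. Real
contaminants share more sequence with a real target than random genomes do,
so contamination robustness on real data leans more heavily on the cutoff
than these simulations require.

## Validation study sizes

The package validates itself on synthetic data at desk scale: a 20 Mb target
genome (≈ 66,700 tags and 266,700 error k-mers) rather than a 3 Gb one, with
k-mer counts pooled across independent replicate simulations to buy back the
precision that the smaller list costs — the stochastic error of the pooled
estimate scales as $1/\sqrt{\Sigma\,\text{tag counts}}$. Pooled counts
measure the summed depth of the replicates, so `pooledDepthEstimate()`
rescales the pooled estimate back to per-replicate depth. The shipped
experiments use 400 pooled replicates at depth 0.01 and 10× contamination,
4000 at depth 0.001 (with and without contamination), and 10 at depth 0.1
with contamination; with these sizes the predicted standard error of each
pooled depth estimate is ≈ 0.7%, comfortably inside the 2% bands being
checked. Error-rate noise enters depth through $(1-P_e)^{-k}$, which is why
the error-k-mer hit total (not the tag total) dominates the replicate
budget at low depth.

```{r quick-example, eval = FALSE}
set.seed(1)
genome <- generateGenome(2e6)
db <- buildKmerDatabase(genome, k = 25)
reads <- simulateReads(genome, depth = 0.1)
est <- runEstimation(countReads(reads, db), db)
est
```

## Numerical and design choices

* **Canonical form**: lexicographic minimum of word and reverse complement
  under A<C<G<T, on 2-bit packed words (A=0,C=1,G=2,T=3, leftmost base most
  significant); k is limited to 32 (one 64-bit word). Counting, list
  membership and neighbor tests are all canonical; without this, roughly
  half of all true tag hits (reverse-strand reads) would be missed.
* **Non-ACGT handling**: lowercase acgt is case-folded and accepted
  (soft-masked FASTA is common); every other character breaks the scanning
  window but still counts in $N_{nucl}$.
* **Positions are 0-based** on the forward strand of the source record (the
  1 Mb annotation window is `floor(position / 1e6)`); stated here because it
  differs from the usual 1-based R convention.
* **"Exceeds the cutoff"** means strictly greater; ties at the cutoff are
  retained.
* **Degenerate inputs**: zero reads, an all-removed tag list, or
  $N_{kmer}=0$ raise undefined-estimate errors rather than returning
  numbers; $D_{tag}=D_{err}=0$ likewise (no usable signal).
* **Isolation thresholds**: both the tag filter and the error-variant filter
  reject on *any* non-parent genomic k-mer within Hamming distance 1; both
  are exposed as the neighbor-membership primitive rather than a tunable
  distance, since distance-1 rejection is what single-substitution capture
  requires.
* **Error-variant accounting**: a tag may yield fewer than four variants
  (recorded in the database provenance); denominators always use actual
  list sizes.
* **Single seed**: every stochastic step (genome generation, read
  simulation, error-variant draw, shuffling) consumes R's RNG stream, so one
  `set.seed()` reproduces an entire experiment byte-for-byte; the
  command-line driver and acceptance script fan a single `--seed` out to
  per-experiment streams.

## Limitations

Sub-chromosomal (per-record or per-1 Mb-window) depth estimation is out of
scope: annotations are stored with each tag, but regional estimates would be
far noisier (precision is proportional to the regional tag count) and are
not exposed. Contamination by DNA of the *same* species cannot be filtered —
another individual's reads carry the same tag k-mers. GC-bias correction,
paired-end awareness and quality filtering are likewise out of scope; the
counter treats mates as independent reads and ignores quality strings
entirely.
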