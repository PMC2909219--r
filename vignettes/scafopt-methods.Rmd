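---
title: "Scaffolding contigs by statistical optimization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffolding contigs by statistical optimization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scafopt)
```

## The problem

A short-read assembler produces contigs: gapless sequences typically much
shorter than the genome. Mate-pair and paired-end libraries provide pairs of
reads separated by a roughly known distance (the insert size), and each pair
whose two reads land in different contigs constrains the relative orientation
and position of those contigs. Real libraries make this hard in two ways: the
separation of genuine pairs is broad (a standard deviation around 20% of the
mean is typical), and a sizeable fraction of pairs is spurious — a broad
background of separations spread over the whole genome. scafopt treats
scaffolding as a sequence of statistical optimization problems over the
*contig connectivity graph* (vertices = contigs, edges = bundles of mate
pairs), alternating between solving for a globally most-consistent
configuration and removing the constraints or contigs that the solution
itself exposes as inconsistent.

## Geometry and conventions

Placements are 0-based and half-open: a read at offset $p$ on a contig of
length $M$ occupies $[p, p + \rho)$, with $\tau = +1$ when the read itself
(not its reverse complement) was used in the contig. Scaffold coordinates
$x_i$ refer to contig start points; orientation $S_i = +1$ means the stored
sequence reads left to right, and a contig with $S_i = -1$ contributes its
reverse complement over $[x_i, x_i + M_i)$. A read's scaffold-forward
leftmost coordinate is $x_i + p$ for $S_i = +1$ and $x_i + M - p - \rho$ for
$S_i = -1$; its scaffold strand is $\tau S_i$.

For both chemistries the pair geometry is the single rule
$\sigma_R\,(g_F - g_R) = \mathrm{Ins}$, where $g$ are leftmost coordinates
and $\sigma_R$ is the strand of the R read. SOLiD mate pairs place both
reads on the same strand (F3 right of R3 along that strand), so the expected
sign of $S_i S_j$ is $\tau_R \tau_F$; Illumina paired ends face each other
from opposite strands, flipping the parity to $-\tau_R \tau_F$. Solving the
rule for $x_j - x_i$ gives each pair's suggested separation
$l^r_{ij}$. Because the printed form of this algebra is easy to get wrong,
the implementation is validated by a round-trip oracle: on zero-noise
simulations every constraint must reproduce the true start-to-start offset
exactly, for both chemistries and all four strand combinations.

## Preprocessing

**Insert size.** Same-contig pairs measure the insert directly. Pairs whose
separation deviates from the suggested insert by more than the suggested
insert itself (five standard deviations under the 20% rule) are removed as
background; the mean and standard deviation of the remainder become the
empirical insert $\mathrm{Ins}$ and spread $\sigma$ used everywhere
downstream. With contigs comparable in length to the insert the estimate is
biased slightly low (only pairs that fit inside a contig are observable);
the positioning stage absorbs this through its threshold floor (below).

**Self-consistency.** A contig is discarded when too many of its same-contig
pairs contradict the library geometry in orientation or deviate from the
empirical insert by more than one empirical standard deviation. Under 20%
noise roughly a third of *genuine* pairs exceed one standard deviation, so an
absolute count threshold would condemn every well-covered contig; the
threshold therefore accepts either an absolute count (value $\ge 1$) or a
fraction of the contig's same-contig pairs (value $< 1$, default 0.5). The
check is applied only to contigs at least 1.5 inserts long — shorter contigs
can only host the truncated left tail of the separation distribution and
would always look inconsistent.

**Chimera splitting.** For each interior position of a contig longer than
twice the insert, the spanning count is the number of pairs with one read
entirely left and one entirely right. A chimeric concatenation of two
distant regions has (near) zero spanning pairs at the junction; the contig is
cut at the minimum of each maximal region with count below `min_span`
(default 3), restricted to positions at least one insert from the ends where
a genuine contig is at full spanning strength. Cut position ties go left.

**Coverage filter.** Collapsed repeats show up as contigs of unusually high
read coverage; contigs above 2.5 times the median contig coverage are set
aside as single contigs, and reads inside 100-base windows above 3 times the
median are excluded from pairing. These defaults are deliberately
permissive at the 30–100x coverages the simulator produces.

## Orientation: Ising ground state

With parities $J_{ij}$ (signed link counts after majority filtering: an edge
keeps its dominant-parity pairs when they are at least `majority_fraction`
(default 0.7) of the total, and is ignored entirely otherwise or when fewer
than $W$ pairs agree), orientations minimize
$E[S] = -\sum_{ij} J_{ij} S_i S_j$ — a maximum-weight-cut problem, NP-hard in
general but benign on the nearly linear graphs real scaffolds produce.

* **Decomposition.** Articulation vertices with more than two neighbors are
  split, each child component receiving a copy; no edge crosses a split, so
  energies add and merging the optimal pieces (using the global flip freedom
  $E[S] = E[-S]$ to make the copies agree) recovers the global optimum.
* **Exact layered dynamic program.** Breadth-first layers $Z_1, Z_2, \dots$
  from a minimum-degree start vertex have the property that edges connect
  only within a layer or between adjacent layers; when every layer holds at
  most `layer_cap` (default 6) vertices, a forward sweep over the
  $2^{|Z_k|}$ layer states with backpointers yields the exact minimum.
* **Simulated annealing** handles the rest: Metropolis single flips from the
  all-+1 start, exponential cooling ($T \leftarrow 0.995\,T$ per sweep from
  $T_0 = 2\max|J_{ij}|$), a plateau stop that only engages once the system
  is cold (stopping at a hot plateau mistakes wandering for convergence),
  and a final zero-temperature descent. The tests assert the annealer
  matches the exact optimum on every instance small enough to enumerate.
* **Degeneracy.** Each component's two-fold flip degeneracy is fixed by
  giving the alphabetically first contig orientation +1.

Edges whose sign the optimal assignment violates are excluded from
positioning.

## Position: the spring network

Modeling each pair's suggested separation as a Gaussian of spread $\sigma$
around $l^r_{ij}$, the joint likelihood of positions factorizes over edges,
and its negative log is the energy of a spring network: a spring of constant
$|J_{ij}|$ and relaxed length $\bar d_{ij}$ (the mean suggested separation
over the edge's retained pairs) between the start points of contigs $i$ and
$j$. With one contig anchored at zero, the equilibrium solves a weighted
Laplacian system — symmetric positive definite on a connected component, so
the solution is unique and the force balance residual is at solver precision
($<10^{-8}$ relative, asserted in the tests).

Before averaging, each edge's pairs undergo the same outlier rule as the
insert estimate: dominant-parity pairs deviating from the edge median by more
than the empirical insert are dropped (and do not count toward $|J_{ij}|$).
This matters: background pairs that survive the parity majority would
otherwise pull $\bar d_{ij}$ arbitrarily far off.

**Residual pruning.** The residual $\Delta_{ij} = |x_j - x_i - \bar d_{ij}|$
of a relaxed solution flags inconsistent constraints. The threshold is
$\max(k\,\sigma/\sqrt{|J_{ij}|},\ 0.5\,\sigma)$ with $k = 5$: the first term
is the standard error of a mean of $|J_{ij}|$ separations, and the floor
accounts for the selection bias of bridging pairs — pairs able to reach
across a gap are a separation-biased sample, so even a heavily linked edge
carries a bias of a fraction of $\sigma$ that no amount of links removes.
What happens to a stretched spring depends on whose support it carries:

* springs holding at most half of **both** endpoints' total link weight are
  background constraint bundles and are dropped as edges (all at once);
* once no such spring remains, the worst stretched spring that dominates the
  support of both its endpoints indicts the contigs themselves
  (mis-assembly, collapsed repeat) and both are removed;
* a worst spring that dominates neither endpoint is dropped singly.

After any removal the pipeline returns to orientation assignment; each
iteration removes at least one edge or contig, so the loop terminates.
Removing both endpoint contigs of every stretched spring — the natural
first design — destroys most of the assembly once the background is dense:
at 10% background on an 80-contig genome the expected number of spurious
$\ge W$-link edges is in the dozens, each sacrificing two good contigs.
Hence the support-based distinction, which removes contigs in the case that
actually indicts them (a genuinely misplaced or mis-assembled contig, whose
own links are the stretched ones) while treating background bundles as what
they are: bad constraints.

## Segmentation: density profile and Potts labels

A spring solution can be fully relaxed and still wrong: two internally
consistent scaffolds joined by a single spurious (or chimera-induced) bridge
form a tree constraint that is always satisfiable, stacking two chains on
top of each other. The *density profile* — the windowed count of contigs
covering each scaffold position (1000-base windows) — exposes this as
plateaus near integers 2, 3, … The number of labels needed is
$q = 1 + \sum_{\text{runs}} (\mathrm{round}(\text{peak}) - 1)$ over maximal
runs of at least two windows at density $\ge 1.5$ (halfway between the
integer plateaus of one and two stacked scaffolds).

Labels $\sigma_i \in \{1..q\}$ then minimize the q-state Potts energy
$E[\sigma] = \sum_{i<j} (O_{ij} - D_{ij})\,\delta_{\sigma_i \sigma_j}$, where
$D_{ij} = 1$ for mate-pair neighbors (attract) and $O_{ij}$ is the pairwise
positional overlap normalized by the mean contig length (repel). The same
annealing schedule as for orientations is used, from a uniform random start.
The attraction and repulsion terms carry equal weight by default
(configurable; on the fixtures tested the optimum is insensitive to the
ratio, since the two terms rarely compete on the same pair). Junctures
cannot satisfy both terms and end up at label boundaries in every run — an
observation the tests assert over repeated seeds.

Suspected junctures (contigs with a differently labeled neighbor) are then
considered for removal: all subsets when at most 12 candidates remain
(4096 subsets), otherwise all subsets of size ≤ 2 plus candidates restricted
to the densest region, and finally a random sample of 2000 subsets. Each
subset is scored by
(number of surviving components spanning less than two inserts) +
5 × (number of windows still at density ≥ 1.5), ties preferring smaller then
lexicographically earlier subsets; the size-≤-2 pass exists because the
single-juncture solution is the common case and a random sample of a large
candidate set rarely contains it. Components still overloaded are segmented
recursively; removed junctures and single-contig components are reported as
single contigs. Scaffolds are components with at least two contigs.

## Finishing

Adjacent contigs in position order are either joined — when the positional
gap is negative or below 10 bases and the best suffix-prefix alignment over
a window of $\max(2|g|, 30)$ bases reaches 90% identity (banded edit
distance; disagreeing overlap columns take the left or higher-coverage
contig's base) — or separated by a run of `N`s: the gap rounded to the
nearest multiple of 50 (ties up, minimum 50, since a zero-length spacer
would silently merge dissimilar sequences). A small positional overlap with
dissimilar ends gets exactly 50 `N`s.

## SOLiD color space

SOLiD reads dinucleotides through four colors — the standard code
0 = {AA,CC,GG,TT}, 1 = {AC,CA,GT,TG}, 2 = {AG,GA,CT,TC},
3 = {AT,TA,CG,GC}. The first
base plus a color determines the next base, so naive chain translation turns
one color error into a corrupted tail — about two of three downstream bases
wrong for a random flip. The robust translator instead keeps contigs in
color space and collects, for every read incorporated into the contig, the
translation of only its first color call: a *base suggestion* $f_{i,b}$ at
the read's start position, which cannot propagate.

The true sequence is the hidden state of a chain model: each color position
contributes $1 - r_c$ if the implied dinucleotide color matches the call and
$r_c/3$ otherwise; each suggestion contributes $1 - r_s$ or $r_s/3$ at
multiplicity $f_{i,b}$ ($r_c$ and $r_s$ are used directly as error
probabilities, errors uniform over the three wrong symbols — the simplest
model matching "the probability that a call is wrong"). A forward pass over
the four states
per position with backpointers and a backtrace from the best final base
maximizes the product exactly; arithmetic is in log space, and ties prefer
the alphabetically earlier base at every state, making the fully degenerate
no-suggestion case deterministic. Defaults $r_s = e_s$ (the platform error
rate) and $r_c = \min(0.5, e_s/d)$ at consensus depth $d$; the translation
is insensitive to doubling both rates, and the tests verify dynamic program
against exhaustive enumeration at every length up to 8 across an error-rate
grid.

One boundary case is worth knowing: a single color error is guaranteed
corrected only when a suggestion covers the first affected base. Without it,
declaring the *next* color erroneous instead explains the data with exactly
the same number of flags, and the two explanations tie; with the high
suggestion densities of real short-read data the situation is rare.

## The simulator

`simulate_genome` / `fragment_to_contigs` / `simulate_mate_pairs` generate
i.i.d.-base genomes (optionally with planted exact repeats), tile them into
contigs separated by gaps drawn as multiples of 50 between 50 and 300 bases
(matching the finisher's resolution so zero-noise runs round-trip exactly),
optionally fuse non-adjacent contigs into chimeras, and draw pairs with
Gaussian separations (negative draws redrawn) under the exact strand
geometry above. Background pairs receive a uniform random second coordinate
*and a random strand* — spurious molecules carry no orientation information,
and a background that always votes the correct parity would make the
majority filter and the Ising step look artificially good. Insert size is
defined as the separation between the two reads' leftmost placement
coordinates, the same definition used by the estimator. Reads falling in
gaps or straddling contig ends are discarded.

The simulator does not model base-call errors in the reads, indels,
quality-score structure, or a real assembler's contig errors; passing tests
show the scaffolding mathematics is right under the stated noise model, not
that any particular assembler's output will be as clean.

The study conditions used by the acceptance checks are a 200 kb genome in 80
contigs, a SOLiD-type library with insert 1350 and 20% spread, 30x pair
coverage and 10% background, ten independent seeds — small enough to run in
minutes yet dense enough that spurious multi-link edges genuinely occur (2–3
background pairs per contig pair on average). Bacterial-scale parameters
(4–6 Mb) change the per-contig-pair background density, not the mathematics.

## Numerical and degenerate-input choices

Log-space throughout the translator; weighted-Laplacian solve with the
anchor row eliminated; `which.max`/`which.min` first-hit tie-breaking
everywhere a tie is possible (DP states, backtrace starts, cut positions,
subset scores); empty inputs return empty-but-valid structures; a library
whose same-contig pairs are all outliers falls back to the suggested insert
with a warning; all randomness flows from a single seed in the
configuration, and a fixed seed gives byte-identical outputs.

## Known limitations

Repeat structure is removed, not resolved; one library's geometry drives
preprocessing when several are supplied (constraints are pooled but not
re-weighted across libraries); the evaluator replaces alignment to a
reference with the simulator's exact ground truth, so it cannot be applied
to real data as-is; SAM/BAM ingestion and gap filling are out of scope.
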