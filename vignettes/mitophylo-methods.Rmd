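---
title: "Mitogenome phylogeography with mitophylo: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitogenome phylogeography with mitophylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mitophylo implements a complete analysis path for intraspecific
phylogeography from mitochondrial protein-coding supermatrices: curation,
three classical tree-inference methods with bootstrap, strict-clock
dating, and taxonomic auditing.  This vignette explains the science behind
each stage, the parameters that matter, and the choices made where the
design was genuinely open.  It states no empirical result beyond what the
package's tests and `scripts/acceptance.R` themselves compute.

## The analysis problem

Complete mitogenomes of honey-bee subspecies differ at only a fraction of
a percent of sites: a pair of lineages separated for 500 Kyr at the
conventional insect mtDNA rate accumulates roughly one substitution per
kilobase per lineage.  At that depth, three things dominate the practical
analysis:

1. every analyzed column counts, so curation (which genes, which strand
   orientation, which columns masked) must be explicit and reproducible;
2. several nodes of the true history may carry *zero* substitutions, so
   tree searches must report ties rather than pretend resolution;
3. public-database taxon labels are themselves data of uneven quality, and
   the tree is the instrument that exposes bad labels.

## Supermatrix construction

The 13 protein-coding genes are extracted in their 5'→3' coding (sense)
orientation; ND5, ND4, ND4L and ND1 are encoded on the light strand and
are reverse-complemented on extraction.  Genes are concatenated in the
canonical genomic order.  Coordinates are 1-based inclusive throughout,
matching the GenBank convention, so no boundary conversion exists
anywhere.

Alignment is positional against a designated reference genome.  Manual
"by eye" adjustment is replaced by one deterministic rule: a sequence
differing from the reference gene length by exactly one triplet is aligned
by the split point that maximizes flanking identity; an insertion expands
the alignment by three gap-filled columns which are immediately masked
(an autapomorphic triplet carries no phylogenetic signal and would only
distort codon bookkeeping), while a deletion becomes a three-base gap.
Anything not resolvable this way excludes the record with a warning, and a
config hook (`aligned_genes`) accepts externally aligned per-gene FASTA
for such cases.

Two further curation rules:

* **ND4 3' window.**  The 3' end of the ND4 heavy-strand equivalent is
  hard to align across subspecies; a 37-column window anchored at the 3'
  end of the ND4 partition is excluded by default.  Because published
  coordinates for this window do not exist, the window is a configuration
  parameter (gene, offset, width).  Under the canonical subspecies-level
  layout (11,043 coding bases) the default yields 11,006 analyzed columns.
* **Ambiguity resolution.**  Stray IUPAC calls (mostly W in AT-rich
  context) are replaced by the column's unanimous unambiguous state when
  one exists — making the column invariant — otherwise by the column
  majority, ties broken by the reference row.  Every replacement is
  logged.  This mirrors the practice of treating such calls as sequencing
  noise rather than polymorphism; the exact historical set of resolved
  columns is unknowable, so the rule is stated and tested instead.

Masked and spacer columns are excluded from *every* downstream statistic;
tests assert that masking a constant column changes no result.

## Site statistics and codon filters

A column is parsimony-informative when at least two states are each
carried by at least two taxa; variable but uninformative columns are
singletons.  Cells holding gaps or unresolved ambiguity codes are excluded
from the state counts, so a state present only in such cells never creates
informativeness — the common parsimony convention; the classification is
tested against a brute-force application of the definition over all
4-taxon columns.  The P12 filter drops third codon positions, the standard
probe for saturation-driven artefacts; P123 keeps everything.  Translation
uses NCBI genetic code 5 (invertebrate mitochondrial); codons touching a
gap, an ambiguity, or a masked column translate to X, which keeps the ND4
partition in frame despite its 37-column mask (37 is not a multiple of 3 —
removing the columns would shift the frame, so translation stays on the
partition grid instead).

## Tree inference

All three engines are native implementations; established packages (ape,
phangorn) appear only as containers, I/O, and as independent cross-checks
in the tests.

* **Neighbor joining** runs on counts of differing unambiguous sites (or
  per-site distances), the scale on which shallow mitogenome work is
  usually reported.  Exact Q-criterion ties — common with integer counts —
  break on the lexicographically smallest leaf-label pair, so the result
  does not depend on input order.  Negative intermediate branch lengths
  are clamped to zero with the deficit shifted to the sibling.
* **Maximum parsimony** is equal-weight Fitch counting (C++ inner loop
  over compressed site patterns, gaps and ambiguities as missing data)
  with hill-climbing SPR from random stepwise-addition starts (default
  10).  *All* distinct minimum-length topologies found are returned: at
  these divergences equal-length trees differing at unresolved nodes are
  the expected outcome, not an anomaly.  Branch substitution counts for
  reporting use a deterministic ACCTRAN-style resolution of the Fitch
  state sets; the per-edge counts sum to the tree length.
* **Maximum likelihood** uses GTR with a proportion of invariant sites.
  Branch lengths are expected substitutions per site averaged over both
  site classes, so the variable class evolves at `b/(1-p_inv)`.  The
  search alternates coordinate-wise Brent on branch lengths (with cached
  transition matrices), Nelder-Mead on transformed model parameters, and
  best-improvement NNI sweeps, until the log-likelihood gain falls below
  `tol` (default 1e-6).  Gamma rate heterogeneity is deliberately out of
  scope.  A start tree without substitution-scale branch lengths is
  re-initialized (topology kept) before optimization — optimizing from a
  saturated start is a known way to strand the fit on a likelihood
  plateau.

**Bootstrap** resamples retained columns with replacement — the same
column universe as the point estimate — re-runs the chosen method per
replicate, and reports bipartition percentages on the point-estimate tree.
The study scale is 3000 replicates; tests use 1–200.

## Strict-clock dating

A rooted ML tree is *linearized*: the topology is fixed and node heights
are re-estimated under the ultrametric constraint, either by constrained
maximum likelihood (root height log-transformed, every other node a logit
fraction of its parent, so nesting holds by construction) or by the
closed-form least-squares projection in which each node's height is the
mean of half the patristic distances of the leaf pairs it joins (for a
two-leaf tree with branches a and b: (a+b)/2).  Heights convert to ages at
a fixed rate, default 0.0115 substitutions/site/Myr, applied per lineage:
`age_Ka = height / 0.0000115`.  Published relative-rate (RelTime-style)
machinery is intentionally not reimplemented: under a single fixed rate
the relaxed-rate superstructure is immaterial to the conversion, so dates
from this package are a documented strict-clock approximation.  Reported
ages round to the nearest integer Ka.

Rooting deserves a note: the root is placed on the *branch* whose split
separates the designated outgroup (`root_by_outgroup()`), because rooting
relative to an arbitrary stored basal node silently misroots whenever that
basal node happens to sit inside the outgroup — a failure mode found and
pinned down by the package's own simulation tests.

The error budget matters when reading dates: a node at 540 Ka spans only
about 70 expected substitutions per lineage at 11 kb, so its height
estimate carries Poisson noise of roughly ±9%.  Tests therefore assert
accuracy on replicate means, and the full-pipeline check asks for mean
absolute relative error within 15% over the backbone nodes of 20 simulated
datasets.

## Taxonomic audit

* `within_between_report()` tabulates the maximum patristic distance
  within each label (undefined for single-member labels — reported NA,
  never 0) and the min/max between each label pair, with the headline
  boolean "between-pair max < within-label max" that argues for synonymy.
* `flag_misassigned()` finds leaves nesting inside a foreign label's
  territory: the leaf's side of every tree split is scanned, smallest
  neighbourhood first, until one returns a strict majority label verdict —
  a rooting-invariant formulation, so a stray sitting in the basal
  (outgroup-side) grade is judged like any other — and the verdict label
  must be foreign and multi-member, with the leaf patristically closer to
  that label's members than to its own.  Candidates are confirmed greedily — strongest
  `d_own/d_foreign` ratio first — and each confirmed flag removes that
  leaf from the trusted member sets before the next round.  The greedy
  loop is what makes the detector robust to label *swaps* (two strays
  shielding each other) and to false capture of honest neighbours by an
  already-contaminated label; both failure modes appeared in simulation
  and are covered by tests.  By default a single-member label nested
  inside another label's clade is *not* flagged — that is legitimate
  nested phylogeographic structure — unless `strict = TRUE`.
* `informative_run_scan()` detects faulty (chimeric) sequence pairs: runs
  of parsimony-informative columns at which the pair shares a state held
  by no other taxon.  "Unbroken run" is read as consecutive *informative*
  columns by default (alignment-adjacent mode available), because
  diagnostic shared runs in real data are runs in the informative-site
  sequence.  The audit flags pairs with an exclusive run of at least 5
  sites (configurable; the motivating real-data example shows runs of 7),
  and adds an attraction-outlier flag when a chimeric leaf also sits
  farther from every member of its own label than that label's internal
  maximum.

## The simulator and what it does (not) show

`sim_config()` defaults define the study conditions: six labeled clades on
a caterpillar backbone splitting at 780, 720, 660, 540 and 250 Ka with
within-clade crown age 100 Ka — echoing the late-Pleistocene timeline this
kind of analysis resolves — four leaves per clade, the canonical 13-gene
subspecies-level layout (11,043 coding bases plus 20-base neutral spacers
standing in for tRNAs), AT-rich stationary frequencies (0.42/0.10/0.06/
0.42), transition-biased GTR exchangeabilities (AG = CT = 6), and the
fixed rate 0.0115 subs/site/Myr.  Within-clade topologies are random-join
ultrametric trees with uniform split times below the crown age.  All
randomness flows from one integer seed; the same seed reproduces every
byte.

Anomaly injection reassigns randomly chosen leaves to foreign clade labels
(registry keeps the truth) and/or overwrites one gene block in two
recipients with a common "ghost" haplotype at 0.2 subs/site divergence — a
grossly corrupted foreign block, which is what makes a chimeric pair light
up as long exclusive informative-site runs against the quiet background of
natural variation.

What passing tests on this simulator do *not* show: real mitogenomes have
indel processes beyond single triplets, recombination-free but
heteroplasmic inheritance, gene-specific rate variation, sequencing-error
structure, and annotation idiosyncrasies far richer than the synonym table
here.  The simulator validates the *machinery* — curation bookkeeping,
estimators, audit logic — under known truth; it cannot validate the
biological adequacy of GTR+I or of any particular clock rate.

## Numerical choices

* Transition matrices via symmetric eigendecomposition of the
  detailed-balance-symmetrized generator; accuracy ~1e-15 (checked against
  scaling-and-squaring Padé).
* Pattern compression before all likelihood/parsimony work; pruning and
  Fitch inner loops in C++ with per-node rescaling against underflow.
* Branch-length bounds [1e-9, 3] subs/site; likelihood convergence 1e-6
  log units; ML clock heights by BFGS on transformed coordinates from the
  least-squares solution.
* Problem sizes in the shipped tests: 4–24 taxa, 11 kb alignments, up to
  20 pipeline replicates and 200 bootstrap replicates — chosen so the
  whole suite exercises study-scale data while staying comfortably
  runnable on a laptop.

## Known limitations

* Strict clock only; dates inherit the single-rate assumption and should
  be read as approximate — across seeded replicates the recovered basal
  split scatters within several percent of its true age, and real data add
  model misspecification on top.
* Positional alignment assumes gene-level homology is already clean
  except for single-triplet indels; messier regions need the external
  alignment hook.
* rRNA, tRNA and control regions are out of scope by design — their
  alignment at this divergence is unreliable.
* The misassignment detector assumes the tree is substantially correct;
  it audits labels against topology, not topology against labels.
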