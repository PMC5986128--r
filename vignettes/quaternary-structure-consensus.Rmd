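---
title: "Consensus evaluation of quaternary-structure annotations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus evaluation of quaternary-structure annotations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsconsensus)
```

## The problem

X-ray crystallography determines the asymmetric unit of a crystal, not the
biological assembly: crystal-packing contacts and biologically relevant
interfaces look alike in the lattice. As a result, a non-negligible fraction
of archived quaternary-structure annotations (the oligomeric state a
structure is believed to adopt in solution) are wrong. This package
implements a consensus framework for evaluating such annotations. A
quaternary structure is described by two components:

* **stoichiometry** — the subunit composition formula (`A` monomer, `A2`
  homodimer, `A2B2` two-component heterotetramer). Letters are abstract
  subunit types ordered by copy count, not chain identifiers.
* **symmetry** — the rotational point group of the assembly: cyclic `Cn`,
  dihedral `Dn`, or cubic `T`/`O`/`I`; `H` labels open helical symmetry.

Four independent predictors produce `(stoichiometry, symmetry)` calls per
entry, and a majority vote aggregates them. A benchmark evaluator compares
calls against curated references and classifies each as correct, incorrect,
inconclusive, or not available.

## The four methods

### Sequence clustering (SC)

Chains are clustered by pairwise sequence identity with single linkage: an
edge joins two chains when a global alignment gives identity at least *k*%
with at least 90% coverage of **both** sequences, and clusters are the
connected components. We use global Needleman–Wunsch alignment with BLOSUM62
scoring (gap opening 10, extension 0.5); identity is counted over the
columns between the first and last position aligned in both sequences
(terminal gaps excluded), which is a deterministic, dependency-free stand-in
for the heuristic local-match clustering used operationally in the field.
The contract is the same — "*k*% identical over 90% of the same length" —
but edge sets near the threshold may differ from heuristic tools, which is
why the clustering tests use fixtures whose identities sit safely away from
the threshold.

Each cluster is associated with two discrete random variables, the
stoichiometry $S_t$ and symmetry $S_y$ of its members' archived
annotations. The consistency score of a pair $(t, y)$ is the product of the
empirical marginals:

$$C(t, y) = P(S_t = t)\,P(S_y = y)$$

The representative state of a cluster is the pair maximizing $C$, accepted
only when the maximum is **strictly** greater than 0.5 (exactly 0.5 is
inconclusive); clusters smaller than a minimum size produce no call at all.
Default minimum sizes are benchmark-calibrated: 5 members at the 40%
identity threshold, 3 at 70/90/95%. Members missing one component are
dropped from that component's marginal with renormalization. The product
form treats the two components as independent; the empirical joint
frequency is available behind `consistency_score(..., joint = TRUE)`
because the defining equation equates the two, and on degenerate clusters
they coincide.

Two points were genuinely open and are our decisions: (i) heteromeric
entries are clustered by the same chain-level criterion as homomers (the
procedure is stated to treat both alike, without detail); the synthetic
fixtures keep heteromers in distinct clusters so tests do not depend on
this; (ii) an entry's own annotation is not excluded from its cluster
profile when predicting for that entry.

### Text mining (TM)

The pipeline over an article's full text: split into sentences → keep
sentences mentioning an oligomeric-state keyword → keep sentences a trained
classifier labels quaternary-structure relevant → keep sentences carrying
experimental-evidence keywords → tally the oligomer keywords of the
survivors and call a strict majority. Ties are inconclusive ("majority" is
undefined at a tie, and the conservative reading abstains); an article that
yields no surviving sentence is inconclusive; a missing article is not
available. TM predicts only the oligomer **order** (a "dimer" mention
cannot distinguish `A2` from `AB`) and never predicts symmetry.

Numerical and preprocessing choices, each configurable:

* Sentence features are tf-idf weights,
  $\mathrm{tfidf}(n,s) = \mathrm{tf}(n,s)\,\log(N/\mathrm{df}(n))$, with the
  **natural** logarithm (the customary default; the base is otherwise
  unspecified).
* Preprocessing lower-cases, strips internal punctuation (hyphens split, so
  "size-exclusion" matches "size exclusion"), collapses whitespace.
* Features are hashed with MurmurHash3 (x86 32-bit, implemented in C++ and
  checked against an independent reference implementation) into $2^b$
  buckets with sign hashing; $b = 18$ is the standalone default. The
  classifier's training matrix defaults to $2^{12}$ buckets, which keeps
  dense matrices small for corpora of a few thousand sentences; raise it
  toward $2^{18}$ for large corpora.
* The SVM uses an RBF kernel with `sigma = 0.013` and `cost = 4`, the
  values tuned by cross-validated grid search on the original training
  corpus, in the same `sigma` parametrization
  ($k(x,y)=\exp(-\sigma\lVert x-y\rVert^2)$) used by the tooling that
  produced them. Boosted logistic regression (101 iterations) is available
  as the alternative algorithm.
* Evidence keywords are required in the **same sentence** as the oligomer
  keyword by default (the stricter reading); `evidence_scope = "article"`
  relaxes this to anywhere in the article.
* The shipped oligomer and evidence keyword lists are editable defaults
  (monomer through dodecamer with plural/adjectival/homo-/hetero- variants;
  solution experiments such as size-exclusion chromatography, analytical
  ultracentrifugation, light scattering, native PAGE, cross-linking). The
  original full lists are supplementary material not reproduced here.

The original 11,000-sentence training corpus is not deposited, so its
published test-set metrics (e.g. SVM accuracy 0.94, AUC 0.98) are reference
documentation only; the package's classifier tests run on synthetic corpora
with controlled vocabulary overlap.

### PISA-style adapter

Assembly-candidate XML is parsed into candidates carrying a dissociation
free energy, surface areas, and per-chain rigid-body operators. Candidates
with positive dissociation energy are stable, negative unstable, and values
within a configurable gray band (default ±0.5 kcal/mol — the borderline
region is not quantified anywhere authoritative) are indeterminate. The
prediction takes the stable candidate with the largest dissociation energy
(ties: larger buried surface, then lower assembly id — a selection rule the
source material leaves open), rebuilds it with the point-group classifier,
and reports its stoichiometry and symmetry. Only-gray candidates give an
inconclusive call; if every multimeric candidate is unstable the
dissociated monomer `(A, C1)` is predicted; an empty candidate list means
the method produced no result.

### EPPIC-style adapter

The prediction XML already carries stoichiometry and symmetry strings; the
adapter parses them, canonicalizes the stoichiometry, and leaves missing
fields absent.

The two XML dialects are defined by this package's fixture writers and
documented in their help pages; adapting real exports may need a thin
element-name mapping.

## Operator-based point-group classification

Given a set of rigid operators (rotation + translation), the classifier:

1. deduplicates operators and requires the identity and proper rotations
   only (improper operators are rejected — chiral macromolecules admit only
   rotational point groups);
2. solves for the least-squares common fixed point of all operators
   (minimum-norm SVD solution, since rotation axes are null directions) and
   rejects sets whose residual shows the axes are not concurrent — this is
   what separates point groups from screw/helical arrangements;
3. checks closure: every pairwise composition must match a member within a
   relative tolerance (default `1e-3`);
4. computes each element's axis (from the antisymmetric part, or the
   dominant eigenvector of $(R+I)/2$ near 180°) and its order by repeated
   multiplication — more robust against rounded operator entries than
   dividing $2\pi$ by the angle;
5. classifies by group order $N$ and axis folds: one shared axis → $C_N$;
   an $n$-fold principal axis with $n$ perpendicular 2-folds and $N = 2n$ →
   $D_n$; $N=12$ with only 2- and 3-folds → $T$; $N=24$ with a 4-fold →
   $O$; $N=60$ → $I$.

Angle and axis tolerances default to 0.05 rad; operator files in the wild
carry limited printed precision, and these are declared defaults, not
reproductions of any other tool's settings. Classification is invariant
under global conjugation (tested over random rotations and off-origin
centers), and the tests also verify agreement with an independent oracle
that classifies purely from the abstract multiplication table.

`assembly_descriptor()` combines entity-label counts (stoichiometry) with
the classification of the deduplicated operator set. Distinct entity labels
are never collapsed, yet the operator set is classified as-is: a 2+2
assembly of two distinct entities on a D2 operator set reports `(A2B2,
D2)`. This is deliberate — it reproduces the hemoglobin convention where
the D2 arrangement is reported even though entity identity only supports
C2 — and it is the one place where the descriptor is a property of the
operator geometry rather than of the labelled chains.

## Consensus and evaluation

Votes are collected per entry after the exclusion rules: not-available
results never vote; inconclusive results are excluded from the denominator
by default (retaining them as denominators is available behind
`include_inconclusive`). Stoichiometry and symmetry are decided
independently, each by a **strict majority of the votes carrying that
component** — the quorum question is not settled anywhere explicit, and
this reading reproduces the worked monomer-reannotated-as-dimer example
while interacting correctly with the exclusion rules. TM participates only
in the stoichiometry vote, by order: its vote backs the unique co-voted
formula with the same total subunit count, stands as the bare `An` formula
when no candidate shares its order, and abstains when several distinct
formulas share the order. The three-method consensus is the same engine
with TM excluded.

Outcomes: both compared components match → correct; all compared
components mismatch → incorrect; one right and one wrong → inconclusive, as
is a prediction that is itself inconclusive. Agreement analysis attributes
each entry to the **exact** subset of methods sharing an outcome, so subset
counts are disjoint within a category. An entry is flagged a possible
outlier when a conclusive consensus disagrees with the deposited archive
annotation on any compared component; the outlier fraction is taken over
entries with a conclusive consensus (whether the corresponding published
fraction used all entries or conclusive ones as denominator is not stated;
we chose the conclusive denominator and record it here).

## Synthetic fixtures: what they emulate and what they do not

All tests run offline from generated inputs; every generator is
deterministic given its seed and emits its own expected result, so the
generator's bookkeeping is the oracle for the engine under test.

* **Cluster fixtures** mutate a seed sequence by point substitutions only
  (no indels), keeping within-cluster identities analytically above the
  threshold with a 5% margin and between-cluster identities at random-
  sequence background. Real homolog clusters have indels, domain
  truncations, and borderline identities; passing tests show the clustering
  and scoring machinery is correct, not that the alignment heuristics match
  any particular external tool near the threshold.
* **Corpora** are templated sentences (positives embed an oligomer keyword
  plus an evidence phrase; negatives place oligomer keywords in
  asymmetric-unit/crystal-packing contexts) with controlled vocabulary
  overlap between classes. Disjoint vocabularies give a corpus separable by
  construction — the held-out accuracy requirement (≥ 0.95 over 5 seeds at
  200+200 sentences) validates the feature pipeline and training loop, not
  performance on real prose.
* **Assembly XML** is written with analytically generated operator sets
  (Cn, Dn about standard axes; T, O, I closed from generators), optionally
  conjugated and re-centered.
* **Benchmark tables** sample reference annotations from the combined
  benchmark's published oligomer composition (543 entries: 248 monomers,
  209 dimers, 26 trimers, 44 tetramers, 14 hexamers, 1 octamer, 1
  dodecamer) and draw an outcome category per method from a per-method
  profile reflecting the reported per-method behavior: SC with a low error
  rate but a sizeable not-available share (small clusters), TM with a
  large inconclusive/not-available share, PISA/EPPIC always voting with
  accuracies in the reported 46–81% band. Dissenting methods are planted
  with mutually distinct wrong answers, so wrong votes never form
  accidental majorities. Real methods' errors correlate (the two
  energy/evolution-based predictors often fail together), which is why the
  synthetic consensus rates come out more favorable than the published
  benchmark's; the planted table validates the voting, exclusion, and
  evaluation logic exactly, not the real-data error structure.

## Problem sizes used by the test and acceptance runs

Chosen as comfortable sizes for the properties being checked: 1,000 random
cluster profiles for the consistency-score oracle; all groups Cn (n ≤ 12),
Dn (n ≤ 6), T, O plus 100 random conjugations for the point-group oracle;
20 random corpora for the tf-idf closed form; 5 × (200+200)-sentence
corpora for the classifier property; the full n = 543 synthetic benchmark
for planted-summary recovery; 16–17 sequences for the single-linkage
union-find equivalence.

## Known limitations

* Helical (open) symmetry is accepted as a label but never produced by the
  classifier; coordinate-based (pseudo)symmetry perception from atoms is
  out of scope — only operators and entity labels are used.
* Alternative-interface assemblies with identical stoichiometry and
  symmetry are indistinguishable in this representation.
* The pairwise-identity stage is quadratic in the number of sequences and
  is meant for benchmark-scale inputs, not archive-wide clustering.
* The published per-entry benchmark prediction table and the 11,000-sentence
  training corpus are journal supplementary material and are not shipped;
  the corresponding published headline rates are therefore reproducible
  only after placing that table under `inst/extdata/` (see the acceptance
  test), and the package's own numbers come from the synthetic benchmark.
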