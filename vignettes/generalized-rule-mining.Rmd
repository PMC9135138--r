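---
title: "Mining generalized association rules with garmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining generalized association rules with garmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(garmine)
```

## The problem and the model

Classical association rules are implications of the form
`a AND b AND ... -> y` between attribute predicates of a categorical data
table: if a record satisfies every term on the left-hand side (LHS), it
tends to satisfy the right-hand side (RHS). In clinical and epidemiological
tables — many attributes, many missing entries — pure conjunctions are often
too rigid: the interesting antecedent is frequently "one of several
near-equivalent exposures". garmine therefore mines *generalized* rules,
whose LHS is a conjunction of disjunctions (AND of OR-clauses) of
*elementary equalities*, each equality stating that a column's value lies in
a given set, e.g.

```
age=AB AND (bread=y OR onions=n) -> butter=y
```

Two properties make this form attractive. Any monotone antecedent over the
equalities can be written this way, and the form is compact: expanding an
AND-of-ORs LHS into disjunctive normal form produces one pure conjunction
per choice of a slot from each clause, so a LHS of three two-way
disjunctions stands for `2 * 2 * 2 = 8` classical rules
(`gar_dnf_count()` reports this count).

Rules are ranked and filtered by four standard interestingness measures,
all empirical frequencies over the `N` table rows:

* **support** — rows where LHS and RHS both hold;
* **confidence** — support / LHS-support, the conditional frequency of the
  RHS given the LHS;
* **lift** — `Pr(LHS and RHS) / (Pr(LHS) * Pr(RHS))`, 1 under independence;
* **leverage** — `Pr(LHS and RHS) - Pr(LHS) * Pr(RHS)`, the additive
  analogue of lift (the Piatetsky–Shapiro measure), 0 under independence.

Leverage has no universally fixed formula in the literature's shorthand
lists; garmine fixes the Piatetsky–Shapiro form above, which pairs with
lift so that `leverage = 0` exactly when `lift = 1`.

### Missing values and N

The input dialect reduces every cell to a single printable ASCII character;
an empty cell is missing (N/A). A missing cell satisfies *no* elementary
equality, and `N` is always the full row count, including rows with missing
entries in the rule's columns. The alternative — excluding, per rule, the
rows with missing values in referenced columns — would make `N` (and hence
lift) rule-dependent and the measures incomparable across rules; with the
chosen reading, sparse columns simply yield lower supports. This is the one
place where two readings of the measures genuinely diverge on sparse
tables, so it is worth stating: garmine includes such rows in `N`.

## The search

A *rule pattern* such as `_ AND (_ OR _) -> _` fixes the Boolean shape; the
miner fills the blanks with elementary equalities. The RHS is always a
single blank, and the search is partitioned by it: every permitted RHS
assignment is one independent job, and the merged output is identical for
any `jobs` setting (the partition is a pure partition; worker scheduling is
deliberately not part of the contract).

Candidate equalities per column are the non-empty value subsets of the
column's observed domain up to `max_value_set_size` (default 2), excluding
the full domain, which is true on every non-missing row and carries no
information. The default cap keeps the otherwise exponential enumeration
linear-ish in the domain size while still admitting two-value sets like
`age=AB`; it is configurable. The RHS defaults to singleton equalities.

Three conventions make each unordered rule appear exactly once despite the
commutativity of AND and OR: within a clause, slots are filled in strictly
increasing canonical order of (column, value set) with pairwise distinct
columns; structurally identical adjacent clauses must fill to
non-decreasing tuples; and the RHS column is excluded from the LHS. A
column may still appear in two different clauses; contradictory repeats
(e.g. `x=a AND x=b`) die naturally at the support bound. Whether one clause
should ever hold two equalities of the same column is genuinely open; the
disjunction `x=ab` already expresses `x=a OR x=b`, so forbidding duplicate
columns inside a clause loses nothing expressible.

Pruning uses a sound support bound: with some clauses fully assigned, the
support of any completion is at most the size of the intersection of the
assigned clauses' row sets with the RHS row set (conjunction only shrinks;
unfilled clauses are the universal set). The miner backtracks whenever this
bound drops below `min_support` — the bound is exact at the leaves, so
pruned search and exhaustive-then-filter search are provably equivalent,
which the test suite checks against an independent per-row oracle across
hundreds of random tables. All four thresholds are inclusive (`>=`), and
rules whose LHS or RHS holds on no row are discarded as carrying no
evidence.

### Bit-parallel evaluation

Every equality's row set is a packed bitset (8 rows per byte in an R raw
vector); OR within clauses and AND across clauses are single vectorised
byte-wise operations, and cardinalities come from a 256-entry population
count table. Whole blocks of rows are thus processed per machine
instruction instead of row by row. The per-row interpreter the tests
compare against lives in the test helpers, kept deliberately separate from
the packed implementation.

## Simplification

The requested pattern is the *most complex* shape returned, not a
guarantee: after filtering, each rule is greedily simplified. A deletion
step removes either a whole conjunct clause or a single disjunct from a
multi-slot clause. At every step all admissible deletions are evaluated;
one *qualifies* if the resulting rule still passes all four thresholds and
its lift is at least `(1 - tolerance)` times the lift of the **original**
rule (default tolerance 0.02, i.e. 2 %). The qualifying deletion with the
highest resulting lift is applied; ties go to the textually smaller rule,
for determinism. The process stops when nothing qualifies; the last clause
is never deleted.

Three design points were genuinely open and are fixed as follows:

* *Anchor of the tolerance.* The 2 % budget is measured against the
  original rule's lift, not the previous step's — an iterated-relative
  reading would let lift decay without bound over many steps.
* *Relative, not absolute.* The tolerance is a fraction of the lift, not
  2 percentage points of lift; an absolute reading would be negligible for
  high-lift rules and crushing near lift 1.
* *Filter-then-pick.* A deletion whose result fails a threshold is simply
  not admissible (rather than terminating the whole simplification); the
  greedy choice is made among admissible deletions only.

Because every accepted step respects the floor, every reported rule
satisfies `lift >= (1 - tolerance) * lift_pre_simplify`, which the
acceptance suite verifies across a hundred seeded fixtures. Rules that
become identical after simplification are reported once. Results are
sorted by lift, then support (both descending), then rule text, and the
TXT/XML reports contain no timestamps, so outputs are byte-identical
across repeated runs — a deliberate trade of a "timing note" field for
reproducibility (timing goes to the log instead).

## The synthetic fixture generator

`gar_planted_spec()` / `gar_generate_table()` build tables in the same CSV
dialect with one planted generalized rule whose metrics are realized
*exactly* by construction, not in expectation: `coverage * n` rows satisfy
the LHS, `confidence * coverage * n` of them satisfy the RHS, and the
remaining rows satisfy the RHS at exactly the background rate (the spec is
rejected unless these products are whole numbers). Everything else — which
disjunct carries a row, which rows are RHS-positive, noise columns, row
order — comes from one Mersenne–Twister stream keyed by the seed, so
fixtures are byte-reproducible and leave the caller's RNG untouched.

The construction keeps every planted clause informative: each non-LHS row
falsifies exactly one clause (round-robin), so deleting a conjunct admits
that clause's block of background rows and visibly drops confidence and
lift; and each disjunct of a multi-slot clause uniquely satisfies its
round-robin share of LHS rows, so deleting a disjunct loses a proportional
share of support. At thresholds 10 % below the planted metrics this makes
the planted rule the unique top hit, which is the package's
parameter-recovery test.

What the generator does *not* emulate: correlated attributes, structured
missingness (its optional N/A noise blanks only non-planted cells,
independently), domains beyond a handful of characters, and multiple
overlapping planted rules. Passing tests on these fixtures therefore show
correctness of the machinery — counting, pruning, simplification, ranking —
not robustness of rule discovery on messy real tables.

### Problem sizes used in the test suite

The standard planted fixture is 200 rows, three planted columns plus an
outcome and two 4-valued noise columns (coverage 0.4, confidence 0.9,
background 0.1). The pruned-vs-exhaustive equivalence suite draws 200
random tables up to 6 columns x 4 values x 64 rows for patterns with up to
two LHS slots, and up to 4 columns x 3 values for the two-clause
disjunctive pattern, where the exhaustive oracle's candidate space grows
multiplicatively; the pruned miner itself is exercised on the larger
tables throughout. These sizes give the oracle suites full coverage of the
combinatorics while keeping a complete test run comfortably fast on one
core.

## Numerical and degenerate-input choices

* Delimiter: chosen by majority count of `;` vs `,` in the header (ties to
  comma) — the dialect admits both and a file states no preference.
* Cells are whitespace-stripped before the first-character truncation; a
  whitespace-only cell is missing. Otherwise `' y'` and `'y'` would be
  silently distinct values.
* Values are case-sensitive: different characters are different values.
* Ragged rows are a hard error, not padded — padding would fabricate
  missingness.
* There is no quoting: a single-character cell cannot contain a delimiter.
* An all-missing column parses fine but offers no equalities, so it is
  simply unusable in rules; querying it yields the empty row set.
* Metrics are printed with four decimals (C `%f` rounding of the binary
  doubles); ranking and thresholds always use the full-precision values.
* `_`/`->` are accepted as ASCII aliases of the box and arrow glyphs.

## Limitations

The value-set cap (default 2) means some informative wide equalities are
never proposed; raising it is exponential in the domain size. The miner is
exact, so very permissive thresholds on wide tables enumerate large
candidate spaces — support thresholds are the practical lever, since they
drive the pruning bound. Negation is not a token; complements must be
expressed as value sets. And the simplifier is greedy: it guarantees the
lift floor, not that the returned rule is the globally simplest equivalent.
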