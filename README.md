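# garmine

Generalized association rule mining on categorical data tables.

## What it does, and for whom

Large clinical, epidemiological and survey tables — many categorical
attributes, plenty of missing entries — hide implication-like relations
between attribute values: classic association rules such as

```
(high cholesterol) AND (high blood pressure) -> (heart disease)
```

`garmine` mines the *generalized* form of these rules, in which the
left-hand side is a conjunction of disjunctions (an AND of OR-clauses) of
elementary equalities, e.g.

```
age=AB AND (bread=y OR onions=n) -> butter=y
```

where `age=AB` means "age is A or B". Disjunctive antecedents matter for
combinatorial biomarker discovery: one generalized rule compresses many
classical rules (a LHS of three two-way disjunctions stands for 2×2×2 = 8
pure conjunctions), which keeps result tables short and readable.

Given a table, a *rule pattern* with blanks (e.g. `_ AND (_ OR _) -> _`)
and thresholds, the miner:

1. enumerates every sensible filling of the blanks with elementary
   equalities (value sets up to a configurable size; the tautological full
   domain is never used);
2. prunes the search with a sound branch-and-bound support bound, so the
   result provably equals exhaustive enumeration followed by filtering;
3. evaluates candidates with word-parallel bit operations (packed row
   bitsets, whole machine words per logical operation);
4. keeps rules meeting the inclusive thresholds on **support**,
   **confidence**, **lift** and **leverage**:
   `confidence = support/lhs_support`,
   `lift = Pr(LHS∧RHS)/(Pr(LHS)·Pr(RHS))` (1 under independence),
   `leverage = Pr(LHS∧RHS) − Pr(LHS)·Pr(RHS)` (0 under independence);
5. simplifies each survivor greedily, deleting conjuncts or disjuncts as
   long as lift stays within 2 % (configurable) of the original rule's
   lift — the requested pattern is the most complex shape returned, not a
   promise;
6. merges the per-RHS jobs into one deterministic ranking (lift, then
   support, then rule text) and writes TXT and/or XML reports that are
   byte-identical across runs.

The input dialect is a comma- or semicolon-separated CSV: header line with
column names, then one record per line; every cell is reduced to a single
printable ASCII character (whitespace stripped, then truncated to the
first character), and an empty cell is N/A, which satisfies no equality.

## Worked example

The packaged `groceries.csv` is a 24-row shopping table with columns
`age` (A/B/C), `bread`, `onions`, `butter` (y/n, one missing cell):

```r
library(garmine)

tab <- gar_read_table(system.file("extdata", "groceries.csv", package = "garmine"))
res <- gar_mine(tab, "_ AND (_ OR _) -> _",
                min_support = 8, min_confidence = 0.7, min_lift = 1.2,
                rhs_columns = "butter")
tidy(res)
```

```
# A tibble: 9 × 9
  rule                                         support lhs_support rhs_support confidence  lift leverage
  <chr>                                          <int>       <int>       <int>      <dbl> <dbl>    <dbl>
1 age=AB AND bread=y -> butter=y                     8           8          13      1      1.85    0.153
2 bread=y -> butter=y                                9          10          13      0.9    1.66    0.149
3 age=AC AND (age=BC OR bread=n) -> butter=n         9          12          11      0.75   1.64    0.146
4 age=AC AND (age=C OR bread=n) -> butter=n          9          12          11      0.75   1.64    0.146
5 bread=n AND (age=AC OR onions=n) -> butter=n       8          11          11      0.727  1.59    0.123
6 bread=n AND (age=AC OR onions=y) -> butter=n       8          11          11      0.727  1.59    0.123
7 bread=n AND (age=BC OR onions=y) -> butter=n       8          11          11      0.727  1.59    0.123
8 age=AB AND (age=B OR onions=n) -> butter=y         9          12          13      0.75   1.38    0.104
9 age=AB AND (age=BC OR onions=n) -> butter=y        9          12          13      0.75   1.38    0.104
```

Reading the top rule: 8 of the 24 shoppers are young-or-middle-aged
(`age=AB`) bread buyers, and every one of them buys butter (confidence
1.00), 1.85× more often than butter's base rate of 13/24. The
`simplified_from` column records that it was simplified from the
disjunctive candidate `age=AB AND (age=C OR bread=y) -> butter=y`: the
extra disjunct did not pay for itself in lift, so the reported rule is
simpler than the requested pattern. `glance(res)` summarises the run (jobs, pruned
branches, rule counts); `autoplot(res)` draws the support–lift plane.

The same run from a shell, via the thin CLI wrapper:

```sh
Rscript inst/scripts/garmine --in groceries.csv --pattern "_ AND (_ OR _) -> _" \
  --min-support 8 --min-confidence 0.7 --min-lift 1.2 \
  --rhs-columns butter --txt out.txt --xml out.xml
```

Seeded synthetic tables with planted rules of exactly known metrics come
from `gar_planted_spec()` + `gar_generate_table()`; see the methods
vignette (`vignettes/generalized-rule-mining.Rmd`) for the model,
parameter conventions and design decisions.

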