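---
title: "Quarterly migration typologies from HDSS registers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quarterly migration typologies from HDSS registers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hdssmove` implements an analysis pipeline for internal migration of
children and adolescents observed in a health and demographic surveillance
system (HDSS). Surveillance registers record residence *episodes* — who
lived in which household between which dates — together with parent and
spouse links, household GPS coordinates, and annual survey rounds. The
pipeline turns that episodic record into a quarterly panel, detects and
classifies moves, derives family-structure variables from the kinship
graph, and quantifies the association between family context and mobility.
This vignette explains the model and the design decisions; the README shows
a worked run.

## From episodes to a quarterly panel

Computing kin-proximity exposures requires pairwise distances between every
index person and their relatives at a common time point, which is
prohibitive on episodic data. The pipeline therefore snapshots the register
once per quarter, on the 15th of the quarter's middle month (Feb/May/Aug/Nov
15), and treats the result as panel data. A person contributes a record at a
snapshot exactly when a residence episode covers that date; episodes are
half-open `[start, end)`, so a move on a snapshot day counts the person at
the destination. Survey-derived covariates (school attendance, marital
status, parental education) are taken from the nearest survey within a
validity window — 12 months forward-carried and 6 months backward-carried by
default, both configurable, since surveillance surveys are annual and their
values age slowly.

Age is the exact day difference divided by 365.25, and every age interval in
the pipeline is half-open `[a, b)`: a boundary age belongs to the older
category. Life stages are sex-specific — females are children under 12 and
adolescents at 12–24, males children under 16 and adolescents at 16–28 —
reflecting earlier female transitions to adulthood in the study setting;
older records are excluded from stage-specific analyses. Each sex-by-stage
range is split into four age subgroups. The male-child bands are implemented
as the contiguous quartets [0,4), [4,8), [8,12), [12,16); the source
material's bullet list leaves age 3 unassigned between "under 3" and "4–7",
and contiguity with equal widths is the only reading that partitions the
range.

Population density is the number of co-temporal surveillance residents
within 250 m of the index household, index excluded; members of one
household share a count because distances use household coordinates. The
category thresholds are within-dataset tertiles, computed on the full panel
and logged, because no external threshold is canonical.

## Move detection and the four-way typology

A move is detected when a person's *geographic* household ID (which changes
when a household relocates or re-forms, unlike the stable unique ID) differs
at the following snapshot; absence at the next snapshot with a recorded
out-migration, or absence at the previous snapshot with a recorded
in-migration, are outward and inward moves. Internal displacements under
5 m are dropped: they are artefacts of geographic IDs being re-assigned
when a new household head is declared. When several candidate moves attach
to one person-quarter (for example an in-migration followed by an
out-migration between snapshots), exactly one is kept uniformly at random;
the draw is seeded and consumed in (person, quarter) order so runs are
reproducible. Internal and outward moves are attributed to the snapshot
*preceding* the move, so covariates describe the sending household;
in-migrations, which have no pre-move record, attach to the arrival
snapshot and are excluded from the regression for exactly that reason.

Distances are haversine great-circle kilometres on a 6371.0088 km sphere —
within about half a percent of ellipsoidal geodesics at surveillance scale,
which cannot flip a 4 km classification in practice; the test suite uses an
independent geodesic implementation as oracle. External endpoints resolve
against a gazetteer: Malawian towns carry a central-point coordinate,
foreign countries the border point nearest the study area. Unresolvable
labels leave the move unclassified; such moves are counted and excluded
from distance-classified outputs rather than guessed.

Moves are *short* strictly below the 4 km cutoff and *long* at or above it.
The cutoff is a configured constant, not re-estimated per run; the
`derive_distance_cutoff()` diagnostics reproduce its empirical motivation —
among children still in primary school whose geographic household ID changed
between consecutive annual interviews, those who kept the same school moved
short distances (the published analysis reports a 0.9 km mean) while school
changers moved much farther (4.6 km mean) — with group means and 95%
intervals cluster-robust by individual.

A move is *independent* when no co-mover is a parent of the index (of any
age) or an adult aged 18 or over, and *accompanied* otherwise; the index's
own age is irrelevant. Co-movers are origin-household members with the same
destination household ID (internal moves) or the same normalised source or
destination town/country (external moves). Crossing the two axes yields the
four-way outcome: short/long × independent/accompanied.

## The kinship graph and family variables

Parent links define typed blood edges and the marriage table defines
spousal edges with validity intervals. Five kin sets drive the family
variables, age-evaluated at the query date:

* **maternal / paternal** — blood kin reachable through the mother/father
  within three parent–child edges of that parent (grandparents, aunts and
  uncles, their children). The walk never passes through the index or the
  index's siblings: sibling families are covered by the next two sets, and
  this also keeps the other parent out of the side set. Three edges bounds
  an otherwise unbounded notion of "relative" for computability; the depth
  is configurable.
* **sister's / brother's family** — siblings of that sex aged 18 or over
  (younger siblings are nuclear family), their current spouses and their
  children.
* **nuclear** — parents plus siblings under 18.

The household-composition category of an index person applies a fixed rule
cascade over co-residents: `no_ids` (no parent identifiers, so kin cannot
be established), `external` (household outside the area), `spouse`,
sister's/brother's family, mother & siblings, father & stepmother,
maternal, paternal, parents & siblings, `other`. The published category
definitions are not mutually exclusive, so precedence had to be fixed:
spouse dominates (spousal households dominate adolescent flows), the listed
order follows, and "parents & siblings" acts as the residual before
`other`, inverting its own "does not fit any below" clause. "More maternal
than paternal"-style comparisons are strict majorities; ties fall through
to the next rule. "Father's other wife" is any current wife of the father
other than the mother, via polygynous spousal edges. The classifier is
total — every roster receives exactly one category — and the test suite
checks it against an independent declarative enumeration on ten thousand
random rosters.

Kin-proximity flags mark, per kin set, whether at least one member lives
within 250 m (inclusive, same haversine metric) but in a different
household. Household age-band counts use seven half-open bands (<1, 1–4,
5–11, 12–18, 19–29, 30–59, 60+), index excluded.

## Clustered descriptives

Person-quarters are correlated within unique household IDs and within
individuals, and the two clusterings are crossed because people change
households. All descriptive uncertainty therefore uses the two-way
Cameron–Gelbach–Miller combination
`V = V(household) + V(individual) − V(household × individual)`,
each term a one-way cluster-robust sandwich (the implementation is
hand-written and cross-checked against `sandwich::vcovCL` in the tests).
Proportions carry normal-approximation intervals on the percent scale,
truncated to [0, 100]; sex comparisons are two-sided Wald tests from a
linear probability model with the same variance. A simulation with
household and individual random effects under an equal-proportions null
shows the test holds its 5% size (type-I error within Monte-Carlo error of
nominal over 1000 replicates).

Flow tables tabulate short moves — the stratum with full information on
both ends — by sending and receiving composition (receiving is the
composition at the post-move snapshot; absent post-move records are
`external`), per stage × independence stratum, with per-sex column percents
and Sankey-ready node/link exports. Printed-table comparisons round half-up
to one decimal. Parent-accompaniment tables classify accompanied moves by
which biological parents co-moved (neither / mother only / father only /
both).

## The multilevel multinomial model

For each sex × stage stratum the outcome per person-quarter is `none`
(baseline) or one of the four move types, and for each non-baseline
category *k*

&nbsp;&nbsp;&nbsp;&nbsp;log P(y = k)/P(y = none) = x′β_k + u_household,k + v_individual,k

with independent Gaussian random intercepts at both levels. Covariates are
the composition category (baseline parents & siblings), the seven age-band
counts, the five kin-nearby flags, own-child presence (adolescents only),
parental death indicators ("known to be dead": unknown vital status counts
as alive), age subgroup, two-year calendar band, tarmac-road distance,
density tertile, parental secondary education and the household head's
employment rank. Rows are excluded when the move outcome is an in-migration
(no sending-household information), when the person lacks both parent IDs,
when composition is `other`/`no_ids`/`external`, or when socio-economic
fields are missing; every exclusion is counted by reason.

No estimator in the R ecosystem fits a cross-classified multilevel
*multinomial* logit directly, so the model is estimated by the
binary-decomposition device of Begg & Gray (1984): for category *k*, rows
with outcome in {none, k} follow a binary logit whose linear predictor is
exactly x′β_k plus the two random intercepts — the other categories'
random effects cancel from the ratio and, being independent, make the
conditioning ignorable. Each component is a correctly specified binary
logistic mixed model with crossed random intercepts, fitted by
`lme4::glmer` (Laplace approximation; `nAGQ = 0` available for speed).
Three properties gate the estimator in the tests: on a saturated one-factor
design without random effects the per-category fits coincide with the joint
multinomial MLE (`nnet::multinom`) to four decimals; null data are
recovered as null; and in a simulation at 5000 individuals with six
panel waves each and known coefficients, 95% Wald intervals attain nominal
coverage pooled over the fixed effects across 50 replicates. One caveat the
piloting made explicit: when individuals contribute very few waves the
random effects are weakly identified and the Laplace approximation
attenuates the intercept (a well-documented binary-mixed-model effect); at
realistic panel wave counts the estimates are unbiased. Fitted category
probabilities use the softmax over fixed-effect linear predictors and sum
to one by construction.

## The synthetic register

The study's surveillance data cannot be redistributed (exact household
coordinates and kin configurations are identifying), so the pipeline ships
a demographic microsimulator that generates registers with the structural
features the analysis relies on, and every stage is tested against it.
Events follow competing exponential hazards in continuous time, discretised
to day resolution via monthly Bernoulli draws with `1 − exp(−rate/12)`:
age-band fertility and mortality, female-hazard-driven marriage with
patrilocal residence (probability 0.85 by default; the groom founds a new
household 10–500 m from his father's when he marries out of a parental
household, and a husband may appear in several wives' households under
polygyny), divorce with the wife returning to her natal household with her
young children, child fostering toward kin households weighted toward the
maternal side, whole-household relocation (a short/long mixture), external
out-migration to gazetteer destinations with later returns, and marriages
of local men to in-migrating external brides — who carry no parent IDs and
so exercise the `no_ids` pathway. Founders are generated as patrilocal
clans (brothers' households clustered within ~300 m, wives married in from
other clans) so maternal/paternal kin geography is non-trivial from the
first quarter. Annual surveys record school attendance with the school
being the nearest point of a ~2.2 km grid, which reproduces the
same-school-short-move / changed-school-long-move structure behind the
cutoff diagnostics.

Default rates are chosen once to be plausible for a rural Malawian
population (total fertility around 4–5, widespread polygyny, high young-age
mobility) at desk scale — about 150 founder households and 800–1500 persons
over 2004–2017 for the analysis scripts, smaller configurations in the
tests. The simulator makes no attempt to reproduce the published counts,
which belong to the restricted register of ~40,000 people; what passing
tests establish is that the *machinery* — detection rules, classifiers,
clustered variances, estimator — is correct on data whose ground truth is
known exactly, not that the synthetic population matches the real one.
Real-data features the generator does not emulate include seasonal labour
migration, reporting error in move dates (all synthetic events are exact),
whole-household out-migrations reported by key informants (treated
identically to observed ones), and COVID-era collection disruptions (the
period ends in 2017 for that reason).

## Numerical conventions and limitations

Determinism: every stochastic step takes an explicit seed (simulation,
move tie-break, model simulation); identical configuration and seed give
bit-identical outputs, which the pipeline manifest checksums verify.
Rounding for printed-table comparisons is half-up at one decimal.
Degenerate inputs are flagged rather than imputed: empty risk-curve
denominators yield NA, absent school-change groups leave diagnostics
undefined, and a model stratum emptied by exclusions raises an error naming
the binding filter. Known limitations: within-quarter round trips are
invisible to snapshot-based detection (quantified against ground truth in
the tests); the 3-edge kin-walk bound truncates very distant kin; and the
per-category binary decomposition, while consistent, is slightly less
efficient than joint multinomial maximum likelihood.
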