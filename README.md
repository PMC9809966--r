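# gutvar

Technical versus biological variability in defined gut bacterial
communities.

## The problem

Replicated bioreactor experiments with defined (synthetic) gut bacterial
communities — e.g. *Roseburia intestinalis* (RI), *Blautia
hydrogenotrophica* (BH), *Bacteroides thetaiotaomicron* (BT), *Collinsella
aerofaciens* (CA) and *Prevotella copri* (PC) grown in parallel
batch-then-chemostat vessels — raise a deceptively simple question: when
replicate vessels disagree, how much of the disagreement is biology and
how much is measurement? 16S rRNA gene sequencing, the default community
readout, involves DNA extraction, amplification and sequencing, each of
which adds noise. `gutvar` implements the analysis needed to answer the
question quantitatively, together with an alternative readout that skips
DNA altogether: supervised classification of flow-cytometry events into
species.

The package is aimed at microbial ecologists and bioprocess scientists
running replicated time-series cultivations who want species-resolved
*absolute* abundances and an honest decomposition of their variability.

## What it computes

**Event classification.** Events (23 scatter/fluorescence parameters per
particle) are gated — by a fixed FL1-A threshold of 3.5·10³ or by an
ensemble of six random forests trained on monoculture versus blank data —
and then classified by ten random forests trained on independent draws of
5000 events per gated monoculture (4286 training / 714 test, i.e. a ⌊n/7⌋
hold-out). An event is assigned to species *s* only if at least 7 of the
10 members vote for *s*; otherwise it is `unknown`.

**Absolute abundance.** Volumetric counting gives total cell density
N = (events/μl) · dilution · 1000 (cells/ml). Sequencing counts are
contaminant-filtered (non-member taxa seen in ≤ 1 sample are dropped),
divided by per-species 16S copy numbers, renormalised, and scaled by N.

**Variability statistics.** For every timepoint × variable cell the
coefficient of variation across vessels, CV = sd/x̄, with printed-table
style row/column averages; paired Wilcoxon signed-rank tests (exact null
by full sign-pattern enumeration up to n = 25) comparing the CV
distributions of two methods; population heterogeneity as the mean (or
sum) of per-channel event ranges.

**Ordination.** Bray–Curtis dissimilarity, classical-scaling PCoA, and
least-squares environmental vector fitting with permutation p-values
p = (1 + #{r²_perm ≥ r²}) / (1 + n_perm).

**Synthetic data.** A generator that emulates the study design — 6
vessels sampled at {12, 25, 37, 49, 61, 67} h, 12 h batch then an
emulated chemostat (complete medium changeover in 24 h, D = 1/24 h⁻¹,
non-growing species wash out as e^(−D(t−12))), triplicate 16S counts with
multiplicative technical noise (σ_tech = 0.5) exceeding vessel noise
(σ_bio = 0.15), and two-phase metabolite trajectories — so that the whole
pipeline is testable end to end with known ground truth.

## Worked example

```r
library(gutvar)

# a separable 4-species panel and its monoculture acquisitions
panel <- makeSpeciesPanel(4, separation = 4, seed = 1)
monos <- lapply(setNames(names(panel$species), names(panel$species)),
                function(s) {
  comp <- setNames(rep(0, 4), names(panel$species)); comp[s] <- 2e8
  simulateEvents(panel, comp, n_events = 3000,
                 seed = match(s, names(panel$species)))$events
})

ens <- fitSpeciesEnsemble(monos, n_members = 10, n_events = 2000, seed = 1)
ens
#> SpeciesEnsemble: 10 members, 4 species (sp1, sp2, sp3, sp4), vote threshold 7
#>   held-out accuracy: 0.946-0.968 (train 1715 / test 285 per species)

mix <- assembleInSilicoCommunity(monos,
          c(sp1 = 0.4, sp2 = 0.3, sp3 = 0.2, sp4 = 0.1), 2000, seed = 2)
cc <- classifyEvents(ens, mix$events)
cc
#> ClassifiedCounts: 2000 events (46 unknown)
#> sp1 sp2 sp3 sp4
#> 778 589 389 198
round(speciesCounts(cc) / sum(speciesCounts(cc)), 3)
#>   sp1   sp2   sp3   sp4
#> 0.398 0.301 0.199 0.101
```

The ensemble recovers the mixing proportions (0.4/0.3/0.2/0.1) to within
±0.002 here, with 2.3% of events left unassigned by the 7-of-10 vote
rule. Comparing two methods' CV cells:

```r
pairedWilcoxon(c(0.26, 0.17, 0.11, 0.08, 0.10, 0.09),   # method A CVs
               c(0.07, 0.06, 0.08, 0.06, 0.12, 0.09))   # method B CVs
#> $statistic 14, $w_minus 1, $p.value 0.125 (exact, n = 5)
```

(one zero difference is dropped; the p-value comes from the exact
enumeration of the 2⁵ sign patterns). The full pipeline — simulate,
classify, abundances, CV tables, Wilcoxon comparison, PCoA + envfit —
runs from one call:

```r
man <- runPipeline(list(), out_dir = "run1", seed = 7)
reportRun(man)
#> ## Mean CV per method
#> - seq_rel: 0.4555
#> - cellscanner_rel: 0.1680
#> - HPLC: 0.0476
#> Sequencing vs cytometry CV, paired Wilcoxon one-sided p = 5.96e-08 (mean ratio 3.67)
#> Classifier held-out accuracy: 0.982-0.993 over 10 members
```

On the default scenario the sequencing CVs exceed the cytometry CVs in
every one of the 24 shared (timepoint, species) cells, so the one-sided
exact p is 2⁻²⁴ ≈ 6·10⁻⁸: technical sequencing noise, not vessel-to-vessel
biology, dominates the apparent variability.

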