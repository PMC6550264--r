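# carefrag

Care fragmentation and data-sharing communities from patient-level hospital
event logs.

When a patient presents to one hospital having last been seen at another, the
receiving clinician may not hold their most recent record. `carefrag` is for
health-services researchers and interoperability planners who want to
quantify these **fragmented presentations** in administrative event logs and
to derive, from the data alone, regional **data-sharing communities** of
providers within which record exchange would cover most of them.

The core objects and methods:

* **Transitions** — each patient's consecutive attendance pairs; a transition
  is fragmented iff its providers differ. Headline statistics follow the
  convention of published national analyses of English hospital data: the
  fragmented percentage divides fragmented presentations by all interactions
  of patients presenting more than once.
* **The patient-sharing network** — a weighted undirected graph over
  providers with edge weight *F<sub>AB</sub>* = the number of fragmented
  transitions between providers *A* and *B* in either order.
* **Resolution modularity and Louvain** — partitions are scored by
  *Q*(γ) = (1/2m) Σ<sub>ij</sub> [A<sub>ij</sub> − γ k<sub>i</sub>k<sub>j</sub>/2m] δ(c<sub>i</sub>, c<sub>j</sub>),
  and optimised by a from-scratch two-phase Louvain implementation, validated
  against an exhaustive set-partition oracle and `igraph`'s modularity.
* **Continuity accounting** — per community, the share of fragmented arrivals
  whose previous record already lay inside the community.
* **A synthetic pseudo-HES generator** — event logs with planted provider
  communities and nationally realistic rates, so the whole pipeline is
  testable without access to confidential data.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
cohort (5,000 patients, 40 providers in 4 planted communities):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_descriptives.R
Rscript analysis/03_network.R
Rscript analysis/04_communities.R
Rscript analysis/05_continuity.R
```

which prints, among other output:

```
simulated 32956 events for 5000 patients at 40 providers
81.7% of patients present more than once (target ~81.3%)
fragmented rate per transition: 30.1% (generator switch rate 30%)
Patient-sharing network: 40 providers, 555 edges, total weight 8,421
louvain: 4 communities, Q = 0.678
adjusted Rand index vs planted communities: 1.000
simulated cohort: continuity within communities 92.4-93.0% (pooled 92.8%), baseline 0%
published national table: continuity 65.18-94.3% across 10 communities
```

Reading the numbers: 81.7% of simulated patients are multi-presenters (the
generator is calibrated to the 81.3% observed nationally); 30.1% of
consecutive-attendance pairs switch provider, matching the planted switch
rate; Louvain at γ = 1 recovers the four planted communities exactly
(adjusted Rand index 1); and if each detected community shared records
internally, 92–93% of its fragmented arrivals would already have the previous
record available, versus 0% with no sharing. The same functions applied to
the equivalent in-code API:

```r
library(carefrag)
bundle <- run_pipeline(simulation_config(seed = 20130401L), seed = 1)
bundle$stats
continuity_gain(bundle$community_table)
```

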