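# shoalnet

Proximity-based social networks — and the timescales on which they persist —
from high-resolution fish telemetry.

## The problem

Whole-lake acoustic positioning systems record the 3-D position of every
tagged fish every few seconds for months. `shoalnet` turns such positional
data into a temporal social network and asks three questions of it:

1. **Who interacts, and when?** A social contact is *persistent proximity*:
   two fish closer than 10 m for at least 30 s, where interruptions shorter
   than 5 min belong to the same interaction and single isolated detections
   are discarded. Contacts are inferred from 15 s resampled trajectories
   (30 s median filter over the raw ~5 s bursts), pairwise distance series
   (N(N−1)/2 of them) with gaps linearly imputed up to 30 min, thresholded
   at 10 m.
2. **Is it social attraction or shared habitat use?** A temporal-shift null
   model rotates each fish's trajectory by an independent whole number of
   days (0–6), preserving individual habits and time-of-day structure while
   breaking inter-individual timing. Effect sizes — interaction counts and
   average local clustering in real over shuffled data — quantify the
   social signal (1 = none). A fraction 7·(1/7)² = 1/7 of pairs draws equal
   shifts, so the effect sizes are slightly conservative.
3. **How long do social communities persist?** Monthly (28-day = 672 h)
   day/night networks are re-aggregated at window ladders of
   672, 336, 168, 84, 48, 24, 12, 6, 3 and 1 hours; each slice's network is
   reduced to its *excess* links (real minus null interaction counts,
   clamped at zero) and passed to map-equation community detection
   (Infomap). The number of communities with ≥ 3 members, traced across
   aggregation levels, peaks at the timescale on which individuals keep
   re-associating — an operational estimate of **social memory**.

Per fish and solar day the package also computes the standard behavioural
indicators, split day/night: temperature *T*, distance from shore *d*,
spatial entropy *S = −Σₘ cₘ log cₘ* (10 m grid), speed *v* and depth *h*;
per pair the mean interaction duration τ⁺, mean time between interactions
τ⁻ and interaction probability *p*.

Because raw whole-lake telemetry is rarely distributable, the package
includes a synthetic trajectory generator — a correlated random walk inside
a lake polygon with tunable social attraction toward latent groups,
memoryless group switching (the generative social-memory timescale), diel
onshore/offshore habitat bias, seasonal regimes, and bursty imperfect
detection — so the whole pipeline is testable against known ground truth.
See the methods vignette (`vignettes/shoalnet-methods.Rmd`) for the model
and every numerical convention.

## Worked example

The numbered scripts under `analysis/` run the full study on simulated
data; each writes its tables under `results/analysis/` and prints a short
summary.

```sh
Rscript analysis/01_simulate.R     # a month of telemetry, 18 fish, 6 groups
Rscript analysis/02_contacts.R     # resample, distances, contact events
Rscript analysis/03_indicators.R   # individual + dyadic indicators
Rscript analysis/04_nullmodel.R    # day-shift shuffle, effect sizes
Rscript analysis/05_timescales.R   # community persistence across ladders
```

Output of a run with the committed settings (seed 2015):

```
01: Simulated 18 fish for 29 days: 3829646 fixes (42.5% of transmitted bursts
    detected), 298 group-membership spells.
02: Grid: 167040 bins x 18 fish (53% valid). 153 pair series -> 41184 contact
    events (30524 day / 10660 night).
03: Population means over 29 solar days. Speed day 0.29 m/s vs night 0.17 m/s;
    interaction probability (pooled) 0.015.
04: Interaction-count effect sizes (real/shuffled): day 1.45, night 2.27,
    overall 1.60. Values above 1 indicate social attraction beyond shared
    habitat use.
05: Night-network community counts peak at 12 h aggregation (generative
    group-switch timescale: 48 h).
```

Reading these numbers: about 42 % of transmitted bursts are detected (the
detection model's target is 40 %) and 53 % of 15 s bins hold a usable
position; pooled interaction probability is a few per cent, as expected for
a summer-regime population of loosely cohesive groups; effect sizes of
1.5–2.3 say there are 50–130 % more contacts than habitat overlap alone
explains; and the night-network community-persistence curve peaks at the
12 h aggregation window for a generative 48 h group-switch timescale — a
deliberate illustration that the argmax estimator reads the timescale only
up to its ladder resolution: community co-membership decays at twice the
individual switching rate, so the peak sits at roughly a quarter of the
generative value (the validation suite shows exact recovery at 12 h and
one-ladder-step recovery at 168 h; see the methods vignette).

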