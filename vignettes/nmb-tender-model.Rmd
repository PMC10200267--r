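---
title: "Scoring device tenders with a three-endpoint net monetary benefit model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring device tenders with a three-endpoint net monetary benefit model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmbtender)
```

## The model

A competitive tender for a lot of comparable medical devices needs a single
score per bid that balances clinical performance against cost. The net
monetary benefit (NMB) provides one: clinical benefit is measured in
quality-adjusted survival, converted to currency at a willingness-to-pay
(WTP) threshold, and the expected costs are subtracted. The device with the
highest NMB wins. Unlike the ICER, which compares two alternatives at a
time through a nonlinear ratio, the NMB is additive and handles any number
of competitors at once.

`nmbtender` implements a deliberately simplified version of this idea,
restricted to a small set of clinical endpoints (three in the documented
profile — e.g. death, major stroke, and minor stroke for carotid stents)
and to expected values over a fixed horizon, with no state-transition
(Markov) machinery and no discounting. The per-device pipeline has eight
steps, computed in quality-adjusted life *days* (QALDs) for readability at
short horizons:

1. Fix the time horizon $H$ (months), giving $D = \mathrm{round}(365\,H/12)$
   days.
2. Baseline survival: $\mathrm{QALD}_\mathrm{base} = u_\mathrm{base} D$,
   where $u_\mathrm{base}$ is the utility in the absence of events.
3. Expected loss from events:
   $\mathrm{QALD}_\mathrm{loss} = \sum_i r_i \, \tilde d_i \, D$, where
   $r_i$ is the device's probability of endpoint $i$ within the horizon and
   $\tilde d_i = d_i t_i / H$ is the endpoint's disutility $d_i$
   time-normalized from its real duration $t_i$ (months) to the horizon.
4. Net survival: $\mathrm{QALD}_\mathrm{net} =
   \mathrm{QALD}_\mathrm{base} - \mathrm{QALD}_\mathrm{loss}$
   (QALYs = QALDs / 365).
5. Monetized benefit: $B = \mathrm{QALD}_\mathrm{net} / 365 \times W$, with
   $W$ the WTP threshold per QALY.
6. Expected cost: $C = \sum_i r_i c_i + P$, with $c_i$ the cost of managing
   one event of endpoint $i$ and $P$ the offered price.
7. $B - C$.
8. $\mathrm{NMB} = B - C$.

The time-normalization in step 3 is the model's one non-obvious move: a
utility loss of 0.50 lasting one month is equivalent, over a 12-month
horizon, to a loss of 0.25 lasting two months; both enter as an adjusted
disutility of $0.5/12 \approx 0.0417$ spread over the horizon. This is an
expected-value approximation — it assumes disutilities act additively and
ignores within-horizon timing — which is precisely what lets the model
avoid cycle-based computation.

## Parameters and their meaning

Fixed (lot-level) parameters, identical for every bid:

| parameter | units | default | notes |
|---|---|---|---|
| `horizon_months` ($H$) | months | — | analysis horizon; 12 in the worked example |
| `baseline_utility` ($u_\mathrm{base}$) | utility (0–1] | — | quality weight with no events |
| `wtp_per_qaly` ($W$) | currency/QALY | — | 60,000 euro/QALY is a common standard |
| `starting_price` | currency | — | maximum admissible bid; at-cap bids are admitted |
| `days_per_year` | days | 365 | QALD/QALY conversion |
| per endpoint: `disutility`, `duration_months`, `cost_per_event` | —, months, currency | — | duration may not exceed the horizon |

Variable (device-level) parameters: the offered `price` and one event
probability per endpoint. Rates can be entered as fractions or as the
percentages clinical reports print (`rate_unit = "percent"`); internally
they are always fractions.

The endpoint count is not hard-wired to three: 1–10 endpoints are
accepted, three being the documented profile.

## Design choices

Several points were genuinely open and are fixed here as package policy:

* **At-cap bids are admitted.** Procurement practice treats the starting
  price as a cap, so the admission test is `price <= starting_price`;
  values above it exclude the bid with a reason naming the rule. A bid
  whose rate columns do not match the lot's endpoints is a *structural*
  defect and is reported distinctly from a price exclusion.
* **The price is part of the cost (default).** With `include_price = TRUE`
  (the default), step 6 adds the offered price to the expected event
  costs, so the score responds to the bid; `include_price = FALSE` gives
  the price-exclusive variant used, e.g., as the quality component of the
  two-scale presentation.
* **Death is handled uniformly.** There is no special mortality arm; a
  "lose everything" reading is obtained by setting the death endpoint's
  disutility to the baseline utility with duration equal to the horizon.
* **Months to days.** `horizon_days = round(days_per_year *
  horizon_months / 12)`, so 12 months is exactly 365 days.
* **Negative net survival clamps to zero with a warning.** Expected losses
  exceeding the whole baseline survival indicate inputs outside the
  model's intended regime; the clamp keeps downstream monetization
  meaningful while making the situation loud.
* **Deterministic tie-breaks.** Equal NMBs rank the cheaper device first,
  then lexicographically by id. A procurement ranking must not depend on
  the order bids were opened in, and it does not.
* **Full precision inside, rounding only at the surface.** All arithmetic
  is double precision; reports render QALDs/QALYs at 4 decimals and
  currency at 2 (both overridable). Conservation (step 4 = step 2 − step 3;
  step 8 = step 5 − step 6) holds to machine precision.

## Replaying published traces

The per-endpoint disutilities and costs of the worked-example tender were
never published, and its printed disutility total (26.2625 QALDs) is not
reachable from the printed Abbott event rates with any disutilities ≤ 1 —
the maximum is about 9.42 QALDs. `compute_nmb()` therefore accepts
externally supplied step totals through its `given` argument
(`disutility_qalds`, `cost_total`); results computed this way are labelled
trace replays in every report. The packaged fixture
(`carotid_stent_fixture()`) ships the published Abbott totals as `given`
values, reconstructed-but-plausible endpoint parameters (the costs *are*
calibrated to reproduce the published 891.5365 cost total exactly), and a
sidecar provenance note separating authoritative from reconstructed
numbers. Because the true fixed parameters are unknown, the published NMBs
of the other two devices (41,118 and 40,900) cannot be independently
recomputed; they are used only as ranking inputs.

```{r replay}
fx <- carotid_stent_fixture()
res <- compute_nmb(fx$lot, fx$offers[["ABBOTT"]], given = fx$given[["ABBOTT"]])
res$step_trace[, c("step", "value", "unit")]
```

## The two-scale presentation

Many administrations require the final score split into a 0–30 price scale
and a 0–70 quality scale. The exact reparameterization conventions vary,
so `two_scale_scores()` implements a documented default: the price score
is `30 * lowest_price / price` (or, with `price_rule = "interpolated"`, a
linear map sending the starting price to 0 and the lowest bid to 30), and
the quality score is `70 * q / max(q)` with `q` the price-exclusive
monetized benefit net of event costs. The anchors are exact by
construction: the cheapest bid scores 30, the best-quality bid 70.

A fixed 30/70 weighting re-weights price against quality, so the two-scale
ordering is *not* guaranteed to reproduce the raw-NMB ordering for
arbitrary inputs. Rather than assert agreement as a theorem, the package
reports it: `two_scale_agreement()` returns both orderings and whether
they coincide, and the test suite records the agreement outcome across
seeded random tenders instead of hiding disagreements.

## The synthetic-tender generator

`generate_tender()` draws whole tenders — a lot plus offers — from
configurable ranges (`synthetic_tender_spec()`), reproducibly for a fixed
seed and without disturbing the caller's RNG stream. Defaults are chosen
to resemble a realistic high-technology device lot: 3 endpoints, 5
devices, a 12-month horizon, baseline utility 0.7–1, WTP 20,000–100,000
per QALY, event rates up to 15%, per-event costs up to 50,000, prices
100–1,000 with the starting price at the top of the range, and 5% of
offers deliberately priced above the cap so the exclusion path is
exercised. Disutilities and costs are drawn strictly positive (making the
NMB strictly monotone in every rate) and rates are rescaled, when
necessary, so expected losses stay below 90% of baseline survival — the
generator deliberately avoids the clamp-to-zero regime, which is tested
separately and directly.

What generated tenders emulate is the *arithmetic* of real tenders:
expected event rates, lot constants, and prices. They do not emulate
patient-level outcome variability, correlated endpoints, rate
uncertainty, or strategic bidding; a green property suite therefore
certifies the computational model, not the clinical realism of any
particular parameterization.

The test suite uses the generator at these sizes: roughly 1,000
lot–device instances for the brute-force oracle equivalence (relative
tolerance 1e-9), 250 tenders for the monotonicity, time-normalization,
closed-form-limit, and two-scale-bound properties, and 200 tenders (about
1,000 offers) for the domain-invariant sweep. The whole suite runs in
well under a minute on one CPU.

## Known limitations

* Expected values only: no probabilistic sensitivity analysis, no
  uncertainty intervals on the NMB.
* No discounting; appropriate for a 12-month horizon, questionable beyond
  a few years.
* Additive disutility model: simultaneous events are double-counted
  rather than combined multiplicatively; acceptable while endpoint rates
  are small.
* One lot per run; no multi-winner or framework-agreement allocation.
* The two-scale rules are a reasonable convention, not a reproduction of
  any particular administration's rulebook.
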