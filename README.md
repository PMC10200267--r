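# nmbtender

Net monetary benefit (NMB) scoring for competitive medical-device tenders.

Public buyers of high-technology devices (stents, valves, implants) need a
reproducible way to turn each bid's clinical performance and price into a
single tender score. `nmbtender` implements a simplified NMB model for
this: clinical benefit is accumulated as quality-adjusted life days
(QALDs) over a fixed horizon, monetized at a willingness-to-pay (WTP)
threshold per QALY, and the expected event costs plus the offered price
are subtracted. For device $j$ with event rates $r_{ij}$ over a lot with
endpoints $i = 1 \dots k$ (three in the documented profile):

$$
\mathrm{NMB}_j \;=\; \underbrace{\Bigl(u_\mathrm{base} - \sum_i r_{ij}\,
\frac{d_i t_i}{H}\Bigr)\frac{D}{365}\,W}_{\text{monetized benefit}}
\;-\; \underbrace{\Bigl(\sum_i r_{ij} c_i + P_j\Bigr)}_{\text{expected cost}}
$$

where $u_\mathrm{base}$ is the baseline utility, $d_i$, $t_i$, $c_i$ the
endpoint's disutility, duration (months), and cost per event, $H$ the
horizon in months, $D$ its day count, $W$ the WTP threshold, and $P_j$ the
offered price. Each disutility is time-normalized to the horizon
($d \cdot t / H$), which is what lets the model stay a closed-form sum
instead of a Markov cycle. Devices are ranked by decreasing NMB — highest
wins; an optional presentation maps results onto the administrative
0–30 price / 0–70 quality two-scale convention.

Intended users: HTA units and procurement offices scoring a lot, and
analysts studying value-based procurement rules.

## Worked example

The package ships a reconstruction of a 2021 carotid-stent tender: three
endpoints (minor stroke, major stroke, death), a 12-month horizon,
baseline utility 0.93, WTP 60,000 euro/QALY, and three bids with their
published 12-month event rates. The published step trace for the winning
device is replayed with its published intermediate totals supplied as
`given` step inputs (the tender's per-endpoint disutilities and costs
were never published; see `inst/extdata/carotid_stent_NOTES.md`):

```r
library(nmbtender)
fx <- carotid_stent_fixture()
compute_nmb(fx$lot, fx$offers[["ABBOTT"]], given = fx$given[["ABBOTT"]])
#> <device_result> ABBOTT (Abbott), price 530.00
#>   [trace replay: disutility_qalds, cost_total supplied externally]
#>   1. Selecting the time horizon: 12.0000 months
#>   2. Estimating QALDs over time horizon (at baseline utility in the absence of events): 339.4500 QALDs
#>   3. Estimating disutility in QALDs related to the endpoints: 26.2625 QALDs
#>   4. Subtracting QALDs of disutility related to the endpoints: 313.1875 QALDs
#>   5. QALDs converted into currency according to the WTP threshold: 51,482.8767 euro
#>   6. Estimating costs related to the endpoints: 891.5365 euro
#>   7. Subtracting costs related to the endpoints: 50,591.3402 euro
#>   8. NMB: 50,591.3402 euro
#>   QALYs: 0.8580
```

Reading the trace: 0.93 utility over 365 days gives 339.45 QALDs at
baseline; the expected event losses (26.2625 QALDs) leave 313.1875 QALDs
≈ 0.8580 QALYs, worth 51,482.88 euro at 60,000 euro/QALY; subtracting the
891.54 euro expected cost (events plus the 530 euro price) leaves an NMB
of about 50,591 euro — this bid's tender score.

Scoring the whole lot with the reconstructed lot parameters ranks the
three bids:

```r
summary(evaluate_tender(fx$lot, fx$offers))
#>   rank       device_id    manufacturer price      nmb
#> 1    1          ABBOTT          Abbott   530 54763.73
#> 2    2 CARDINAL_HEALTH Cardinal Health   518 52134.45
#> 3    3       MEDTRONIC       Medtronic   408 48372.77
```

Abbott wins despite the highest price: its lower event rates buy more
quality-adjusted survival than the price difference costs. The same
pipeline is available from a shell via the script installed in the
package's `exec/` directory:

```sh
CLI=$(Rscript -e 'cat(system.file("exec", "nmbtender", package = "nmbtender"))')
Rscript "$CLI" demo --out OUTDIR       # packaged example, full report bundle
Rscript "$CLI" compute --lot LOT.json --devices DEVICES.csv \
    --rate-unit percent --two-scale --out OUTDIR
```

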