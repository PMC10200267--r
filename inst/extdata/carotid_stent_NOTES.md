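# Carotid-stent worked example — provenance notes

This fixture reconstructs a 2021 Italian regional tender for carotid stents
(three endpoints: minor stroke, major stroke, death; 12-month horizon; WTP
60,000 euro/QALY) re-analysed in the technical report this example follows.

## What is authoritative

- Event rates at 12 months (printed as percentages in the source, stored as
  percent in `carotid_stent_devices.csv`): Abbott 2.35 / 0.16 / 0.07;
  Cardinal Health 1.69 / 1.04 / 0.93; third device 0.89 / 3.12 / 1.78.
- The Abbott step-trace totals in `carotid_stent_given.json`:
  disutility 26.2625 QALDs and total cost 891.5365 euro.
- The three-endpoint NMBs printed for the tender: 50,591 / 41,118 / 40,900.
- WTP threshold 60,000 euro/QALY; horizon 12 months.

## What is NOT authoritative (reconstructed)

- **Baseline utility 0.93**: back-derived from the printed baseline
  339.45 QALDs / 365 days; not printed in the source.
- **Per-endpoint disutilities, durations, and per-event costs**: never
  printed. The costs here are calibrated so that the Abbott expected event
  cost (361.5365 euro) plus the 530-euro price reproduces the printed
  step-6 total 891.5365 exactly. The disutilities/durations are plausible
  placeholders only: the printed disutility total (26.2625 QALDs) is not
  reachable from Abbott's rates with any disutilities <= 1 over 365 days
  (the maximum is about 9.42 QALDs), so the printed value is shipped as a
  *given* step input in `carotid_stent_given.json` instead of being derived.
  Consequently the Cardinal Health / Medtronic NMBs (41,118 / 40,900)
  cannot be independently recomputed from this fixture.
- **Starting price 600 euro**: chosen above all printed offers; the real
  starting price is not printed.

## Source discrepancies (recorded, not resolved)

- The third manufacturer is named "Johnson & Johnson" in the running text
  but "Medtronic" in the results table; the fixture follows the table.
- Prices: the text prints Cardinal Health 508 / Medtronic(J&J) 418; the
  results table prints 518 / 408. The fixture follows the table.
- The printed step-7 value 50,591.3436 differs from the exact subtraction
  51,482.88 - 891.5365 = 50,591.3435 by 1e-4 (intermediate rounding in the
  source).
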