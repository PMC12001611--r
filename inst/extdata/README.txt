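synthetic_monthly_its.csv

A SYNTHETIC example series generated with the package's own simulator
(its_sim_spec / simulate_its, seed 2026): 58 monthly observations (36 pre,
22 post), intervention at month 36, true immediate effect -0.25, true
gradual effect 0.001 per month, noise SD 0.1. Columns: time, outcome, post.
It mimics the shape of a monthly standardized-rate policy-evaluation series
but is not real data.

Try:
  Rscript inst/cli/segits fit --input inst/extdata/synthetic_monthly_its.csv \
    --delta 36 --output report.csv
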