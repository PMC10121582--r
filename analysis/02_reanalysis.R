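#!/usr/bin/env Rscript
# Reanalysis of the sequential-lineup identification decisions (559
# participants, one six-person lineup each) with the 2-HT model.
#
# Findings this script reproduces from the bundled table:
#   - the base model (b, dA equated across instruction conditions) fits:
#     G^2(2) = 2.42, p = 0.30; shared b = 0.00 (boundary), dA = 0.13
#   - culprit-presence detection dP does not differ significantly between
#     instruction conditions: dG^2(1) = 3.05, p = 0.081
#   - guessing-based selection g is significantly lower under
#     first-yes-counts instructions: dG^2(1) = 5.31, p = 0.021

library(lineup2ht)
dir.create("results", showWarnings = FALSE)

tab <- lineup_fixture("horry_reanalysis")
spec <- base_model_spec(rownames(tab))
fit <- fit_2ht(spec, tab)
print(fit)
write_fit_json(fit, "results/reanalysis_fit.json")

tests <- lapply(c(dP = "dP", g = "g"), function(p) {
  compare_2ht(spec, tab, p, base_fit = fit, compute_se = FALSE)
})
for (t in tests) print(t)

test_table <- data.frame(
  restriction = vapply(tests, `[[`, "", "restriction_description"),
  delta_g_squared = vapply(tests, `[[`, 0, "delta_g_squared"),
  delta_df = vapply(tests, `[[`, 0L, "delta_df"),
  p_value = vapply(tests, `[[`, 0, "p_value")
)
write.csv(test_table, "results/reanalysis_tests.csv", row.names = FALSE)
cat("written: results/reanalysis_fit.json, results/reanalysis_tests.csv\n")
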