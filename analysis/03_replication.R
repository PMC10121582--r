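#!/usr/bin/env Rscript
# Conceptual replication (355 participants, four identification decisions
# each) analysed with the same base 2-HT model as the reanalysis.
#
# Findings this script reproduces from the bundled table:
#   - the base model fits: G^2(2) = 3.09, p = 0.21; b = 0.01, dA = 0.06
#   - dP does not differ between conditions: dG^2(1) = 0.01, p = 0.94
#   - g is again significantly lower under first-yes-counts instructions,
#     now with a much larger test statistic: dG^2(1) = 21.16, p < 0.001
# Together with 02 this supports the account that first-yes-counts
# instructions reduce guessing-based selection and leave culprit-presence
# detection unaffected.

library(lineup2ht)
dir.create("results", showWarnings = FALSE)

tab <- lineup_fixture("replication")
spec <- base_model_spec(rownames(tab))
fit <- fit_2ht(spec, tab)
print(fit)
write_fit_json(fit, "results/replication_fit.json")

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
write.csv(test_table, "results/replication_tests.csv", row.names = FALSE)
cat("written: results/replication_fit.json, results/replication_tests.csv\n")
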