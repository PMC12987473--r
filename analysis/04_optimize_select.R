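#!/usr/bin/env Rscript
# NSGA-II search over the 44-point feasible design grid (spacing 30-80 cm
# by 5, four pruning methods) on the fitted surrogate, cross-checked
# against the exhaustive Pareto oracle, then equal-weight weighted-sum
# selection of one recommended configuration.
#
# Run analysis/03_fit_surrogate.R first.

library(melonopt)

model <- read_surrogate("results/surrogate_model.json")
front <- evolve(model, ga_params(seed = 2024L))
oracle <- brute_force_pareto(model)
cat("Evolved front has", nrow(front$solutions), "designs;",
    "matches the exhaustive oracle:",
    identical(front$solutions, oracle$solutions), "\n")
print(front)

decision <- weighted_sum_select(front, weights = c(1, 1, 1))
print(decision)

dir.create("results", showWarnings = FALSE)
write.csv(front$solutions, "results/pareto_front.csv", row.names = FALSE)
decision_result_json(decision, "results/decision.json")
cat("wrote results/pareto_front.csv, results/decision.json\n")
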