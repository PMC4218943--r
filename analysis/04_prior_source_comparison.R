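#!/usr/bin/env Rscript

# Phantom analogue of the matched-vs-public atlas comparison: subjects
# with post-mortem-like collapsed cerebrum/CSF contrast are segmented
# twice, once with priors from a population-matched atlas and once with
# priors from an atlas of different geometry and in-vivo-like contrast.
#
# Finding (seed 1, 5 repeats): the matched atlas wins the merged
# cerebrum+CSF region in every repeat (Dice gain ~0.01-0.03); cerebellum
# and brainstem are segmented near-perfectly under both prior sources
# because their intensity contrast survives post mortem.

library(pmbrainvol)

dir.create("results", showWarnings = FALSE)

cmp <- experiment_prior_sources(n_seeds = 5, grid = 48, seed = 1)
print(cmp, digits = 4)
write.csv(cmp, "results/prior_source_comparison.csv", row.names = FALSE)

wins <- vapply(split(cmp, cmp$seed), function(d)
  all(round(d$dice_matched, 3) >= round(d$dice_mismatched, 3)), TRUE)
cc <- cmp[cmp$class == "cerebrum_csf", ]
cat(sprintf("matched atlas wins (3-decimal precision): %d of %d repeats\n",
            sum(wins), length(wins)))
cat(sprintf("mean Dice gain on cerebrum+CSF: %.4f\n",
            mean(cc$dice_matched - cc$dice_mismatched)))
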