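#!/usr/bin/env Rscript
# Cavalieri biovolume of every simulated confocal stack, comparison with
# ground truth, and the paired OCT-vs-CLSM method correlation.

suppressPackageStartupMessages(library(biofilmq))

truth <- read.csv("data/synthetic/clsm_truth.csv")
res <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
  st <- read_clsm_tiff(file.path("data/synthetic/clsm",
                                 paste0(truth$stack[i], ".tif")))
  q <- quantify_stack(st)
  data.frame(stack = truth$stack[i], truth_um3 = truth$truth_um3[i],
             estimate_um3 = q$biovolume, threshold = q$threshold_used)
}))
res$rel_error <- res$estimate_um3 / res$truth_um3 - 1
write.csv(res, "results/clsm_biovolume.csv", row.names = FALSE)
cat(sprintf("Cavalieri biovolume on %d stacks: max |relative error| %.2g\n",
            nrow(res), max(abs(res$rel_error))))

# paired method comparison: the two modalities measured on matched carriers
oct <- read.csv("results/oct_thickness.csv")
n <- min(nrow(oct), nrow(res))
cmp <- compare_methods(oct$estimate_um[seq_len(n)],
                       res$estimate_um3[seq_len(n)])
cat(sprintf("OCT vs CLSM Pearson r = %.2f (95%% CI %.2f-%.2f; p = %.2g; n = %d)\n",
            cmp$r, cmp$ci[1], cmp$ci[2], cmp$p_value, cmp$n))
write.csv(data.frame(r = cmp$r, ci_low = cmp$ci[1], ci_high = cmp$ci[2],
                     p = cmp$p_value, n = cmp$n),
          "results/method_comparison.csv", row.names = FALSE)
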