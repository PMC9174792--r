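#!/usr/bin/env Rscript
## Phylogenetic niche conservatism on the simulated screen from
## 03_exometabolite_profiles.R: patristic vs profile distances (Mantel),
## pairwise profile correlations with Bonferroni, and the within-family
## similarity test. Run 03 first.

suppressPackageStartupMessages(library(exometab))
stopifnot(file.exists("results/profiles/fold_changes.tsv"))

fcdf <- exometab:::read_tsv("results/profiles/fold_changes.tsv")
fc <- as.matrix(fcdf[, -1])
rownames(fc) <- fcdf$metabolite
pd <- patristic_distances("results/profiles/tree.nwk")
prd <- profile_distances(fc[, rownames(pd)])

assoc <- distance_association(pd, prd, n_perm = 999, seed = 99)
cat(sprintf("Mantel: rho = %.3f, p = %.4f (%d pairs, %d permutations)\n",
            assoc$rho, assoc$p_mantel, assoc$n_pairs, assoc$n_perm))
cat(sprintf("Pairwise regression: profile distance = %.2f + %.2f x phylo distance\n",
            assoc$intercept, assoc$slope))

cors <- pairwise_profile_correlations(fc)
sig <- sum(cors$p_adj[upper.tri(cors$p_adj)] < 0.05, na.rm = TRUE)
cat(sprintf("%d/%d isolate pairs significantly correlated (Bonferroni p < 0.05)\n",
            sig, cors$n_pairs))

groups <- exometab:::read_tsv("results/profiles/groups.tsv")
gt <- group_conservatism_test(fc, setNames(groups$family, groups$isolate))
cat(sprintf(
  "Within-family vs between-family profile similarity: mean rho %.3f vs %.3f, one-sided rank-sum p = %.4g\n",
  gt$mean_within, gt$mean_between, gt$p.value))

out <- data.frame(
  statistic = c("mantel_rho", "mantel_p", "regression_slope",
                "sig_correlated_pairs", "group_test_p"),
  value = c(assoc$rho, assoc$p_mantel, assoc$slope, sig, gt$p.value))
exometab:::write_tsv(out, "results/conservatism.tsv")
cat("written results/conservatism.tsv\n")
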