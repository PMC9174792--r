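#!/usr/bin/env Rscript
## Formulate the tiered defined medium and account its elemental budget.
## Writes: results/stoichiometry.tsv, results/recipe.tsv, results/cn_ratios.tsv

suppressPackageStartupMessages(library(exometab))
dir.create("results", showWarnings = FALSE)

med <- load_fixture("nldm_medium")
cat("Medium:", med$name, "-", nrow(med$components), "metabolites in",
    length(unique(med$components$group)), "concentration tiers\n")

tab <- stoichiometry_table(med, rounded = TRUE)
print(tab)
exometab:::write_tsv(tab, "results/stoichiometry.tsv")

## C:N on every basis, since a bare "9:1" does not say which one it is.
cn <- data.frame(
  basis = c("molar", "molar", "mass", "mass"),
  includes_ammonium = c(TRUE, FALSE, TRUE, FALSE),
  cn_ratio = c(cn_ratio(med, "molar", TRUE), cn_ratio(med, "molar", FALSE),
               cn_ratio(med, "mass", TRUE), cn_ratio(med, "mass", FALSE)))
print(cn, digits = 4)
cat("-> the molar ratio including 1 mM ammonium is",
    round(cn$cn_ratio[1], 2), "i.e. ~9:1, the soil-biomass design target\n")
exometab:::write_tsv(cn, "results/cn_ratios.tsv")

r <- recipe(med)
exometab:::write_tsv(r, "results/recipe.tsv")
cat("Recipe written:", sum(r$type == "metabolite"), "metabolite lines,",
    sum(r$type == "salt"), "salts,", sum(r$type == "supplement"),
    "supplements\n")

## Inverse design demo: what base concentration would the lowest tier
## need for the whole medium to hit 1,500 mg/L organic C at the same
## 50:30:10:1 tier multipliers?
mult <- med$components$conc_uM / min(med$components$conc_uM)
base <- solve_tier_scale(as.list(med$components$formula), mult, 1500)
cat(sprintf("For 1500 mg/L organic C the 1x tier would be %.2f uM (now 17.5)\n",
            base))
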