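#!/usr/bin/env Rscript
# Interaction figures: stratified jitter-score slopes with 95% bands across
# moderator levels (the moderation phenomenon), as vector PDF.
suppressPackageStartupMessages({
  library(copdvoice)
  library(ggplot2)
})

res <- run_pipeline(run_config(seed = 20260921L),
                    spec = cohort_spec(seed = 20260921L),
                    out_dir = "results/models")
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

for (nm in names(res$moderation)) {
  md <- res$moderation[[nm]]
  md$stratum <- factor(md$stratum, levels = md$stratum)
  p <- ggplot(md, aes(stratum, estimate)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_pointrange(aes(ymin = ci_low, ymax = ci_high)) +
    labs(x = paste("stratum of", format_term <- md$moderator[1]),
         y = "stratified slope (95% CI)",
         title = gsub("|", ": ", nm, fixed = TRUE)) +
    theme_minimal()
  f <- file.path("results/figures",
                 paste0(gsub("[^a-z0-9]+", "_", tolower(nm)), ".pdf"))
  ggsave(f, p, width = 6, height = 4)
  message("wrote ", f)
}
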