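#!/usr/bin/env Rscript
# Build the amino-sugar core model in its v1-like form (with the
# gap-filled glutamine-dependent Fru6P amination) and curate it to the
# v2-like form by applying the bundled recipe: remove the GlmS reaction
# and its glutamine-recycling helper. Writes both models and the
# replayable curation log under results/models/.

library(mucimin)

dir.create("results/models", showWarnings = FALSE, recursive = TRUE)

v1 <- make_toy_model("amino_sugar_core", with_glms = TRUE)
cat("v1-like core:", length(v1$reactions), "reactions,",
    length(v1$metabolites), "metabolites\n")

recipe <- read_curation(system.file("extdata", "curation", "v1_to_v2.json",
                                    package = "mucimin"))
cur <- apply_curation(v1, recipe)
v2 <- prune_unused_metabolites(cur$model)
v2$version_tag <- "v2-like"
cat("v2-like core:", length(v2$reactions), "reactions,",
    length(v2$metabolites), "metabolites\n")

stopifnot(structurally_equal(v2, make_toy_model("amino_sugar_core")))
cat("curated model equals the directly built v2-like core\n")

# the diff of the two versions recovers the recipe
d <- diff_models(v1, make_toy_model("amino_sugar_core", with_glms = TRUE))
stopifnot(length(d) == 0)

write_model(v1, "results/models/core_v1.xml", "sbml")
write_model(v2, "results/models/core_v2.xml", "sbml")
write_model(v2, "results/models/core_v2", "table")
write_curation(recipe, "results/models/v1_to_v2.json")
cat("wrote results/models/{core_v1.xml,core_v2.xml,core_v2_*.tsv,v1_to_v2.json}\n")
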