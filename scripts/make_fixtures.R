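#!/usr/bin/env Rscript
# Regenerates the packaged plain-text fixtures under inst/extdata/.
# Run from the repository root. The cohort seed is fixed so the shipped
# files are reproducible from venom_cohort_specs().

library(intronsig)

co <- venom_cohort(seed = 20161226L)
write_cohort(co, file.path("inst", "extdata", "cohort12"))

write.table(example_module(),
            file.path("inst", "extdata", "motifs_example.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("fixtures written:",
    paste(list.files(file.path("inst", "extdata"), recursive = TRUE),
          collapse = ", "), "\n")
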