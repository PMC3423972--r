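#!/usr/bin/env Rscript

# Step 1: generate the synthetic chemogenomic screen.
#
# The screen stands in for a compound x gene-deletion fitness-defect p-value
# matrix: 20 compounds x 100 genes, background p-values Uniform(0,1), and a
# planted 4-compound / 20-gene module drawn Beta(0.05, 1) whose first member
# is the signature compound. 5% of cells are masked missing at random.
# Outputs: results/screen/matrix.tsv (the profile matrix) and
# results/screen/truth.json (the planted ground truth).

suppressMessages(library(chemoconsensus))

out_dir <- "results/screen"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

params <- sim_params(seed = 1)  # study-condition defaults
s <- simulate_chemgen(params)

write_chemgen_tsv(s$matrix, file.path(out_dir, "matrix.tsv"))
jsonlite::write_json(s$truth, file.path(out_dir, "truth.json"),
                     auto_unbox = TRUE, pretty = TRUE)

v <- s$matrix$values
cat(sprintf("simulated screen: %d compounds x %d genes, %.1f%% missing\n",
            nrow(v), ncol(v), 100 * mean(is.na(v))))
cat(sprintf("signature compound: %s\n", s$truth$signature_id))
cat(sprintf("planted module: %s over %d genes\n",
            paste(s$truth$module_compound_ids, collapse = ", "),
            length(s$truth$module_gene_ids)))
module <- v[s$truth$module_compound_ids, s$truth$module_gene_ids]
cat(sprintf("planted-block mean p = %.3f vs background mean p = %.3f\n",
            mean(module, na.rm = TRUE),
            mean(v[-(1:4), ], na.rm = TRUE)))
cat("wrote", file.path(out_dir, "matrix.tsv"), "and truth.json\n")
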