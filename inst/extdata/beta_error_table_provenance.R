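# Generates the bundled beta error table shipped as
# inst/extdata/beta_error_table.tsv. Grid and seed are fixed so the table
# is reproducible:
#   Rscript inst/extdata/beta_error_table_provenance.R path/to/out.tsv
library(ascnclone)
out <- commandArgs(trailingOnly = TRUE)[1]
tb <- build_error_table(nsnps_grid = c(10, 25, 50, 100, 200),
                        cov_grid = c(20, 50, 100, 200),
                        beta_grid = seq(0, 1, by = 0.25),
                        reps = 1000, confidence = 0.9, seed = 6106L)
write_tsv_table(tb, out)
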