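#!/usr/bin/env Rscript

# Optional integration run against a local ChEMBL Ki extract.
#
# Expects a delimited activity file (TSV with ChEMBL column names, see
# acnet::chembl_col_map()) containing Ki measurements for the targets of
# interest, e.g. CHEMBL259 (melanocortin receptor 4), CHEMBL244
# (coagulation factor X), CHEMBL237 (kappa opioid receptor). No download
# client is included: supply the extract yourself.
#
#   Rscript chembl_reproduction.R <extract.tsv> <target_id> <outdir>
#
# Prints the curated compound count, pKi range, cliff count and network
# statistics for the class, and writes all pipeline artifacts to outdir.

suppressMessages(library(acnet))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) != 3) {
  stop("usage: chembl_reproduction.R <extract.tsv> <target_id> <outdir>")
}
raw <- read_activity_records(args[1])
cur <- curate_activity_class(raw, args[2])
cat(sprintf(
  "%s: %d compounds, pKi range [%.2f, %.2f]\n",
  args[2], nrow(cur), min(cur$pki), max(cur$pki)
))
p <- run_ac_pipeline(cur, output_dir = args[3])
print(p)
if (!is.null(p$network)) print(glance(p$network))
if (!is.null(p$reduced)) print(glance(p$reduced))
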