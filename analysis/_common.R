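# Shared setup for the numbered analysis scripts: the demo study
# configuration (a down-scaled genome so every script runs in seconds) and
# file-based handoff between stages under results/analysis/.

suppressMessages(library(clonemeth))

RESULTS <- file.path("results", "analysis")
DATA <- file.path(RESULTS, "data")
dir.create(DATA, recursive = TRUE, showWarnings = FALSE)

demo_config <- function() {
  sim_config(n_cpgs = 20000, master_seed = 42L)
}

# reload the simulated study from the files written by 01_simulate.R
load_demo <- function() {
  sheet <- read_samplesheet(file.path(DATA, "samplesheet.csv"))
  recs <- lapply(sheet$sample_id, function(s)
    read_bismark_coverage(file.path(DATA, "coverage", paste0(s, ".cov.gz"))))
  names(recs) <- sheet$sample_id
  list(matrix = assemble_matrix(recs, sheet, site_policy = "union"),
       sheet = sheet,
       truth = utils::read.delim(file.path(DATA, "truth_table.tsv")),
       annotation = read_gff3(file.path(DATA, "annotation.gff3"),
                              go_map = read_go_map(file.path(DATA, "gene_go_map.tsv"))))
}

stressor_names <- c("microcystin", "temperature", "zinc", "azacytidine")
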