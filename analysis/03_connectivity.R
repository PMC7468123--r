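#!/usr/bin/env Rscript
# Stage 3: scale-4 MODWT wavelet-coherence connectivity for every retained
# subject.  Each 264-region-style panel becomes a symmetric coherence matrix
# (zero diagonal) written with a JSON sidecar of the spectral settings.
suppressPackageStartupMessages(library(mstconnect))

cfg <- read_config("results/data/config.yaml")
qc <- utils::read.csv("results/qc_report.csv")
keep <- qc$subject_id[qc$included]
dir.create("results/connectivity", showWarnings = FALSE)

for (id in keep) {
  panel <- read_panel(file.path("results/data/panels", paste0(id, ".tsv")),
                      sampling_interval = cfg$sampling_interval)
  cm <- build_connectivity_matrix(panel)
  write_matrix(cm, file.path("results/connectivity", paste0(id, ".tsv")))
}
cat(sprintf("Connectivity matrices for %d subjects (band %.3f-%.3f Hz).\n",
            length(keep), scale4_band(cfg$sampling_interval)[1],
            scale4_band(cfg$sampling_interval)[2]))
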