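#!/usr/bin/env Rscript
# Stage 2: subject-level motion exclusion.  A subject is dropped when mean
# relative RMS displacement exceeds 0.2 mm or when >= 20 frames exceed
# 0.25 mm.  Writes results/qc_report.csv.
suppressPackageStartupMessages(library(mstconnect))

meta <- read_metadata("results/data/subjects.csv")
motion <- lapply(meta$subject_id, function(id) {
  read_trace(file.path("results/data/traces", paste0(id, ".txt")))
})
names(motion) <- meta$subject_id

qc <- qc_cohort(motion)
utils::write.csv(qc, "results/qc_report.csv", row.names = FALSE)
cat(sprintf("QC: %d of %d subjects retained", sum(qc$included), nrow(qc)))
if (any(!qc$included)) {
  cat("; excluded:", paste(qc$subject_id[!qc$included], collapse = ", "))
}
cat("\n")
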