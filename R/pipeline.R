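#' Demo pipeline configuration
#'
#' A small three-group cohort (30 nodes, 10 subjects per group) that runs the
#' full pipeline in seconds; used by the analysis scripts and the determinism
#' checks.
#'
#' @param seed Integer seed.
#' @return A \code{cohort_config}.
#' @export
demo_config <- function(seed = 1L) {
  cohort_config(group_sizes = c(HC = 10L, SCZ = 10L, BD = 10L),
                n_nodes = 30L, n_samples = 600L, seed = seed)
}

#' Run the full pipeline
#'
#' Simulate (or ingest) a cohort, apply motion QC, compute wavelet-coherence
#' connectivity, extract MST metrics, and run the group-level inference.
#' All artifacts are written as plain text under \code{output_dir} together
#' with a JSON run manifest (config echo, per-stage timings, subject counts
#' before/after QC, file digests).  Identical config and seed give identical
#' numeric outputs.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param output_dir Writable output directory.
#' @param dataset Optional pre-built dataset (as returned by
#'   \code{\link{generate_cohort}} or \code{\link{ingest_external}}); when
#'   \code{NULL} the cohort is simulated from \code{config}.
#' @param conn_config \code{\link{connectivity_config}} settings.
#' @param n_perm Permutations for the nodal tests (0 disables them).
#' @param q FDR level for the global-measure family.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config, output_dir, dataset = NULL,
                         conn_config = connectivity_config(),
                         n_perm = 0L, q = 0.05) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("mstconnect")),
                   config = unclass(config), stages = list())
  tic <- function() Sys.time()
  took <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tic()
  if (is.null(dataset)) dataset <- generate_cohort(config)
  write_metadata(dataset$subjects, file.path(output_dir, "subjects.csv"))
  manifest$stages$simulate <- list(seconds = took(t0),
                                   n_subjects = nrow(dataset$subjects))

  t0 <- tic()
  qc <- qc_cohort(dataset$motion)
  utils::write.csv(qc, file.path(output_dir, "qc_report.csv"), row.names = FALSE)
  keep <- qc$subject_id[qc$included]
  manifest$stages$qc <- list(seconds = took(t0),
                             n_before = nrow(qc), n_after = length(keep),
                             excluded = qc$subject_id[!qc$included])
  if (length(keep) < 4L) stop("stage qc: fewer than 4 subjects survive motion exclusion")

  t0 <- tic()
  metrics <- list(); nodal <- list()
  mat_dir <- file.path(output_dir, "connectivity")
  dir.create(mat_dir, showWarnings = FALSE)
  for (id in keep) {
    cm <- tryCatch(build_connectivity_matrix(dataset$panels[[id]], conn_config),
                   error = function(e) stop("stage connectivity, subject ", id,
                                            ": ", conditionMessage(e)))
    write_matrix(cm, file.path(mat_dir, paste0(id, ".tsv")))
    tr <- maximum_spanning_tree(cm)
    metrics[[id]] <- cbind(subject_id = id, mst_global_metrics(tr))
    nodal[[id]] <- cbind(subject_id = id, mst_nodal_metrics(tr))
  }
  manifest$stages$connectivity <- list(seconds = took(t0))

  t0 <- tic()
  global <- do.call(rbind, metrics)
  utils::write.csv(global, file.path(output_dir, "mst_global.csv"), row.names = FALSE)
  nodal_tab <- do.call(rbind, nodal)
  utils::write.csv(nodal_tab, file.path(output_dir, "mst_nodal.csv"), row.names = FALSE)
  manifest$stages$mst <- list(seconds = took(t0))

  t0 <- tic()
  cohort <- merge(dataset$subjects, global, by = "subject_id")
  utils::write.csv(cohort, file.path(output_dir, "cohort_table.csv"), row.names = FALSE)
  measures <- c("strength", "diameter_norm", "kappa", "leaf_fraction")
  fits <- lapply(measures, function(m) fit_ancova(cohort, m))
  eff <- do.call(rbind, lapply(fits, function(f) f$effects))
  grp_rows <- eff$effect == "group"
  eff$fdr_significant <- NA
  eff$fdr_significant[grp_rows] <- bh_fdr(eff$p[grp_rows], q = q)
  utils::write.csv(eff, file.path(output_dir, "ancova_results.csv"), row.names = FALSE)
  adj <- do.call(rbind, lapply(seq_along(measures), function(i) {
    cbind(measure = measures[i], fits[[i]]$adjusted_means)
  }))
  utils::write.csv(adj, file.path(output_dir, "adjusted_means.csv"), row.names = FALSE)
  post <- do.call(rbind, lapply(measures, function(m) {
    cbind(measure = m, posthoc_pairwise(cohort, m))
  }))
  utils::write.csv(post, file.path(output_dir, "posthoc_contrasts.csv"), row.names = FALSE)

  if (n_perm >= 100L) {
    groups <- sort(unique(cohort$group))
    pairs <- utils::combn(groups, 2L, simplify = FALSE)
    nodal_res <- list()
    for (pr in pairs) {
      sel <- cohort$subject_id[cohort$group %in% pr]
      sub <- nodal_tab[nodal_tab$subject_id %in% sel, ]
      for (metric in c("degree", "betweenness")) {
        wide <- stats::reshape(sub[c("subject_id", "node_id", metric)],
                               idvar = "subject_id", timevar = "node_id",
                               direction = "wide")
        M <- as.matrix(wide[-1L])
        colnames(M) <- sub("^.*\\.", "", colnames(M))
        labs <- cohort$group[match(wide$subject_id, cohort$subject_id)]
        res <- nodal_permutation_test(M, labs, n_perm = n_perm,
                                      seed = derive_seed(config$seed, 0L, 9L))
        nodal_res[[paste(pr[1], pr[2], metric)]] <-
          cbind(contrast = paste(pr[1], "vs", pr[2]), metric = metric, res)
      }
    }
    utils::write.csv(do.call(rbind, nodal_res),
                     file.path(output_dir, "nodal_permutation.csv"),
                     row.names = FALSE)
  }
  manifest$stages$inference <- list(seconds = took(t0))

  files <- list.files(output_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$digests <- as.list(tools::md5sum(files))
  names(manifest$digests) <- substring(names(manifest$digests),
                                       nchar(output_dir) + 2L)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Ingest an externally supplied dataset
#'
#' Validates a directory of panel files, a metadata CSV and a directory of
#' motion traces against the documented formats; schema violations are
#' reported with file and position.
#'
#' @param panel_dir Directory of \code{<subject_id>.tsv} panel files.
#' @param metadata_csv Subject metadata CSV.
#' @param trace_dir Directory of \code{<subject_id>.txt} motion traces.
#' @param sampling_interval Sampling interval of the panels (s).
#' @return Dataset list (\code{subjects}, \code{panels}, \code{motion})
#'   ready for \code{\link{run_pipeline}}.
#' @export
ingest_external <- function(panel_dir, metadata_csv, trace_dir,
                            sampling_interval = 0.609) {
  subjects <- read_metadata(metadata_csv)
  need <- c("subject_id", "group", "age", "sex", "education")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  panels <- list(); motion <- list()
  n_frames <- NULL
  for (id in subjects$subject_id) {
    pf <- file.path(panel_dir, paste0(id, ".tsv"))
    if (!file.exists(pf)) stop("metadata subject ", id, " has no panel file ", pf)
    panels[[id]] <- read_panel(pf, sampling_interval)
    nf <- ncol(panels[[id]]$values)
    if (is.null(n_frames)) n_frames <- nf
    if (nf != n_frames) stop("panel ", pf, " has ", nf,
                             " frames; expected ", n_frames)
    tf <- file.path(trace_dir, paste0(id, ".txt"))
    if (!file.exists(tf)) stop("metadata subject ", id, " has no trace file ", tf)
    motion[[id]] <- read_trace(tf)
    if (length(motion[[id]]) != nf) {
      stop("trace ", tf, " has ", length(motion[[id]]),
           " frames; panel has ", nf)
    }
  }
  list(subjects = subjects, panels = panels, motion = motion)
}
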