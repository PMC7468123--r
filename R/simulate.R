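# Deterministic per-subject seed streams: a counter-based derivation from the
# top-level seed so adding a subject never perturbs the streams of others.
# Uses a splitmix-style 32-bit avalanche hash (implemented in exact double
# arithmetic) so streams derived from adjacent seeds, indices or salts are
# unrelated; a linear scheme would make stream (seed, index) collide with
# (seed', index') whenever the combination matches.  Result < 2^31 - 1.
.mix32 <- function(z) {
  xor32 <- function(a, b) {
    bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
      bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  }
  mul32 <- function(a, b) {
    ((a %% 65536) * b + ((a %/% 65536 * b) %% 65536) * 65536) %% 4294967296
  }
  z <- (z + 2654435769) %% 4294967296
  z <- xor32(z, z %/% 65536)
  z <- mul32(z, 2246822507)
  z <- xor32(z, z %/% 8192)
  z <- mul32(z, 3266489909)
  xor32(z, z %/% 65536)
}

#' Derive a child seed from a top-level seed
#'
#' Counter-based hashing of \code{(seed, index, salt)} to an integer seed
#' below \eqn{2^{31}}, so per-subject (and per-replicate) random streams are
#' mutually unrelated and stable under cohort growth.
#'
#' @param seed Top-level integer seed.
#' @param index Counter (e.g. subject or replicate number).
#' @param salt Stream discriminator within one counter value.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, index, salt = 0L) {
  z <- .mix32(as.numeric(seed) %% 4294967296)
  z <- .mix32((z + as.numeric(index)) %% 4294967296)
  z <- .mix32((z + as.numeric(salt)) %% 4294967296)
  as.integer(z %% 2147483629)
}

#' Wrap a regional time-series matrix as a panel
#'
#' @param values Numeric node-by-frame matrix (one row per region).
#' @param sampling_interval Sampling interval in seconds.
#' @param node_ids Optional region identifiers (defaults to \code{V1..Vn}).
#' @return An object of class \code{timeseries_panel}.
#' @export
as_panel <- function(values, sampling_interval = 0.609, node_ids = NULL) {
  if (inherits(values, "timeseries_panel")) return(values)
  values <- as.matrix(values)
  if (anyNA(values)) stop("panel contains missing values")
  if (sampling_interval <= 0) stop("sampling_interval must be positive")
  ids <- node_ids %||% rownames(values) %||% paste0("V", seq_len(nrow(values)))
  rownames(values) <- ids
  structure(list(node_ids = ids, values = values,
                 sampling_interval = sampling_interval),
            class = "timeseries_panel")
}

#' @export
print.timeseries_panel <- function(x, ...) {
  cat(sprintf("timeseries_panel: %d regions x %d frames @ %.3f s\n",
              nrow(x$values), ncol(x$values), x$sampling_interval))
  invisible(x)
}

#' Simulate a band-limited multivariate panel with a target coherence
#'
#' Draws latent Gaussian factors whose correlation matrix is the
#' positive-definite projection of the element-wise square root of the target
#' coherence (jointly Gaussian signals with correlation \eqn{r} have
#' magnitude-squared coherence \eqn{r^2}), band-passes them to the nominal
#' scale-4 band of the sampling interval, standardises each series, and adds
#' white measurement noise.  The realised pairwise coherence in the band
#' approximates the target in level and preserves its rank order; exact
#' matching is not attempted.
#'
#' @param template A \code{template_network} (or bare coherence matrix).
#' @param n_samples Number of frames (>= 256 for spectral estimation).
#' @param sampling_interval Seconds per frame.
#' @param noise_sd White-noise standard deviation (signals are unit-variance).
#' @param seed Integer seed; identical seeds give identical panels.
#' @return A \code{timeseries_panel}.
#' @export
simulate_panel <- function(template, n_samples = 600L,
                           sampling_interval = 0.609, noise_sd = 0.5,
                           seed = 1L) {
  if (inherits(template, "template_network")) {
    C <- template$target_coherence
  } else {
    C <- as.matrix(template)
  }
  n_samples <- as.integer(n_samples)
  if (n_samples < 256L) stop("n_samples must be >= 256 for spectral estimation")
  P <- nrow(C)
  R <- sqrt(pmin(pmax(C, 0), 1))
  diag(R) <- 1
  R <- nearest_correlation(R)
  ch <- tryCatch(chol(R), error = function(e) {
    stop("positive-definite projection did not converge: ", conditionMessage(e))
  })
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_samples * P), n_samples, P) %*% ch
  # brick-wall band-pass to the nominal scale-4 band
  fs <- 1 / sampling_interval
  band <- scale4_band(sampling_interval)
  nyq_bins <- n_samples %/% 2L
  freq <- c(0:nyq_bins, -((n_samples - nyq_bins - 1L):1)) * fs / n_samples
  keep <- abs(freq) >= band[1] & abs(freq) <= band[2]
  Zh <- stats::mvfft(Z)
  Zh[!keep, ] <- 0
  S <- Re(stats::mvfft(Zh, inverse = TRUE)) / n_samples
  S <- sweep(S, 2L, apply(S, 2L, stats::sd), "/")
  X <- S + matrix(stats::rnorm(n_samples * P, sd = noise_sd), n_samples, P)
  as_panel(t(X), sampling_interval = sampling_interval)
}

#' Simulate a per-frame head-motion trace
#'
#' Per-frame relative RMS displacements (mm): gamma-distributed frame values
#' around the requested mean plus occasional seeded spikes, so QC exclusions
#' occur at realistic rates.
#'
#' @param group Group label (recorded only; the distribution is set by
#'   \code{motion_mean}).
#' @param n_samples Number of frames.
#' @param motion_mean Target mean displacement (mm), > 0.
#' @param seed Integer seed.
#' @param spike_prob Per-frame probability of a displacement spike.
#' @return Numeric vector of nonnegative displacements, one per frame.
#' @export
simulate_motion <- function(group = "HC", n_samples = 600L, motion_mean = 0.08,
                            seed = 1L, spike_prob = 0.004) {
  if (!is.numeric(motion_mean) || motion_mean <= 0) {
    stop("motion_mean must be positive")
  }
  set.seed(seed)
  spikes <- stats::rbinom(n_samples, 1L, spike_prob) *
    stats::runif(n_samples, 0.20, 0.45)
  base_mean <- max(motion_mean - spike_prob * 0.325, motion_mean / 2)
  disp <- stats::rgamma(n_samples, shape = 4, rate = 4 / base_mean) + spikes
  disp
}

#' Cohort simulation settings
#'
#' Defaults mirror the acquisition geometry of a 600-frame, 0.609-s PRESTO
#' resting-state protocol parcellated into 264 regions; group-specific motion
#' means reflect patients moving more (0.10 mm) than controls (0.08 mm).
#'
#' @param group_sizes Named integer vector of subjects per group; names drawn
#'   from \code{HC}, \code{SCP}, \code{SCZ}, \code{BD}.
#' @param n_nodes,n_samples,sampling_interval Panel geometry.
#' @param strength_deficit Coherence deficit fraction for SCZ/SCP-like groups.
#' @param topology_flattening Flattening fraction for BD-like groups.
#' @param noise_sd Measurement-noise SD in \code{\link{simulate_panel}}.
#' @param subject_jitter_sd Between-subject coherence variability (applied as
#'   both edge-wise jitter and a shared hub-strength shift).
#' @param motion_mean Named per-group mean displacement (mm).
#' @param base_level,hub_boost,hub_count Template structure
#'   (\code{hub_count = NULL} means \code{round(n_nodes / 8)}).
#' @param seed Mandatory integer seed.
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(group_sizes = c(HC = 10L, SCZ = 10L, BD = 10L),
                          n_nodes = 264L, n_samples = 600L,
                          sampling_interval = 0.609,
                          strength_deficit = 0.15,
                          topology_flattening = 0.6,
                          noise_sd = 0.5, subject_jitter_sd = 0.06,
                          motion_mean = c(HC = 0.08, SCP = 0.08,
                                          SCZ = 0.10, BD = 0.10),
                          base_level = 0.30, hub_boost = 0.35,
                          hub_count = NULL, seed = 1L) {
  stopifnot(length(group_sizes) >= 1, all(group_sizes > 0),
            all(names(group_sizes) %in% c("HC", "SCP", "SCZ", "BD")),
            n_nodes > 1, n_samples >= 256, sampling_interval > 0,
            strength_deficit >= 0, strength_deficit < 1,
            topology_flattening >= 0, topology_flattening < 1,
            noise_sd >= 0, subject_jitter_sd >= 0,
            is.numeric(seed), length(seed) == 1L)
  hub_count <- hub_count %||% max(1L, round(n_nodes / 8))
  structure(list(group_sizes = group_sizes, n_nodes = as.integer(n_nodes),
                 n_samples = as.integer(n_samples),
                 sampling_interval = sampling_interval,
                 strength_deficit = strength_deficit,
                 topology_flattening = topology_flattening,
                 noise_sd = noise_sd, subject_jitter_sd = subject_jitter_sd,
                 motion_mean = motion_mean, base_level = base_level,
                 hub_boost = hub_boost, hub_count = as.integer(hub_count),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Group-specific demographic distributions: means loosely follow typical
# psychosis-spectrum cohorts (patients younger than bipolar, controls in
# between); they exist to exercise covariate adjustment, not to replicate any
# cohort.
.demographics <- list(
  HC  = list(age = c(40, 12), male_p = 0.50, edu = c(14.5, 2.5)),
  SCP = list(age = c(35, 10), male_p = 0.40, edu = c(14.0, 2.5)),
  SCZ = list(age = c(33, 10), male_p = 0.70, edu = c(13.0, 2.5)),
  BD  = list(age = c(47, 11), male_p = 0.45, edu = c(14.0, 2.5))
)

.draw_subject_record <- function(group, id, seed) {
  set.seed(seed)
  d <- .demographics[[group]]
  age <- max(18, round(stats::rnorm(1, d$age[1], d$age[2])))
  sex <- if (stats::runif(1) < d$male_p) "male" else "female"
  edu <- max(6, round(stats::rnorm(1, d$edu[1], d$edu[2])))
  antipsychotic <- switch(group,
    SCZ = stats::runif(1) < 0.90,
    BD  = stats::runif(1) < 0.50,
    FALSE)
  lithium <- if (group == "BD") stats::runif(1) < 0.60 else FALSE
  data.frame(subject_id = id, group = group, age = age, sex = sex,
             education = edu, antipsychotic = antipsychotic,
             lithium = lithium, stringsAsFactors = FALSE)
}

# Per-subject coherence target: shared core-periphery template with a
# subject-level hub-strength shift plus symmetric edge jitter, then the group
# effect.  The group effect precedes the positive-definite projection (done
# inside simulate_panel); for the deliberately strong hub targets this
# concentrates the strength deficit on the strong edges, preserving rank
# structure.
.subject_template <- function(config, group, seed) {
  set.seed(seed)
  hub_shift <- stats::rnorm(1, 0, config$subject_jitter_sd)
  tpl <- make_template(config$n_nodes, config$hub_count,
                       base_level = config$base_level,
                       hub_boost = max(0, config$hub_boost + hub_shift))
  C <- tpl$target_coherence
  J <- matrix(stats::rnorm(config$n_nodes^2, sd = config$subject_jitter_sd),
              config$n_nodes, config$n_nodes)
  C <- C + (J + t(J)) / 2
  C <- pmin(pmax(C, 0.01), 0.95)
  diag(C) <- 0
  tpl$target_coherence <- C
  apply_group_effect(tpl, group,
                     strength_deficit = config$strength_deficit,
                     topology_flattening = config$topology_flattening)
}

#' Generate a synthetic cohort
#'
#' One metadata record, one regional time-series panel and one motion trace
#' per subject, fully reproducible from the config seed (per-subject streams
#' are derived by a counter-based scheme, so adding subjects does not perturb
#' existing ones).
#'
#' @param config A \code{\link{cohort_config}}.
#' @return List with \code{subjects} (data frame), \code{panels} (named list
#'   of \code{timeseries_panel}) and \code{motion} (named list of traces).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- list(); panels <- list(); motion <- list()
  idx <- 0L
  for (g in names(config$group_sizes)) {
    for (i in seq_len(config$group_sizes[[g]])) {
      idx <- idx + 1L
      id <- sprintf("sub-%s%03d", g, i)
      s_meta  <- derive_seed(config$seed, idx, 1L)
      s_tpl   <- derive_seed(config$seed, idx, 2L)
      s_panel <- derive_seed(config$seed, idx, 3L)
      s_mot   <- derive_seed(config$seed, idx, 4L)
      subjects[[idx]] <- .draw_subject_record(g, id, s_meta)
      tpl <- .subject_template(config, g, s_tpl)
      panels[[id]] <- simulate_panel(tpl, n_samples = config$n_samples,
                                     sampling_interval = config$sampling_interval,
                                     noise_sd = config$noise_sd, seed = s_panel)
      mm <- config$motion_mean[[g]] %||% 0.08
      set.seed(derive_seed(config$seed, idx, 5L))
      subj_mm <- max(0.02, stats::rnorm(1, mm, 0.03))
      motion[[id]] <- simulate_motion(g, config$n_samples, subj_mm, seed = s_mot)
    }
  }
  list(subjects = do.call(rbind, subjects), panels = panels, motion = motion)
}
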