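#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Fits \code{measure ~ group + covariates} by least squares and reports, for
#' the group factor and each covariate, the drop-the-effect F test (full
#' versus effect-dropped model, the Type-III convention of mainstream
#' statistics packages), partial eta squared
#' \eqn{SS_{effect}/(SS_{effect}+SS_{error})}, and covariate-adjusted group
#' means with standard errors evaluated at the covariate means.
#'
#' @param table Data frame with one row per subject.
#' @param measure Name of the outcome column.
#' @param group_factor Name of the grouping column.
#' @param covariates Character vector of covariate columns (numeric or
#'   dichotomous); may be empty, in which case the test reduces to the
#'   classical one-way ANOVA.
#' @return An object of class \code{ancova_result}: list with \code{effects}
#'   (data frame: measure, effect, df_effect, df_error, F, p,
#'   partial_eta_sq) and \code{adjusted_means} (data frame: group, emmean,
#'   SE).
#' @export
fit_ancova <- function(table, measure, group_factor = "group",
                       covariates = c("age", "sex", "education")) {
  stopifnot(is.data.frame(table), measure %in% names(table),
            group_factor %in% names(table), all(covariates %in% names(table)))
  tab <- table
  tab[[group_factor]] <- factor(tab[[group_factor]])
  counts <- table(tab[[group_factor]])
  if (length(counts) < 2L) stop("need at least 2 groups")
  if (any(counts < 2L)) {
    stop("every group needs at least 2 subjects (offending: ",
         paste(names(counts)[counts < 2L], collapse = ", "), ")")
  }
  if (anyNA(tab[c(measure, group_factor, covariates)])) {
    stop("missing values in measure, group or covariates")
  }
  terms_all <- c(group_factor, covariates)
  full <- stats::lm(stats::reformulate(terms_all, response = measure), data = tab)
  if (anyNA(stats::coef(full))) stop("rank-deficient design (aliased coefficients)")
  ss_err <- sum(stats::residuals(full)^2)
  df_err <- full$df.residual

  eff_rows <- lapply(terms_all, function(term) {
    reduced_terms <- setdiff(terms_all, term)
    f_red <- if (length(reduced_terms) == 0L) {
      stats::lm(stats::reformulate("1", response = measure), data = tab)
    } else {
      stats::lm(stats::reformulate(reduced_terms, response = measure), data = tab)
    }
    ss_eff <- sum(stats::residuals(f_red)^2) - ss_err
    df_eff <- f_red$df.residual - df_err
    Fval <- (ss_eff / df_eff) / (ss_err / df_err)
    data.frame(measure = measure, effect = term, df_effect = df_eff,
               df_error = df_err, F = Fval,
               p = stats::pf(Fval, df_eff, df_err, lower.tail = FALSE),
               partial_eta_sq = ss_eff / (ss_eff + ss_err),
               stringsAsFactors = FALSE)
  })
  emm <- emmeans::emmeans(full, specs = group_factor, data = tab)
  es <- as.data.frame(emm)
  adjusted <- data.frame(group = es[[group_factor]], emmean = es$emmean,
                         SE = es$SE, stringsAsFactors = FALSE)
  structure(list(effects = do.call(rbind, eff_rows),
                 adjusted_means = adjusted,
                 model = full, group_factor = group_factor),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  print(x$effects, row.names = FALSE)
  cat("\nAdjusted means (at covariate means):\n")
  print(x$adjusted_means, row.names = FALSE)
  invisible(x)
}

#' Pairwise post-hoc contrasts of adjusted group means
#'
#' Model-based pairwise differences of covariate-adjusted means with their
#' standard errors from the fitted ANCOVA.  The default is the LSD convention
#' (unadjusted p values, multiplicity being handled separately by FDR
#' control); Tukey HSD adjustment is available behind \code{adjust}.
#'
#' @inheritParams fit_ancova
#' @param adjust \code{"none"} (Fisher LSD) or \code{"tukey"} (HSD).
#' @return Data frame: contrast, estimate, SE, df, t, p.
#' @export
posthoc_pairwise <- function(table, measure, group_factor = "group",
                             covariates = c("age", "sex", "education"),
                             adjust = c("none", "tukey")) {
  adjust <- match.arg(adjust)
  fit <- fit_ancova(table, measure, group_factor, covariates)
  emm <- emmeans::emmeans(fit$model, specs = group_factor, data = fit$model$model)
  pr <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = adjust))
  data.frame(contrast = pr$contrast, estimate = pr$estimate, SE = pr$SE,
             df = pr$df, t = pr$t.ratio, p = pr$p.value,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up FDR procedure: with ordered p values \eqn{p_{(1)} \le \dots \le
#' p_{(m)}}, reject hypotheses \eqn{1..k^*} where \eqn{k^*} is the largest
#' \eqn{k} with \eqn{p_{(k)} \le k q / m}.
#'
#' @param p_values Numeric vector of p values in \eqn{[0, 1]}.
#' @param q Target false discovery rate in \eqn{(0, 1)}.
#' @return Logical vector of rejection flags, in input order.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p values must lie in [0, 1]")
  }
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Max-statistic permutation test of nodal metrics
#'
#' Two-group comparison of a nodal metric (degree or betweenness) at every
#' node.  The observed statistic is the absolute difference of group means
#' per node; the null distribution is built by permuting group labels, and
#' family-wise error across nodes is controlled by the max-statistic method:
#' \deqn{p_{FWE}(v) = \frac{1 + \#\{b : \max_u |\Delta_b(u)| \ge
#'   |\Delta_{obs}(v)|\}}{n_{perm} + 1}.}
#' The add-one Monte-Carlo estimator keeps p strictly positive; the absolute
#' difference makes the test two-sided.  Labels only are permuted
#' (covariates do not enter).
#'
#' @param nodal Numeric subjects-by-nodes matrix (or data frame) of the
#'   metric.
#' @param labels Group label per subject; exactly two distinct groups.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; identical seeds give identical p values.
#' @return Data frame: node_id, observed_stat, direction, p_fwe.
#' @export
nodal_permutation_test <- function(nodal, labels, n_perm = 10000L, seed = 1L) {
  M <- as.matrix(nodal)
  labels <- as.character(labels)
  if (nrow(M) != length(labels)) stop("labels must match rows of nodal matrix")
  lev <- unique(labels)
  if (length(lev) != 2L) stop("exactly two groups are required (got ", length(lev), ")")
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) stop("n_perm must be >= 100")
  n1 <- sum(labels == lev[1]); n2 <- sum(labels == lev[2])
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 subjects")

  w_obs <- ifelse(labels == lev[1], 1 / n1, -1 / n2)
  delta_obs <- drop(crossprod(M, w_obs))
  obs <- abs(delta_obs)

  set.seed(seed)
  S <- nrow(M)
  Wp <- matrix(-1 / n2, S, n_perm)
  for (b in seq_len(n_perm)) {
    Wp[sample.int(S, n1), b] <- 1 / n1
  }
  null_max <- apply(abs(crossprod(M, Wp)), 2L, max)
  p_fwe <- vapply(obs, function(o) (1 + sum(null_max >= o)) / (n_perm + 1),
                  numeric(1))
  ids <- colnames(M) %||% as.character(seq_len(ncol(M)))
  data.frame(node_id = ids, observed_stat = obs,
             direction = ifelse(delta_obs >= 0,
                                paste(lev[1], ">", lev[2]),
                                paste(lev[1], "<", lev[2])),
             p_fwe = p_fwe, stringsAsFactors = FALSE)
}

#' Medication-stratum contrast within a diagnostic group
#'
#' Same model machinery as \code{\link{fit_ancova}}, with a dichotomous
#' medication flag (antipsychotic or lithium use) as the factor, for
#' contrasting treated and untreated strata within one diagnostic group.
#'
#' @param table Data frame restricted to one diagnostic group.
#' @param measure Outcome column name.
#' @param stratum_flag Name of the dichotomous stratum column.
#' @param covariates Covariate columns.
#' @return An \code{ancova_result} for the stratum factor.
#' @export
medication_contrast <- function(table, measure, stratum_flag = "antipsychotic",
                                covariates = c("age", "sex", "education")) {
  strata <- unique(table[[stratum_flag]])
  if (length(strata) != 2L) stop("stratum flag must take exactly two values")
  fit_ancova(table, measure, group_factor = stratum_flag,
             covariates = covariates)
}
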