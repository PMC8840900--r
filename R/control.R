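# Randomized control-group benchmark: random six-species sets replace the
# titmouse covariate, each refit is classified against the titmouse effect,
# and the classifications are summarized.

#' Draw random control groups
#'
#' Samples `n_groups` sets of `size` distinct species from the non-titmouse
#' forest-bird pool.  Species within a set are drawn without replacement;
#' the same set may recur across draws.
#'
#' @param pool character vector of candidate species codes (titmice must
#'   already be excluded).
#' @param n_groups number of groups; default 300.
#' @param size species per group; default 6.
#' @param seed integer seed; draws are reproducible given the seed.
#' @return list of character vectors, each of length `size`, with names
#'   `grp001`, `grp002`, ...
#' @export
drawControlGroups <- function(pool, n_groups = 300L, size = 6L, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  pool <- unique(as.character(pool))
  if (length(pool) < size) {
    stop("species pool (", length(pool), ") smaller than group size (",
         size, ")", call. = FALSE)
  }
  set.seed(seed)
  out <- lapply(seq_len(n_groups), function(i) sort(sample(pool, size)))
  names(out) <- sprintf("grp%03d", seq_len(n_groups))
  out
}

#' Build the response for one control group
#'
#' Rebuilds the per-sample biomass with the control-group species moved
#' from the forest-bird response into the `control` covariate, then removes
#' samples where no (remaining) forest birds were observed, so every
#' retained sample has a positive response.
#'
#' @param records filtered individual-count records.
#' @param traits species trait table.
#' @param locations point/site coordinates (see [buildSamples()]).
#' @param group character vector of control species codes (no titmice).
#' @param area sampled area (km^2).
#' @return samples data.frame as from [buildSamples()], zero-response rows
#'   removed, with attribute `n_zero_removed`.
#' @export
controlResponse <- function(records, traits, locations, group,
                            area = 0.031) {
  s <- buildSamples(records, traits, locations, area = area,
                    control_species = group)
  zero <- s$b == 0
  out <- s[!zero, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_zero_removed") <- sum(zero)
  out
}

#' Fit the linear control-group model
#'
#' The spatial Gompertz model with the control-group biomass as the only
#' indicator covariate (no quadratic term), as used when benchmarking an
#' indicator group against random species sets.
#'
#' @param samples samples with a `control` column (and `pc` if the spec
#'   includes it).
#' @param spec an [sgmSpec()] with `indicator = "control"`; defaults to the
#'   linear control spec with a productivity term when `pc` is present.
#' @param mesh optional knot mesh (reuse across groups for speed).
#' @param group_id identifier carried into the summary.
#' @param seed integer seed.
#' @param ... passed to [fitSGM()].
#' @return list of class `control_fit`: `group_id`, `gamma4`, `se`, `ci`,
#'   `converged`, `significant`, plus the full `fit` object.
#' @export
fitControl <- function(samples, spec = NULL, mesh = NULL,
                       group_id = NA_character_, seed = 1L, ...) {
  if (is.null(spec)) {
    spec <- sgmSpec(indicator = "control",
                    include_pc = "pc" %in% names(samples))
  }
  if (spec$indicator != "control" || "tit2" %in% spec$covariates) {
    stop("control fits use the linear control-covariate spec", call. = FALSE)
  }
  fit <- tryCatch(fitSGM(samples, spec = spec, mesh = mesh, seed = seed, ...),
                  error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(group_id = group_id, gamma4 = NA_real_,
                          se = NA_real_, ci = c(NA_real_, NA_real_),
                          converged = FALSE, significant = NA, fit = NULL),
                     class = "control_fit"))
  }
  j <- match("gamma_control", fit$lay$names)
  sig <- significance(fit$theta[j], fit$se_theta[j])
  structure(list(group_id = group_id, gamma4 = unname(fit$theta[j]),
                 se = unname(fit$se_theta[j]), ci = sig$ci,
                 converged = fit$converged, significant = sig$significant,
                 fit = fit),
            class = "control_fit")
}

#' Classify a control-group effect against the titmouse effect
#'
#' The zero test takes precedence: a control effect whose 95% CI encompasses
#' zero (closed interval) is `not_significant`.  Otherwise the CI is
#' compared with the titmouse point estimate: if the CI excludes it, the
#' group is `stronger` (gamma4 above gamma1) or `weaker` (below); if the CI
#' encompasses it, `not_different`.
#'
#' @param summary a `control_fit` (or any list with `gamma4`, `ci`,
#'   `converged`).
#' @param gamma1 titmouse point estimate from the linear titmouse model.
#' @return one of `"not_significant"`, `"stronger"`, `"weaker"`,
#'   `"not_different"`.
#' @export
classifyControl <- function(summary, gamma1) {
  if (!isTRUE(summary$converged)) {
    stop("cannot classify a non-converged control fit", call. = FALSE)
  }
  lo <- summary$ci[1L]; hi <- summary$ci[2L]
  if (lo <= 0 && 0 <= hi) return("not_significant")
  if (lo <= gamma1 && gamma1 <= hi) return("not_different")
  if (summary$gamma4 > gamma1) "stronger" else "weaker"
}

#' Summarize a set of control-group fits
#'
#' Counts converged, significant, stronger and weaker groups, proportions
#' among the significant fits, and location statistics of the significant
#' control effects.
#'
#' @param summaries list of `control_fit` objects (non-converged entries
#'   allowed).
#' @param gamma1 titmouse point estimate used for classification.
#' @return list of class `control_report`: `n_drawn`, `n_converged`,
#'   `n_significant`, `n_stronger`, `n_weaker`, `n_not_different`,
#'   `pct_stronger`, `pct_weaker` (percent of significant fits, 1 decimal;
#'   NA when there are none), `gamma4_mean`, `gamma4_median`, `gamma4_min`,
#'   `gamma4_max` (over significant fits), `classes` (per-group table).
#' @export
summarizeControls <- function(summaries, gamma1) {
  cls <- vapply(summaries, function(s) {
    if (!isTRUE(s$converged)) "not_converged" else classifyControl(s, gamma1)
  }, character(1))
  g4 <- vapply(summaries, function(s) s$gamma4, numeric(1))
  ids <- vapply(summaries, function(s) {
    if (is.null(s$group_id)) NA_character_ else as.character(s$group_id)
  }, character(1))
  sig <- cls %in% c("stronger", "weaker", "not_different")
  n_sig <- sum(sig)
  pct <- function(n) if (n_sig > 0) round(100 * n / n_sig, 1) else NA_real_
  qs <- if (n_sig > 0) {
    c(mean(g4[sig]), stats::median(g4[sig]), min(g4[sig]), max(g4[sig]))
  } else rep(NA_real_, 4L)
  structure(list(
    n_drawn = length(summaries),
    n_converged = sum(cls != "not_converged"),
    n_significant = n_sig,
    n_stronger = sum(cls == "stronger"),
    n_weaker = sum(cls == "weaker"),
    n_not_different = sum(cls == "not_different"),
    pct_stronger = pct(sum(cls == "stronger")),
    pct_weaker = pct(sum(cls == "weaker")),
    gamma4_mean = qs[1L], gamma4_median = qs[2L],
    gamma4_min = qs[3L], gamma4_max = qs[4L],
    gamma1 = gamma1,
    classes = data.frame(group_id = ids, gamma4 = g4, class = cls,
                         stringsAsFactors = FALSE)),
    class = "control_report")
}

#' @export
print.control_report <- function(x, ...) {
  cat("Control-group benchmark vs titmouse effect gamma1 =", x$gamma1, "\n")
  cat("  drawn:", x$n_drawn, " converged:", x$n_converged,
      " significant:", x$n_significant, "\n")
  if (x$n_significant > 0) {
    cat(sprintf("  stronger: %d (%.1f%%)  weaker: %d (%.1f%%)  not different: %d\n",
                x$n_stronger, x$pct_stronger, x$n_weaker, x$pct_weaker,
                x$n_not_different))
    cat(sprintf("  significant gamma4: mean %.3f median %.3f range [%.3f, %.3f]\n",
                x$gamma4_mean, x$gamma4_median, x$gamma4_min, x$gamma4_max))
  } else {
    cat("  no significant control fits; proportions undefined\n")
  }
  invisible(x)
}

#' Run the full control-group benchmark
#'
#' Draws control groups, rebuilds the response for each, refits the linear
#' model and summarizes the classifications against a supplied titmouse
#' point estimate.  Non-converged refits are retained in the report as
#' `not_converged`.
#'
#' @param records,traits,locations as in [controlResponse()].
#' @param gamma1 titmouse point estimate from the linear titmouse model on
#'   the full forest-bird response.
#' @param n_groups,size,seed control-group draw settings.
#' @param pc optional data.frame `site_id`, `year`, `pc` joined to each
#'   group's samples (productivity covariate).
#' @param area sampled area (km^2).
#' @param fit_control_opts list passed as `control` to [fitSGM()].
#' @return a `control_report` (see [summarizeControls()]); per-group fits
#'   are in attribute `"summaries"`.
#' @export
controlBenchmark <- function(records, traits, locations, gamma1,
                             n_groups = 300L, size = 6L, seed,
                             pc = NULL, area = 0.031,
                             fit_control_opts = list()) {
  pool <- traits$species_code[traits$is_forest & !traits$is_titmouse &
                                !traits$is_excluded_guild]
  pool <- intersect(pool, unique(records$species_code))
  groups <- drawControlGroups(pool, n_groups = n_groups, size = size,
                              seed = seed)
  summaries <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    s <- controlResponse(records, traits, locations, groups[[i]],
                         area = area)
    if (!is.null(pc)) {
      s$pc <- pc$pc[match(paste(s$site_id, s$year),
                          paste(pc$site_id, pc$year))]
    }
    summaries[[i]] <- fitControl(s, group_id = names(groups)[i],
                                 seed = seed + i,
                                 control = fit_control_opts)
    summaries[[i]]$species <- groups[[i]]
  }
  rep <- summarizeControls(summaries, gamma1)
  attr(rep, "summaries") <- summaries
  rep
}

#' Null calibration of the control-effect test
#'
#' On one simulated survey, repeatedly replaces the control covariate with
#' fresh pure noise (standard normal, independent of everything) and refits
#' the linear control model, recording how often the control effect is
#' declared significant.  With a well-calibrated Wald test the significant
#' fraction is close to the nominal 5%.
#'
#' @param sim an `sgm_sim` from [simulateObservations()].
#' @param n_draws number of noise covariates fitted; default 300.
#' @param seed integer seed.
#' @param include_pc include the productivity covariate in the fits?
#' @param fit_control_opts list passed as `control` to [fitSGM()].
#' @return list with `n_draws`, `n_converged`, `n_significant`,
#'   `frac_significant`, and the per-draw table `draws`.
#' @export
nullControlCalibration <- function(sim, n_draws = 300L, seed = 1L,
                                   include_pc = TRUE,
                                   fit_control_opts = list()) {
  spec <- sgmSpec(indicator = "control", include_pc = include_pc)
  samples <- sim$samples
  mesh <- sim$mesh
  rows <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    set.seed(seed + 7L * i)
    samples$control <- stats::rnorm(nrow(samples))
    cf <- fitControl(samples, spec = spec, mesh = mesh,
                     group_id = sprintf("noise%03d", i), seed = seed + i,
                     control = fit_control_opts)
    rows[[i]] <- data.frame(draw = i, gamma4 = cf$gamma4, se = cf$se,
                            lo = cf$ci[1L], hi = cf$ci[2L],
                            converged = cf$converged,
                            significant = isTRUE(cf$significant))
  }
  draws <- do.call(rbind, rows)
  conv <- draws$converged
  list(n_draws = n_draws, n_converged = sum(conv),
       n_significant = sum(draws$significant[conv]),
       frac_significant = mean(draws$significant[conv]),
       draws = draws)
}
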