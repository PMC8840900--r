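# Pipeline orchestration: one entry point that wires ingestion, covariates,
# fitting, model selection, the control benchmark and the simulators behind
# a structured config, writing delimited outputs plus a JSON manifest.

pipelineStages <- c("ingest", "covariates", "fit", "select", "control",
                    "simulate", "recover", "report")

# deterministic per-stage seeds derived from the one global seed
stageSeed <- function(seed, stage) {
  seed + 101L * match(stage, pipelineStages)
}

readConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop("config must set a seed", call. = FALSE)
  if (is.null(config$output)) stop("config must set output dir", call. = FALSE)
  config
}

writeTable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

writeManifest <- function(out_dir, stage, config, inputs, outputs, seed) {
  man <- list(stage = stage, seed = seed,
              inputs = if (length(inputs)) {
                as.list(tools::md5sum(inputs))
              } else list(),
              outputs = as.list(basename(outputs)),
              package_version = as.character(utils::packageVersion("indibird")))
  jsonlite::write_json(man, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

ingestFromConfig <- function(config) {
  p <- config$paths
  for (f in c("counts", "traits", "locations")) {
    if (is.null(p[[f]]) || !file.exists(p[[f]])) {
      stop("config error: missing input file for '", f, "'", call. = FALSE)
    }
  }
  mode <- if (identical(config$country_mode, "pair_counts")) {
    "pair_counts"
  } else "individual_counts"
  rec <- readPointCounts(p$counts, dialect = config$dialect %||% list(),
                         mode = mode)
  if (mode == "pair_counts") rec <- pairsToIndividuals(rec)
  rec <- mergeBreedingPeriods(rec)
  traits <- readSpeciesTraits(p$traits)
  rec <- applyGuildFilters(rec, traits)
  loc <- utils::read.csv(p$locations, stringsAsFactors = FALSE)
  list(records = rec, traits = traits, locations = loc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

specFromConfig <- function(config, indicator = "tit") {
  m <- config$model %||% list()
  sgmSpec(indicator = indicator,
          include_quadratic = isTRUE(m$quadratic %||% TRUE),
          include_pc = isTRUE(m$pc %||% FALSE),
          family = m$family %||% "gamma",
          sigma_param = m$sigma_param %||% "cv",
          n_knots = config$knots %||% NULL,
          area = config$area %||% 0.031,
          anisotropy = isTRUE(m$anisotropy %||% FALSE),
          init = m$init %||% "stationary")
}

loadSamples <- function(config, out_dir) {
  path <- file.path(out_dir, "samples.csv")
  if (!file.exists(path)) {
    stop("no samples.csv in output dir; run the ingest (or simulate) stage",
         call. = FALSE)
  }
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  pcp <- config$paths$pc %||% file.path(out_dir, "pc.csv")
  if (!("pc" %in% names(s)) && file.exists(pcp)) {
    pc <- utils::read.csv(pcp, stringsAsFactors = FALSE)
    s$pc <- pc$pc[match(paste(s$site_id, s$year), paste(pc$site_id, pc$year))]
    if (anyNA(s$pc)) {
      stop("productivity scores missing for some site-years", call. = FALSE)
    }
  }
  s
}

fitReportList <- function(fit) {
  fe <- fixedEffects(fit, betas = TRUE)
  list(spec = list(family = fit$spec$family,
                   sigma_param = fit$spec$sigma_param,
                   covariates = fit$spec$covariates,
                   area = fit$spec$area,
                   n_knots = fit$mesh$n_knots,
                   init = fit$spec$init,
                   anisotropy = fit$spec$anisotropy),
       n_samples = fit$n_samples, n_dropped_zero = fit$n_dropped,
       years = fit$years,
       estimates = fe,
       nll = fit$nll, aic = fit$aic, n_fixed = fit$n_fixed,
       converged = fit$converged, grad_rel = fit$grad_rel,
       restarts = fit$restarts, seed = fit$seed,
       data_fingerprint = as.list(fit$data_fingerprint))
}

#' Run one pipeline stage
#'
#' Orchestrates the package's stages behind a single call: `ingest` reads
#' and filters raw counts into biomass samples; `covariates` builds
#' productivity scores from annual climate; `fit` fits the spatial Gompertz
#' model; `select` compares the linear and quadratic titmouse models;
#' `control` runs the randomized control-group benchmark; `simulate` writes
#' a synthetic survey; `recover` runs a parameter-recovery experiment;
#' `report` renders parameter and response-curve tables from a stored fit.
#' Every stage writes its outputs plus a JSON manifest (inputs' checksums,
#' seed, package version) into the config's output directory.
#'
#' @param stage one of `ingest`, `covariates`, `fit`, `select`, `control`,
#'   `simulate`, `recover`, `report`.
#' @param config path to a YAML config file, or an equivalent named list.
#'   Keys: `seed`, `output`, `paths` (`counts`, `traits`, `locations`,
#'   `climate`, `pc`), `country_mode`, `area`, `knots`, `model`
#'   (`quadratic`, `pc`, `family`, `sigma_param`), `control` (`n_groups`,
#'   `size`), `trim_fraction`, `simulate` (passed to [simConfig()]),
#'   `recover` (`n_reps`).
#' @return invisibly, a list of the stage's main results.
#' @export
runPipeline <- function(stage = pipelineStages, config) {
  stage <- match.arg(stage)
  config <- readConfig(config)
  out_dir <- config$output
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- stageSeed(config$seed, stage)
  inputs <- character(0)
  outputs <- character(0)
  result <- NULL

  if (stage == "ingest") {
    ing <- ingestFromConfig(config)
    inputs <- unlist(config$paths[c("counts", "traits", "locations")])
    samples <- buildSamples(ing$records, ing$traits, ing$locations,
                            area = config$area %||% 0.031)
    tf <- config$trim_fraction %||% 0
    if (tf > 0) samples <- trimExtremes(samples, tf)
    outputs <- writeTable(samples, file.path(out_dir, "samples.csv"))
    message("ingest: ", nrow(samples), " samples from ",
            nrow(ing$records), " records")
    result <- list(samples = samples)
  } else if (stage == "covariates") {
    cpath <- config$paths$climate
    if (is.null(cpath) || !file.exists(cpath)) {
      stop("config error: missing climate table", call. = FALSE)
    }
    inputs <- cpath
    cl <- utils::read.csv(cpath, stringsAsFactors = FALSE)
    if (all(c("precip_total", "temp_mean") %in% names(cl))) {
      annual <- cl
    } else {
      # per-cell monthly rows: site_id, year, month, precip, temp
      annual <- do.call(rbind, lapply(
        split(cl, paste(cl$site_id, cl$year)), function(d) {
          pc_cells <- split(d$precip, d$month)
          tc_cells <- split(d$temp, d$month)
          if (length(pc_cells) != 12L) return(NULL)
          scr <- screenClimateCells(pc_cells, tc_cells,
                                    config$precip_range_max %||% 50,
                                    config$temp_range_max %||% 11)
          if (scr$excluded) return(NULL)
          ac <- annualClimate(scr$precip_monthly, scr$temp_monthly)
          data.frame(site_id = d$site_id[1L], year = d$year[1L],
                     precip_total = ac$precip_total, temp_mean = ac$temp_mean)
        }))
      message("covariates: ", nrow(annual), " site-years retained of ",
              length(unique(paste(cl$site_id, cl$year))))
    }
    scores <- productivityIndex(annual)
    outputs <- writeTable(scores, file.path(out_dir, "pc.csv"))
    result <- list(pc = scores)
  } else if (stage == "fit") {
    samples <- loadSamples(config, out_dir)
    spec <- specFromConfig(config)
    if (!spec$include_pc) samples$pc <- NULL
    fit <- fitSGM(samples, spec = spec, seed = seed)
    rep <- fitReportList(fit)
    jsonlite::write_json(rep, file.path(out_dir, "fit_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows")
    dg <- data.frame(knot = rep(seq_len(fit$mesh$n_knots), length(fit$years)),
                     x = fit$mesh$knots[, 1L], y = fit$mesh$knots[, 2L],
                     year = rep(fit$years, each = fit$mesh$n_knots),
                     d_hat = as.vector(fit$d_hat))
    rc <- responseCurve(fit, seed = seed)
    outputs <- c(file.path(out_dir, "fit_report.json"),
                 writeTable(dg, file.path(out_dir, "density_grid.csv")),
                 writeTable(rc, file.path(out_dir, "response_curve.csv")))
    result <- list(fit = fit)
  } else if (stage == "select") {
    samples <- loadSamples(config, out_dir)
    has_pc <- "pc" %in% names(samples) && isTRUE(config$model$pc %||% FALSE)
    m <- config$model %||% list()
    mk_spec <- function(quad) {
      sgmSpec(indicator = "tit", include_quadratic = quad,
              include_pc = has_pc, family = m$family %||% "gamma",
              sigma_param = m$sigma_param %||% "cv",
              n_knots = config$knots %||% NULL,
              area = config$area %||% 0.031)
    }
    sp_l <- mk_spec(FALSE)
    sp_q <- mk_spec(TRUE)
    if (!has_pc) samples$pc <- NULL
    fl <- fitSGM(samples, spec = sp_l, seed = seed)
    fq <- fitSGM(samples, spec = sp_q, seed = seed)
    chosen <- selectQuadratic(fl, fq)
    sel <- attr(chosen, "selection")
    out <- list(linear = fitReportList(fl), quadratic = fitReportList(fq),
                delta_aic = sel$delta_aic,
                gamma2_significant = sel$gamma2_significant,
                quadratic_chosen = sel$quadratic_chosen)
    jsonlite::write_json(out, file.path(out_dir, "selection.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows")
    outputs <- file.path(out_dir, "selection.json")
    result <- list(linear = fl, quadratic = fq, chosen = chosen)
  } else if (stage == "control") {
    ing <- ingestFromConfig(config)
    inputs <- unlist(config$paths[c("counts", "traits", "locations")])
    cc <- config$control %||% list()
    # gamma1 from the linear titmouse model on the full response
    samples <- buildSamples(ing$records, ing$traits, ing$locations,
                            area = config$area %||% 0.031)
    sp_l <- sgmSpec(indicator = "tit", include_quadratic = FALSE,
                    include_pc = FALSE,
                    family = (config$model %||% list())$family %||% "gamma",
                    n_knots = config$knots %||% NULL,
                    area = config$area %||% 0.031)
    fl <- fitSGM(samples, spec = sp_l, seed = seed)
    gamma1 <- unname(fl$theta[match("gamma_tit", fl$lay$names)])
    rep <- controlBenchmark(ing$records, ing$traits, ing$locations,
                            gamma1 = gamma1,
                            n_groups = cc$n_groups %||% 300L,
                            size = cc$size %||% 6L,
                            seed = cc$seed %||% seed,
                            area = config$area %||% 0.031)
    sm <- attr(rep, "summaries")
    tab <- data.frame(
      group_id = vapply(sm, `[[`, "", "group_id"),
      species = vapply(sm, function(s) paste(s$species, collapse = ";"), ""),
      gamma4 = vapply(sm, `[[`, 0, "gamma4"),
      se = vapply(sm, `[[`, 0, "se"),
      lo = vapply(sm, function(s) s$ci[1L], 0),
      hi = vapply(sm, function(s) s$ci[2L], 0),
      converged = vapply(sm, `[[`, TRUE, "converged"),
      class = rep$classes$class)
    outputs <- writeTable(tab, file.path(out_dir, "control_groups.csv"))
    jsonlite::write_json(unclass(rep)[setdiff(names(unclass(rep)), "classes")],
                         file.path(out_dir, "control_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    outputs <- c(outputs, file.path(out_dir, "control_summary.json"))
    print(rep)
    result <- list(report = rep, gamma1 = gamma1)
  } else if (stage == "simulate") {
    sc <- do.call(simConfig, utils::modifyList(list(seed = seed),
                                               config$simulate %||% list()))
    sim <- simulateObservations(sc)
    com <- simulateCommunity(sim)
    outputs <- c(
      writeTable(sim$samples, file.path(out_dir, "samples.csv")),
      writeTable(com$records, file.path(out_dir, "counts.csv")),
      writeTable(com$traits, file.path(out_dir, "traits.csv")),
      writeTable(com$locations, file.path(out_dir, "locations.csv")))
    truth <- sim$truth
    truth$fields <- lapply(truth$fields, function(m) round(unclass(m), 6))
    truth$d <- NULL
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, file.path(out_dir, "truth.json"))
    message("simulate: ", nrow(sim$samples), " samples, ",
            nrow(com$records), " species-count records")
    result <- list(sim = sim, community = com)
  } else if (stage == "recover") {
    rc <- config$recover %||% list()
    sc <- do.call(simConfig, utils::modifyList(list(seed = seed),
                                               config$simulate %||% list()))
    rec <- recoveryExperiment(sc, n_reps = rc$n_reps %||% 5L, seed = seed)
    outputs <- writeTable(rec$summary, file.path(out_dir, "recovery.csv"))
    print(rec)
    result <- list(recovery = rec)
  } else if (stage == "report") {
    fpath <- file.path(out_dir, "fit_report.json")
    if (!file.exists(fpath)) {
      stop("no fit_report.json in output dir; run the fit stage first",
           call. = FALSE)
    }
    rep <- jsonlite::read_json(fpath, simplifyVector = TRUE)
    est <- rep$estimates
    keep <- !grepl("^beta_", est$term)
    tab <- est[keep, c("term", "estimate", "lo", "hi", "significant")]
    outputs <- writeTable(tab, file.path(out_dir, "parameter_table.csv"))
    result <- list(parameters = tab)
  }

  writeManifest(out_dir, stage, config, inputs, outputs, seed)
  invisible(result)
}
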