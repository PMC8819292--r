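#' Run configuration
#'
#' Everything that determines a full pipeline run: the population truth, the
#' model options and the output directory.  A run is a pure function of its
#' config: rerunning with the same config gives byte-identical tables.
#'
#' @param population a [population_config()].
#' @param out_dir output directory (created if needed).
#' @param max_cells_per_participant per-cell meridian observations are
#'   subsampled (seeded) to at most this many per participant before
#'   profile fitting.
#' @param fit_symmetric also fit the symmetric profile variants and report
#'   asymmetry likelihood-ratio tests.
#' @param REML use REML for the shape model (default FALSE = ML).
#' @return List of class `run_config`.
#' @export
run_config <- function(population = population_config(),
                       out_dir = "foveatopo-run",
                       max_cells_per_participant = 300,
                       fit_symmetric = TRUE, REML = FALSE) {
  stopifnot(inherits(population, "population_config"))
  structure(list(population = population, out_dir = out_dir,
                 max_cells_per_participant = as.integer(max_cells_per_participant),
                 fit_symmetric = isTRUE(fit_symmetric), REML = isTRUE(REML)),
            class = "run_config")
}

# 32-bit FNV-1a hash of a string, as hex; used to stamp outputs with the
# config identity without any binary dependency.  The state is kept as a
# double in [0, 2^32); xor and the modular multiply are done on 16-bit
# halves to stay inside exact double/bitw ranges.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- hi * 65536 + bitwXor(as.integer(lo), as.integer(b))
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((hi * m) %% 65536) * 65536 + lo * m
    h <- h %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

config_hash <- function(config) {
  # canonicalize to 6 significant digits: stable across the YAML and JSON
  # round trips (YAML prints 6 significant digits)
  canon <- rapply(unclass_rec(config),
                  function(x) if (is.numeric(x)) signif(x, 6) else x,
                  how = "replace")
  ser <- jsonlite::toJSON(canon, auto_unbox = TRUE, digits = NA)
  fnv1a(as.character(ser))
}

unclass_rec <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_rec) else unclass(x)
}

#' Read and write run configurations
#'
#' YAML (or JSON) serialization of a [run_config()].
#'
#' @param config a `run_config`.
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- unclass_rec(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 12)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  pop <- obj$population
  run_config(
    population = population_config(
      n_participants = pop$n_participants,
      cone_profile = do.call(power_law_params, pop$cone_profile),
      rpe_profile = do.call(genexp_params, pop$rpe_profile),
      shape_model = do.call(shape_lmm_params, pop$shape_model),
      field_extent_deg = unlist(pop$field_extent_deg),
      deg_to_um = pop$deg_to_um, jitter_sd_frac = pop$jitter_sd_frac,
      thickness_noise_sd = pop$thickness_noise_sd,
      n_thickness_grid = pop$n_thickness_grid, seed = pop$seed),
    out_dir = obj$out_dir,
    max_cells_per_participant = obj$max_cells_per_participant,
    fit_symmetric = obj$fit_symmetric, REML = obj$REML)
}

fit_json <- function(fit) {
  if (inherits(fit, "density_fit")) {
    s <- summary(fit)
    list(family = fit$family, asymmetric = fit$asymmetric,
         method = fit$method,
         coefficients = cbind(term = rownames(s$coefficients),
                              s$coefficients),
         random_sd = as.list(s$random_sd),
         logLik = fit$logLik, AIC = fit$AIC, df = fit$df,
         n_obs = fit$n_obs, n_participants = fit$n_participants)
  } else {
    list(include = fit$include, REML = fit$REML,
         coefficients = cbind(term = rownames(fit$coefficients),
                              fit$coefficients),
         varcomp = as.list(fit$varcomp),
         logLik = fit$logLik, AIC = fit$AIC, df = fit$df,
         n_obs = fit$n_obs, n_participants = fit$n_participants)
  }
}

#' Run the full synthetic-study analysis pipeline
#'
#' simulate -> tessellate -> per-cell meridian extraction -> profile fits
#' (power and genexp, with AIC selection and optional asymmetry LR tests)
#' -> shape LMM with variance decomposition and RPE-term LR test ->
#' agreement statistics (Deming of log10 peak densities, Bland-Altman of
#' ROI-count versus fitted peak density, interrater ICC on simulated
#' recounts).  All tables are written as CSV and all fits as JSON into
#' `config$out_dir`, along with a run manifest recording the seed and
#' config hash.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the fitted objects and result tables.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  pop <- config$population
  message("[1/6] simulating study (", pop$n_participants, " participants)")
  study <- generate_study(pop)
  write_cell_table(unlist(lapply(study$participants,
                                 function(p) list(p$cone, p$rpe)),
                          recursive = FALSE),
                   file.path(out, "cells.csv"))
  write_thickness_table(lapply(study$participants, `[[`, "thickness"),
                        file.path(out, "thickness.csv"))
  jsonlite::write_json(lapply(study$participants, `[[`, "effects"),
                       file.path(out, "true_effects.json"),
                       auto_unbox = TRUE, digits = 12)

  message("[2/6] tessellating mosaics")
  vhw <- pop$field_extent_deg[["vertical_halfwidth"]]
  per <- lapply(study$participants, function(p) {
    cs <- mosaic_stats(p$cone)
    rs <- mosaic_stats(p$rpe)
    list(id = p$id, cone_stats = cs, rpe_stats = rs,
         cone_mer = meridian_extract(cs, vhw),
         rpe_mer = meridian_extract(rs, vhw))
  })
  stats_tab <- do.call(rbind, lapply(per, function(p) {
    rbind(cbind(participant_id = p$id, cell_type = "cone",
                as.data.frame(p$cone_stats)),
          cbind(participant_id = p$id, cell_type = "rpe",
                as.data.frame(p$rpe_stats)))
  }))
  write.csv(stats_tab, file.path(out, "cell_stats.csv"), row.names = FALSE)

  message("[3/6] fitting density profiles")
  mer_obs <- function(field) {
    do.call(rbind, lapply(seq_along(per), function(i) {
      m <- per[[i]][[field]]
      set.seed(stream_seed(pop$seed, i, salt = 71L))
      if (nrow(m) > config$max_cells_per_participant) {
        m <- m[sort(sample.int(nrow(m), config$max_cells_per_participant)), ]
      }
      cbind(participant_id = per[[i]]$id, m)
    }))
  }
  cone_obs <- mer_obs("cone_mer")
  rpe_obs <- mer_obs("rpe_mer")
  write.csv(cone_obs, file.path(out, "cone_observations.csv"),
            row.names = FALSE)
  write.csv(rpe_obs, file.path(out, "rpe_observations.csv"),
            row.names = FALSE)

  fits <- list()
  for (ct in c("cone", "rpe")) {
    obs <- if (ct == "cone") cone_obs else rpe_obs
    fits[[paste0(ct, "_power")]] <- fit_density_profile(obs, "power")
    fits[[paste0(ct, "_genexp")]] <- fit_density_profile(obs, "genexp")
    cmp <- compare_profile_models(fits[[paste0(ct, "_power")]],
                                  fits[[paste0(ct, "_genexp")]])
    write.csv(cmp, file.path(out, paste0(ct, "_model_comparison.csv")),
              row.names = FALSE)
    sel_fam <- cmp$family[which.min(cmp[[grep("^AIC", names(cmp))[1]]])]
    if (config$fit_symmetric) {
      sym <- fit_density_profile(obs, sel_fam, asymmetric = FALSE)
      lrt <- lr_test(sym, fits[[paste0(ct, "_", sel_fam)]])
      fits[[paste0(ct, "_", sel_fam, "_sym")]] <- sym
      jsonlite::write_json(
        list(family = sel_fam, chisq = lrt$statistic, df = lrt$df,
             p = lrt$p.value),
        file.path(out, paste0(ct, "_asymmetry_lr.json")),
        auto_unbox = TRUE, digits = 8)
    }
  }
  for (nm in names(fits)) {
    jsonlite::write_json(fit_json(fits[[nm]]),
                         file.path(out, paste0("fit_", nm, ".json")),
                         auto_unbox = TRUE, digits = 10)
  }

  message("[4/6] fitting foveal shape model")
  max_ecc <- min(5, pop$field_extent_deg[["nasal_max"]],
                 pop$field_extent_deg[["temporal_max"]])
  shape_obs <- do.call(rbind, lapply(seq_along(per), function(i) {
    build_shape_observations(per[[i]]$cone_stats, per[[i]]$rpe_stats,
                             study$participants[[i]]$thickness,
                             max_ecc_deg = max_ecc,
                             vertical_halfwidth_deg = vhw)
  }))
  write.csv(shape_obs, file.path(out, "shape_observations.csv"),
            row.names = FALSE)
  shape_fit <- fit_foveal_shape(shape_obs, REML = config$REML)
  decomp <- variance_decomposition(shape_fit)
  shape_nc <- fit_foveal_shape(shape_obs, REML = config$REML,
                               include = "cone")
  lrt_rpe <- lr_test(shape_nc, shape_fit)
  jsonlite::write_json(
    c(fit_json(shape_fit),
      list(variance_shares_pct = as.list(round(decomp$shares, 4)),
           rpe_term_lr = list(chisq = lrt_rpe$statistic, df = lrt_rpe$df,
                              p = lrt_rpe$p.value))),
    file.path(out, "fit_shape.json"), auto_unbox = TRUE, digits = 10)

  message("[5/6] agreement statistics")
  roi_cone <- vapply(per, function(p) {
    roi_density(p$cone_stats, roi_spec(c(0, 0), "square", 50, "bounded"))$density_mm2
  }, numeric(1))
  roi_rpe <- vapply(per, function(p) {
    roi_density(p$rpe_stats, roi_spec(c(0, 0), "square", 200, "bounded"))$density_mm2
  }, numeric(1))
  peak_cone <- peak_density(fits$cone_power)
  peak_rpe <- peak_density(fits$rpe_genexp)
  agr <- list(
    deming_log10_peaks = unclass(deming_fit(log10(peak_cone),
                                            log10(peak_rpe), nboot = 2000,
                                            seed = pop$seed)),
    bland_altman_cone_roi_vs_fit = unclass(bland_altman(roi_cone, peak_cone)),
    bland_altman_rpe_roi_vs_fit = unclass(bland_altman(roi_rpe, peak_rpe))
  )
  rpe_counts <- vapply(per, function(p) {
    roi_density(p$rpe_stats, roi_spec(c(0, 0), "square", 200, "bounded"))$count
  }, numeric(1))
  if (length(rpe_counts) >= 5) {
    raters <- generate_rater_pair(rpe_counts,
                                  rater_sd = max(1, 0.02 * mean(rpe_counts)),
                                  seed = stream_seed(pop$seed, salt = 83L))
    agr$interrater_icc <- unclass(icc_oneway(cbind(raters$rater1,
                                                   raters$rater2)))
  } else {
    agr$interrater_icc <- "skipped: fewer than 5 rated locations"
  }
  jsonlite::write_json(agr, file.path(out, "agreement.json"),
                       auto_unbox = TRUE, digits = 10)

  message("[6/6] writing manifest")
  manifest <- list(seed = pop$seed, config_hash = config_hash(config),
                   n_participants = pop$n_participants,
                   outputs = sort(list.files(out)))
  jsonlite::write_json(manifest, file.path(out, "run.json"),
                       auto_unbox = TRUE)
  write_run_config(config, file.path(out, "config.yaml"))

  invisible(list(study = study, profile_fits = fits, shape_fit = shape_fit,
                 decomposition = decomp, agreement = agr,
                 manifest = manifest))
}
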