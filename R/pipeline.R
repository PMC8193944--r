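#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()]:
#' per-stage seeds, generator preset names, detection parameters, the
#' quantal failure criterion, Hill-fit constraints, calibration constants,
#' and circadian options. Configurations can also be loaded from YAML; keys
#' not present in the default are rejected.
#'
#' @param path Optional YAML file whose entries override the defaults.
#' @return A named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(path = NULL) {
  cfg <- list(
    seed = 1L,
    n_cells = 6L,                  # paired cells per age group
    spont_duration_s = 30,         # per-cell trace length in the pipeline
    spont_sample_rate_hz = 5000,
    detection = list(amp_threshold_pa = 15, deriv_threshold_pa_per_ms = 8,
                     refractory_ms = 10, baseline_window_ms = 10),
    failure_k = 3,
    quantal_n_stim = 75L,
    hill = list(emax_fixed = 100, free_emax = FALSE),
    calibration = list(r_min = 0.3, r_max = 6, kd_nm = 224, beta = 5),
    circadian = list(fraction = 0.10, peak_scope = "day",
                     min_daily_revs = 50,
                     n_animals = c(young_wt = 6L, young_vgat = 6L,
                                   aged_wt = 10L, aged_vgat = 10L))
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop_invalid("unknown configuration key(s): ",
                   paste(unknown, collapse = ", "))
    for (k in names(user)) {
      if (is.list(cfg[[k]])) {
        unknown2 <- setdiff(names(user[[k]]), names(cfg[[k]]))
        if (length(unknown2))
          stop_invalid("unknown configuration key(s) under '", k, "': ",
                       paste(unknown2, collapse = ", "))
        cfg[[k]][names(user[[k]])] <- user[[k]]
      } else cfg[[k]] <- user[[k]]
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(cfg), tmp, version = 2)
  unname(tools::md5sum(tmp))
}

derive_seed <- function(seed, k) (seed * 10007L + k) %% .Machine$integer.max

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages simulate-and-detect, quantal, dose-fit, fura and
#' circadian on generator presets, writing one CSV/JSON table per stage plus
#' a run manifest sufficient to reproduce any stage. With an empty stage
#' vector only the manifest is written. All randomness derives from
#' \code{config$seed}; a fixed configuration therefore reproduces every
#' output file byte-for-byte (timestamps live only in the manifest).
#'
#' @param config A [pipeline_config()] (or a YAML path).
#' @param stages Character subset of
#'   \code{c("detect", "quantal", "dose_fit", "fura", "circadian", "anova")}.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly: stages run, file paths, config hash,
#'   seeds, package version, timestamps.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("detect", "quantal", "dose_fit", "fura",
                                    "circadian", "anova"),
                         out_dir = "synphys_out") {
  if (is.character(config)) config <- pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  known <- c("detect", "quantal", "dose_fit", "fura", "circadian", "anova")
  if (length(stages) && !all(stages %in% known))
    stop_invalid("unknown stage(s): ",
                 paste(setdiff(stages, known), collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("synphys")),
                   config_hash = config_hash(config), seed = config$seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list())
  det_par <- do.call(detection_params, config$detection)
  outfile <- function(name) file.path(out_dir, name)
  completed <- character(0)

  run_stage <- function(name, fun) {
    files <- fun()
    manifest$stages[[name]] <<- list(outputs = files,
                                     seed = derive_seed(config$seed, match(name, known)))
    completed <<- c(completed, name)
  }

  result <- tryCatch({
    if ("detect" %in% stages) run_stage("detect", function() {
      s0 <- derive_seed(config$seed, 1L)
      rows <- list()
      for (age in c("young", "aged")) {
        ctrl <- synth_preset(paste0(age, "_control"))
        ami <- synth_preset(paste0(age, "_ami"))
        for (cell in seq_len(config$n_cells)) {
          stat <- lapply(list(control = ctrl, drug = ami), function(pr) {
            p <- pr$spontaneous
            p$duration_s <- config$spont_duration_s
            p$sample_rate_hz <- config$spont_sample_rate_hz
            p$seed <- derive_seed(s0, cell * 17L +
                                    (age == "aged") * 7919L +
                                    identical(pr, ami) * 104729L)
            ev <- detect_events(simulate_spontaneous(p, pr$effect)$trace,
                                det_par)
            event_statistics(ev)
          })
          rows[[length(rows) + 1]] <- data.frame(
            age = age, cell = cell,
            control_freq_hz = stat$control$frequency_hz,
            drug_freq_hz = stat$drug$frequency_hz,
            control_amp_pa = stat$control$mean_amp_pa,
            drug_amp_pa = stat$drug$mean_amp_pa)
        }
      }
      tab <- do.call(rbind, rows)
      utils::write.csv(tab, outfile("sipsc_per_cell.csv"), row.names = FALSE)
      fold <- do.call(rbind, lapply(split(tab, tab$age), function(d) {
        fr <- normalized_fold_change(data.frame(control_value = d$control_freq_hz,
                                                drug_value = d$drug_freq_hz))
        data.frame(age = d$age[1], fold_freq = fr$mean_ratio,
                   fold_freq_sem = fr$sem_ratio, n = fr$n)
      }))
      utils::write.csv(fold, outfile("sipsc_fold_change.csv"),
                       row.names = FALSE)
      c(outfile("sipsc_per_cell.csv"), outfile("sipsc_fold_change.csv"))
    })

    if ("quantal" %in% stages) run_stage("quantal", function() {
      s0 <- derive_seed(config$seed, 2L)
      rows <- list()
      for (age in c("young", "aged")) for (cond in c("control", "ami")) {
        pr <- synth_preset(paste0(age, "_", cond))
        p <- pr$quantal
        p$n_stim <- config$quantal_n_stim
        p$seed <- derive_seed(s0, (age == "aged") * 2L + (cond == "ami") + 1L)
        tr <- classify_failures(simulate_evoked(p, pr$effect),
                                noise_sd_pa = p$noise_sd_pa,
                                k = config$failure_k)
        qc <- quantal_content(tr)
        ma <- mean_amplitude_excluding_failures(tr)
        rows[[length(rows) + 1]] <- data.frame(
          age = age, condition = cond, n_stim = qc$n_stim,
          n_failures = qc$n_failures, m = qc$m, se_m = qc$se_m,
          mean_amp_excl_failures_pa = ma$mean_pa)
      }
      tab <- do.call(rbind, rows)
      utils::write.csv(tab, outfile("quantal_summary.csv"), row.names = FALSE)
      outfile("quantal_summary.csv")
    })

    if ("dose_fit" %in% stages) run_stage("dose_fit", function() {
      fit <- fit_hill(ami_dose_response(),
                      emax_fixed = config$hill$emax_fixed,
                      free_emax = config$hill$free_emax)
      jsonlite::write_json(list(ec50_um = fit$ec50_um, hill_h = fit$hill_h,
                                emax_pct = fit$emax_pct, sse = fit$sse,
                                converged = fit$converged),
                           outfile("hill_fit.json"), auto_unbox = TRUE,
                           digits = NA)
      outfile("hill_fit.json")
    })

    if ("fura" %in% stages) run_stage("fura", function() {
      s0 <- derive_seed(config$seed, 4L)
      calib <- do.call(calibration_constants, config$calibration)
      deltas <- lapply(c(control = "young_control", drug = "young_ami"),
                       function(nm) {
        pr <- synth_preset(nm)
        unlist(lapply(1:4, function(cell) {
          p <- pr$fura
          p$calib <- calib
          p$stim_times_s <- c(15, 40)
          p$seed <- derive_seed(s0, cell + (nm == "young_ami") * 1000L)
          sim <- simulate_fura(p, pr$effect)
          mean(transient_amplitudes(sim$trace, p$stim_times_s))
        }))
      })
      summ <- inhibition_summary(deltas$control, deltas$drug)
      utils::write.csv(data.frame(
        mean_control_nm = summ$mean_control, sem_control = summ$sem_control,
        mean_drug_nm = summ$mean_drug, sem_drug = summ$sem_drug,
        pct_inhibition = summ$pct_inhibition,
        t = summ$t_test$t, p = summ$t_test$p),
        outfile("fura_inhibition.csv"), row.names = FALSE)
      outfile("fura_inhibition.csv")
    })

    if ("circadian" %in% stages) run_stage("circadian", function() {
      s0 <- derive_seed(config$seed, 5L)
      cc <- config$circadian
      rows <- list()
      for (grp in names(cc$n_animals)) {
        pr <- synth_preset(grp)
        for (a in seq_len(cc$n_animals[[grp]])) {
          p <- pr$actogram
          p$seed <- derive_seed(s0, match(grp, names(cc$n_animals)) * 101L + a)
          sim <- simulate_actogram(p, animal_id = sprintf("%s_%02d", grp, a))
          es <- entrainment_summary(sim$actogram, fraction = cc$fraction,
                                    peak_scope = cc$peak_scope,
                                    min_daily_revs = cc$min_daily_revs)
          rows[[length(rows) + 1]] <- data.frame(
            group = grp, animal = a, psi_min = es$psi_min,
            onset_variability_min = es$onset_variability_min,
            total_daily_activity = es$total_daily_activity,
            n_days_used = es$n_days_used)
        }
      }
      tab <- do.call(rbind, rows)
      utils::write.csv(tab, outfile("circadian_per_animal.csv"),
                       row.names = FALSE)
      outfile("circadian_per_animal.csv")
    })

    if ("anova" %in% stages) run_stage("anova", function() {
      tabs <- lapply(c("daily_activity", "phase_angle", "onset_variability"),
                     function(ms) {
        a <- anova2_from_summary(wheel_running_summary(ms))
        cbind(measure = ms, as.data.frame(a))
      })
      utils::write.csv(do.call(rbind, tabs), outfile("anova_summary.csv"),
                       row.names = FALSE)
      outfile("anova_summary.csv")
    })
    NULL
  }, error = function(e) e)

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$completed_stages <- completed
  manifest$failed <- if (inherits(result, "error")) conditionMessage(result)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (inherits(result, "error"))
    stop("pipeline halted after stages [", paste(completed, collapse = ", "),
         "]: ", conditionMessage(result))
  invisible(manifest)
}

#' Write the fixture file set
#'
#' Writes one small, versioned example file for every reader in the
#' package: a simulated current trace, an evoked trial table, an actogram,
#' a fura ratio trace, the published concentration-inhibition table and the
#' published wheel-running 2x2 summaries. Regeneration under the same seed
#' is byte-identical.
#'
#' @param out_dir Writable directory (created if needed).
#' @param seed Integer seed for the simulated fixtures.
#' @return Character vector of paths written, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  add <- function(p) paths <<- c(paths, p)

  sim <- simulate_spontaneous(
    spontaneous_params(duration_s = 5, sample_rate_hz = 2000,
                       seed = derive_seed(seed, 1L)), cell_id = "fixture_cell")
  add(write_trace_csv(sim$trace, file.path(out_dir, "trace.csv")))
  add(write_events_csv(sim$truth, file.path(out_dir, "events.csv")))

  tr <- simulate_evoked(quantal_params(m_true = 1, n_stim = 50,
                                       seed = derive_seed(seed, 2L)),
                        cell_id = "fixture_cell")
  tr <- classify_failures(tr, noise_sd_pa = 3)
  add(write_trials_csv(tr, file.path(out_dir, "trials.csv")))

  act <- simulate_actogram(actogram_params(n_days = 10,
                                           seed = derive_seed(seed, 3L)),
                           animal_id = "fixture_animal")$actogram
  add(write_actogram_csv(act, file.path(out_dir, "actogram.csv")))

  fu <- simulate_fura(fura_sim_params(duration_s = 30, stim_times_s = 10,
                                      seed = derive_seed(seed, 4L)),
                      cell_id = "fixture_cell")
  add(write_fura_csv(fu$trace, file.path(out_dir, "fura.csv")))

  for (f in c("ami_calcium_doseresponse.csv", "wheel_running_summaries.csv")) {
    file.copy(system.file("extdata", f, package = "synphys"),
              file.path(out_dir, f), overwrite = TRUE)
    add(file.path(out_dir, f))
  }
  invisible(paths)
}
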