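#' Default run configurations
#'
#' `"paper_faithful"` pins the full-scale analysis: 25 participants, 20
#' melody presentations (250 omission trials per condition), threefold
#' cross-validation repeated 20 times at every sample of -200..300 ms.
#' `"paper_faithful_small"` keeps every methodological choice but runs at
#' desk scale: 8 participants, decoding every 10 ms with 5 iterations, and
#' 500 cluster permutations.
#'
#' @param preset preset name.
#' @param seed master seed.
#' @return nested configuration list (class `run_config`).
#' @export
default_run_config <- function(preset = c("paper_faithful_small",
                                          "paper_faithful"),
                               seed = 1L) {
  preset <- match.arg(preset)
  small <- preset == "paper_faithful_small"
  structure(list(
    seed = as.integer(seed),
    design = list(presentations_per_melody = 20, omission_rate = 0.5),
    simulation = list(n_participants = if (small) 8 else 25),
    preprocess = list(),
    decode = list(n_iterations = if (small) 5 else 20,
                  decimation_ms = if (small) 10 else 1),
    stats = list(n_permutations = if (small) 500 else 10000,
                 cluster_alpha = 0.05,
                 on1_search = c(50, 110), on1_half_width = 10,
                 chance = 0.25, power_dz = 0.66,
                 power_alpha = 0.05, power_target = 0.80),
    run_decoding = TRUE,
    preset = preset), class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' JSON is always supported; YAML requires the `yaml` package.
#'
#' @param path config file.
#' @return `run_config` list merged over [default_run_config()] defaults.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the yaml package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
  base <- default_run_config(
    preset = if (!is.null(raw$preset)) raw$preset else "paper_faithful_small",
    seed = if (!is.null(raw$seed)) raw$seed else 1L)
  modifyList(base, raw[setdiff(names(raw), "preset")])
}

#' Validate a run configuration
#'
#' Instantiates every module configuration so section errors surface before
#' any computation.
#'
#' @param config a `run_config`.
#' @return list of instantiated module configs (invisibly usable).
#' @export
validate_run_config <- function(config) {
  sim <- do.call(simulation_config,
                 c(config$simulation, list(seed = config$seed)))
  pre <- do.call(preprocess_config, config$preprocess)
  dec <- do.call(decode_config, config$decode)
  stopifnot(config$stats$n_permutations >= 1,
            config$stats$chance > 0, config$stats$chance < 1)
  list(simulation = sim, preprocess = pre, decode = dec, stats = config$stats)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_table_with_header <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ospdecode %s config_hash=%s seed=%d",
                     as.character(utils::packageVersion("ospdecode")),
                     hash, seed), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes design -> simulate -> preprocess -> ERP measurement -> decoding
#' -> statistics for a configuration, writing every table with a provenance
#' header (package version, config hash, master seed). Deterministic and
#' idempotent for a fixed seed. Any stage error aborts with the stage name.
#'
#' @param config a `run_config` (list or path to YAML/JSON).
#' @param out_dir writable output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return A `run_report`: paths of all outputs plus the summary statistics.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir, quiet = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  cfgs <- tryCatch(validate_run_config(config),
                   error = function(e) stop("config error: ",
                                            conditionMessage(e), call. = FALSE))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))

  set.seed(config$seed)
  aux_seeds <- sample.int(.Machine$integer.max - 1L, 3L)
  n_part <- cfgs$simulation$n_participants
  decode_seeds <- sample.int(.Machine$integer.max - 1L, n_part)

  say("design")
  schedule <- stage("design", do.call(build_schedule,
    c(list(melody_specs = default_melody_specs(), seed = aux_seeds[1]),
      config$design)))
  paths <- list(schedule = file.path(out_dir, "schedule.csv"))
  write_schedule(schedule, paths$schedule)
  scheduled_counts <- with(as.data.frame(schedule),
                           table(note[omitted], condition[omitted]))

  say("simulate + preprocess + measure (%d participants)", n_part)
  sim <- cfgs$simulation
  set.seed(aux_seeds[3])
  amps <- draw_participant_amplitudes(n_part, sim)
  part_seeds <- sample.int(.Machine$integer.max - 1L, n_part)
  conditions <- c("familiar", "unfamiliar")

  erps <- list(familiar = list(), unfamiliar = list())
  roi_series <- list(familiar = list(), unfamiliar = list())
  acc_series <- list(familiar = list(), unfamiliar = list())
  included <- logical(n_part)
  n_used <- matrix(0L, n_part, 2, dimnames = list(NULL, conditions))
  truths <- vector("list", n_part)

  for (i in seq_len(n_part)) {
    id <- sprintf("P%02d", i)
    res <- stage("simulate", simulate_participant(
      schedule, sim, participant_seed = part_seeds[i], participant_id = id,
      on1_amplitude = amps[i, ]))
    truths[[i]] <- res$truth
    ok <- TRUE
    clean <- list()
    for (cond in conditions) {
      es <- stage("preprocess", preprocess_epochs(res$epochs[[cond]],
                                                  cfgs$preprocess))
      clean[[cond]] <- es
      ret <- table(factor(es$labels[es$retained], levels = note_levels()))
      sch <- scheduled_counts[note_levels(), cond]
      gate <- check_inclusion(stats::setNames(as.integer(ret), note_levels()),
                              stats::setNames(as.integer(sch), note_levels()),
                              cfgs$preprocess)
      ok <- ok && gate$included
      erp <- stage("erp", average_epochs(es))
      erps[[cond]][[i]] <- erp
      roi_series[[cond]][[i]] <- roi_mean(erp, cfgs$preprocess$roi)
      n_used[i, cond] <- sum(es$retained)
    }
    included[i] <- ok
    if (config$run_decoding && ok) {
      dcfg <- cfgs$decode
      dcfg$seed <- decode_seeds[i]
      for (cond in conditions)
        acc_series[[cond]][[i]] <- stage("decode",
          decode_timecourse(clean[[cond]], dcfg))
    }
    say("  %s done (included=%s)", id, ok)
  }

  say("erp window + amplitudes")
  gm <- lapply(conditions, function(cond)
    roi_mean(grand_average(erps[[cond]]), cfgs$preprocess$roi))
  names(gm) <- conditions
  win <- stage("erp", define_on1_window(gm$familiar, gm$unfamiliar,
                                        search = config$stats$on1_search,
                                        half_width = config$stats$on1_half_width))
  amp_tab <- do.call(rbind, lapply(seq_len(n_part), function(i)
    data.frame(participant = sprintf("P%02d", i),
               condition = conditions,
               n_epochs = n_used[i, ],
               amplitude_uV = vapply(conditions, function(cond)
                 mean_amplitude(roi_series[[cond]][[i]], win), 0),
               included_decoding = included[i])))
  paths$amplitudes <- file.path(out_dir, "amplitudes.csv")
  write_table_with_header(amp_tab, paths$amplitudes, hash, config$seed)
  for (cond in conditions) {
    p <- file.path(out_dir, sprintf("grand_average_%s.csv", cond))
    write_table_with_header(
      data.frame(time_ms = gm[[cond]]$time, amplitude_uV = gm[[cond]]$value),
      p, hash, config$seed)
    paths[[paste0("grand_", cond)]] <- p
  }

  say("stats")
  wide <- reshape_amp(amp_tab)
  tt <- stage("stats", paired_t_dz(wide$familiar, wide$unfamiliar))
  bf <- stage("stats", jzs_bf10(tt$t, tt$n))
  pw <- stage("stats", power_sample_size(config$stats$power_dz,
                                         config$stats$power_alpha,
                                         config$stats$power_target))

  decoding_report <- NULL
  if (config$run_decoding && sum(included) >= 2) {
    idx <- which(included)
    acc_mat <- lapply(conditions, function(cond)
      do.call(rbind, lapply(idx, function(i) acc_series[[cond]][[i]]$accuracy)))
    names(acc_mat) <- conditions
    t_axis <- acc_series$familiar[[idx[1]]]$time
    acc_tab <- do.call(rbind, lapply(idx, function(i)
      do.call(rbind, lapply(conditions, function(cond)
        data.frame(participant = sprintf("P%02d", i), condition = cond,
                   time_ms = acc_series[[cond]][[i]]$time,
                   accuracy = acc_series[[cond]][[i]]$accuracy)))))
    paths$accuracy <- file.path(out_dir, "accuracy.csv")
    write_table_with_header(acc_tab, paths$accuracy, hash, config$seed)
    cl <- stage("stats", cluster_permutation(
      acc_mat$familiar, acc_mat$unfamiliar, time = t_axis,
      n_permutations = config$stats$n_permutations,
      cluster_alpha = config$stats$cluster_alpha, seed = aux_seeds[2]))
    sig <- cl$clusters[cl$clusters$p_perm < config$stats$cluster_alpha, ,
                       drop = FALSE]
    win_tests <- NULL
    if (nrow(sig)) {
      best <- sig[which.max(abs(sig$t_sum)), ]
      wacc <- lapply(conditions, function(cond)
        apply(acc_mat[[cond]][, t_axis >= best$start_ms &
                                 t_axis <= best$end_ms, drop = FALSE], 1, mean))
      names(wacc) <- conditions
      win_tests <- lapply(conditions, function(cond) {
        t1 <- one_sample_t_dz(wacc[[cond]], mu = config$stats$chance)
        b1 <- jzs_bf10(t1$t, t1$n)
        list(condition = cond, mean = mean(wacc[[cond]]),
             sd = sd(wacc[[cond]]), t = t1$t, df = t1$df, p = t1$p,
             dz = t1$dz, bf10 = b1$bf10)
      })
      names(win_tests) <- conditions
    }
    decoding_report <- list(n_included = length(idx),
                            clusters = cl$clusters,
                            threshold = cl$threshold,
                            n_permutations = cl$n_permutations,
                            window_tests = win_tests)
  }

  report <- list(
    package_version = as.character(utils::packageVersion("ospdecode")),
    config_hash = hash, seed = config$seed, preset = config$preset,
    on1 = list(window = unclass(win)[c("lo", "hi", "peak_latency")],
               mean = vapply(conditions, function(cond)
                 mean(wide[[cond]]), 0),
               sd = vapply(conditions, function(cond) sd(wide[[cond]]), 0),
               t = tt$t, df = tt$df, p = tt$p, dz = tt$dz, bf10 = bf$bf10),
    decoding = decoding_report,
    power = list(n_required = pw$n_required, dz = pw$dz,
                 alpha = pw$alpha, power = pw$power),
    included = included)
  paths$stat_report <- file.path(out_dir, "stat_report.json")
  jsonlite::write_json(report, paths$stat_report, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths$run_info <- file.path(out_dir, "run_info.json")
  jsonlite::write_json(list(config = unclass(config), config_hash = hash,
                            seeds = list(master = config$seed,
                                         design = aux_seeds[1],
                                         cluster = aux_seeds[2],
                                         participants = part_seeds,
                                         decode = decode_seeds)),
                       paths$run_info, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  structure(list(paths = paths, report = report,
                 truth = list(amplitudes = amps, participant = truths)),
            class = "run_report")
}

reshape_amp <- function(amp_tab) {
  list(familiar = amp_tab$amplitude_uV[amp_tab$condition == "familiar"],
       unfamiliar = amp_tab$amplitude_uV[amp_tab$condition == "unfamiliar"])
}

#' @export
print.run_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("oN1 window %g-%g ms (peak %g ms)\n", r$on1$window$lo,
              r$on1$window$hi, r$on1$window$peak_latency))
  cat(sprintf("oN1 mean familiar %.2f uV, unfamiliar %.2f uV; t(%d) = %.2f, p = %.4g, dz = %.2f, BF10 = %.2f\n",
              r$on1$mean[["familiar"]], r$on1$mean[["unfamiliar"]],
              r$on1$df, r$on1$t, r$on1$p, r$on1$dz, r$on1$bf10))
  if (!is.null(r$decoding)) {
    cat(sprintf("decoding: %d participants included, %d cluster(s)\n",
                r$decoding$n_included, nrow(r$decoding$clusters)))
    if (nrow(r$decoding$clusters)) print(r$decoding$clusters)
  }
  cat(sprintf("power analysis: n = %d for dz = %.2f\n",
              r$power$n_required, r$power$dz))
  invisible(x)
}
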