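#' Run a named experiment recipe
#'
#' End-to-end experiment protocols (build, stimulate, simulate trials,
#' analyze) with all artifacts written to a directory: output series and
#' PSDs as CSV, sweep images as CSV matrix and PNG, harmonic tables, a
#' machine-readable JSON summary and the resolved configuration snapshot.
#'
#' Recipes:
#' \describe{
#'   \item{`tonic_demo`}{unconnected populations under constant bias
#'     currents; writes rasters and firing rates.}
#'   \item{`sweep_periodic` / `sweep_poisson`}{input-frequency sweep of the
#'     base model (full: 10-50 Hz step 1, 10 trials; ci scale: 5
#'     frequencies, 3 trials).}
#'   \item{`in_suppression`}{periodic sweep over the upper band under base
#'     and feed-forward-suppressed variants; subharmonic comparison table.}
#'   \item{`retina_compare`}{emulated-retina input at 10/20/40 Hz under both
#'     variants (six cases); series and PSDs.}
#'   \item{`multi_node`}{3-node model, 10 Hz periodic input, both variants;
#'     PSDs and fundamental/2nd-harmonic power ratio.}
#' }
#'
#' @param name recipe name.
#' @param out_dir output directory (created).
#' @param base_seed integer seed.
#' @param scale `"full"` (protocol sizes) or `"ci"` (reduced trial and
#'   frequency counts for quick runs).
#' @param config an [lgn_config()].
#' @return Named list summary (also written as `summary.json`), invisibly.
#' @export
run_recipe <- function(name = c("tonic_demo", "sweep_periodic",
                                "sweep_poisson", "in_suppression",
                                "retina_compare", "multi_node"),
                       out_dir, base_seed = 1, scale = c("full", "ci"),
                       config = lgn_config()) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(out_dir, "config-snapshot.yaml"))
  an <- config$analysis
  n_trials <- if (scale == "ci") 3 else config$simulation$n_trials
  duration <- config$simulation$duration
  dt <- config$simulation$dt

  run_and_psd <- function(net, spec, seed = base_seed) {
    avg <- run_trials(net, spec, n_trials = n_trials, base_seed = seed,
                      duration = duration, dt = dt)
    x <- preprocess(model_output(avg), fs_in = 1000 / dt,
                    epoch = unlist(an$epoch), fs_out = an$fs_out,
                    band = unlist(an$band), order = an$order)
    psd <- welch_psd(x, fs = an$fs_out, seg_len = an$seg_len,
                     overlap = an$overlap, pad_factor = an$pad_factor)
    list(avg = avg, series = x, psd = psd)
  }
  save_case <- function(res, tag) {
    write_series_csv(res$series, file.path(out_dir, paste0(tag, "-series.csv")))
    write.table(as.data.frame(res$psd),
                file.path(out_dir, paste0(tag, "-psd.csv")),
                sep = ",", quote = FALSE, row.names = FALSE)
  }

  summary <- list(recipe = name, scale = scale, base_seed = base_seed,
                  n_trials = n_trials)

  if (name == "tonic_demo") {
    rates <- sapply(c(3, 5, 7), function(idc)
      attr(tonic_demo(i_dc = idc, duration = 1000), "rates_hz"))
    colnames(rates) <- paste0("i_dc_", c(3, 5, 7))
    write.table(rates, file.path(out_dir, "tonic-rates.csv"), sep = ",",
                quote = FALSE, col.names = NA)
    summary$rates_hz <- as.list(as.data.frame(rates))
  } else if (name %in% c("sweep_periodic", "sweep_poisson")) {
    freqs <- if (scale == "ci") c(10, 20, 30, 40, 50) else 10:50
    net <- build_lgn(config)
    sw <- sweep_psd(net, freqs,
                    stimulus_type = sub("sweep_", "", name),
                    n_trials = n_trials, base_seed = base_seed,
                    duration = duration, dt = dt)
    write_sweep_csv(sw, file.path(out_dir, "sweep.csv"))
    plot_sweep(sw, file.path(out_dir, "sweep.png"))
    summary$input_freqs <- sw$input_freqs
    summary$peak_freqs <- sw$peaks
    summary$second_harmonic_present <-
      vapply(sw$profiles, function(p) p$present[p$component == "2f"], TRUE)
  } else if (name == "in_suppression") {
    freqs <- if (scale == "ci") c(36, 40, 44, 48, 50) else 36:50
    for (variant in c("base", "in_suppressed")) {
      cfg <- if (variant == "base") config else apply_in_suppression(config)
      sw <- sweep_psd(build_lgn(cfg), freqs, "periodic",
                      n_trials = n_trials, base_seed = base_seed,
                      duration = duration, dt = dt)
      write_sweep_csv(sw, file.path(out_dir, paste0("sweep-", variant, ".csv")))
      sub_half <- vapply(sw$profiles,
                         function(p) p$present[p$component == "1/2f"], TRUE)
      summary[[paste0("half_f_present_", variant)]] <- sub_half
    }
  } else if (name == "retina_compare") {
    for (freq in c(10, 20, 40)) {
      stim <- retina_stimulus(freq, duration)
      for (variant in c("base", "in_suppressed")) {
        cfg <- if (variant == "base") config else apply_in_suppression(config)
        res <- run_and_psd(build_lgn(cfg), stim)
        tag <- sprintf("retina-%dHz-%s", freq, variant)
        save_case(res, tag)
        summary[[paste0("peak_", tag)]] <- peak_frequency(res$psd)
      }
    }
  } else if (name == "multi_node") {
    for (variant in c("base", "in_suppressed")) {
      cfg <- if (variant == "base") config else apply_in_suppression(config)
      net <- build_multi_node(cfg, 3)
      res <- run_and_psd(net, list(type = "periodic", freq = 10))
      tag <- paste0("multinode-10Hz-", variant)
      save_case(res, tag)
      prof <- harmonic_profile(res$psd, 10)
      summary[[paste0("peak_", variant)]] <- peak_frequency(res$psd)
      summary[[paste0("f0_over_2f0_", variant)]] <-
        prof$power[prof$component == "1f"] / prof$power[prof$component == "2f"]
    }
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Generate text fixtures
#'
#' Writes small reproducible fixture files: emulated-retina first-spike
#' event streams for 10/20/40 Hz LED flashing (12 x 12 pixels, 1 s),
#' synthetic periodic and Poisson spike-train files, and a tiny two-neuron
#' network configuration for unit tests.  Regeneration from the same seed is
#' bit-identical.
#'
#' @param out_dir writable output directory.
#' @param seed integer seed.
#' @return Character vector of written paths, invisibly.
#' @export
generate_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (freq in c(10, 20, 40)) {
    ev <- retina_stimulus(freq, 1000, jitter_sd = 0.05, noise_seed = seed)
    p <- file.path(out_dir, sprintf("retina-%02dHz-synthetic.tsv", freq))
    write_events(ev, p)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "periodic-20Hz.tsv")
  write_events(periodic_train(20, 1000, 144), p)
  paths <- c(paths, p)
  p <- file.path(out_dir, "poisson-20Hz.tsv")
  write_events(poisson_trains(20, 1000, 144, seed = seed), p)
  paths <- c(paths, p)
  p <- file.path(out_dir, "tiny-network.yaml")
  yaml::write_yaml(list(
    populations = list(TCR = list(size = 1), IN = list(size = 1),
                       TRN = list(size = 1), RET = list(size = 2))), p)
  paths <- c(paths, p)
  invisible(paths)
}
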