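#' Analysis configuration
#'
#' Bundles every tunable parameter of the pipeline with its default:
#' 10 ms analysis bins, count truncation at 20, equal-stimulus priors for
#' stimulus information, Monte Carlo chunks of 100000 samples with a 0.2-bit
#' stopping and 0.6-bit abort error, 20 bootstrap repetitions, 10 random
#' groupings for the floor reference, 50 Hz resolution checks.
#'
#' @param bin_ms Analysis bin width (ms).
#' @param r_max Count truncation for entropy sums.
#' @param fs Rate sampling frequency (Hz).
#' @param mu_floor Lower bound on expected counts per bin.
#' @param scheme Prior scheme for stimulus information.
#' @param mc_chunk,mc_se_stop,mc_max,mc_se_abort Monte Carlo controls (see
#'   [mc_params()]).
#' @param nb_boot Bootstrap repetitions for [bootstrap_error()].
#' @param n_perm Random groupings for [floor_category_info()].
#' @param f_cut Temporal-resolution cutoff (Hz).
#' @param seed Integer master seed.
#' @param window_ms Response window (ms).
#' @return A validated `run_config` list.
#' @export
run_config <- function(bin_ms = 10, r_max = 20, fs = 1000, mu_floor = 1 / 20,
                       scheme = "equal_stimulus", mc_chunk = 100000,
                       mc_se_stop = 0.2, mc_max = 5e6, mc_se_abort = 0.6,
                       nb_boot = 20, n_perm = 10, f_cut = 50, seed = 1,
                       window_ms = 600) {
  cfg <- list(bin_ms = bin_ms, r_max = r_max, fs = fs, mu_floor = mu_floor,
              scheme = scheme, mc_chunk = mc_chunk, mc_se_stop = mc_se_stop,
              mc_max = mc_max, mc_se_abort = mc_se_abort, nb_boot = nb_boot,
              n_perm = n_perm, f_cut = f_cut, seed = seed,
              window_ms = window_ms)
  if (!(cfg$mc_se_stop > 0 && cfg$mc_se_stop < cfg$mc_se_abort))
    stop("require 0 < mc_se_stop < mc_se_abort")
  if (!cfg$scheme %in% c("equal_stimulus", "equal_category"))
    stop("unknown prior scheme '", cfg$scheme, "'")
  structure(cfg, class = "run_config")
}

#' Read a flat key=value configuration file
#'
#' @param path Path to a text file with one `key = value` pair per line
#'   (`#` comments allowed).  Unknown keys are rejected.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1L], collapse = "="), ""))
  known <- names(formals(run_config))
  if (any(!keys %in% known))
    stop("unknown config key(s): ",
         paste(setdiff(keys, known), collapse = ", "))
  args <- stats::setNames(lapply(seq_along(keys), function(i) {
    v <- suppressWarnings(as.numeric(vals[i]))
    if (is.na(v)) vals[i] else v
  }), keys)
  do.call(run_config, args)
}

#' Write a configuration to a flat key=value file
#' @param cfg A [run_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  writeLines(paste(names(cfg), unlist(cfg), sep = " = "), path)
  invisible(path)
}

#' Run the full analysis pipeline on one neuron
#'
#' Rate estimation (with jackknife replicates), instantaneous and cumulative
#' information for stimuli and categories, the Categorical Information Index
#' with its references, exponential fits to the cumulative curves (only when
#' the stimulus cumulative information is significant somewhere), and the
#' Poisson/resolution diagnostics.  All outputs are written as tab-delimited
#' tables alongside the resolved configuration so the run can be reproduced
#' from the emitted files alone.
#'
#' @param spikes A [spike_train_set()] or a path to a spike table.
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @param config A [run_config()].
#' @return Invisibly, a list with all computed objects (`rates`, `binned`,
#'   `instant_stim`, `instant_cat`, `cum_stim`, `cum_cat`, `cii`, `fits`,
#'   `diagnostics`).
#' @export
run_pipeline <- function(spikes, out_dir = NULL, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.character(spikes))
    spikes <- stage("read", read_spike_table(spikes, config$window_ms))
  stopifnot(inherits(spikes, "spike_train_set"))
  mc <- mc_params(chunk = config$mc_chunk, se_stop = config$mc_se_stop,
                  max_samples = config$mc_max, se_abort = config$mc_se_abort,
                  seed = config$seed)
  emit <- function(obj, file, writer) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, file))
    obj
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_config(config, file.path(out_dir, "config.txt"))
  }
  ens <- stage("rates", rate_ensemble(spikes, fs = config$fs))
  br <- stage("rates", integrate_to_bins(ens, bin_ms = config$bin_ms,
                                         r_max = config$r_max,
                                         mu_floor = config$mu_floor))
  grouping <- category_map(spikes)
  inst_s <- emit(stage("instantaneous",
                       instantaneous_info(br, scheme = config$scheme)),
                 "instantaneous_stim.tsv", write_info_series)
  inst_c <- emit(stage("instantaneous",
                       instantaneous_info(br, grouping = grouping)),
                 "instantaneous_cat.tsv", write_info_series)
  cum_s <- emit(stage("cumulative",
                      cumulative_info(br, mc = mc, scheme = config$scheme)),
                "cumulative_stim.tsv", write_info_series)
  cum_c <- emit(stage("cumulative",
                      cumulative_info(br, grouping = grouping, mc = mc)),
                "cumulative_cat.tsv", write_info_series)
  cii <- stage("cii", {
    flo <- floor_category_info(br, grouping, mc = mc, n_perm = config$n_perm)
    sizes <- as.integer(table(grouping))
    expd <- expected_category_info(cum_s$info, sizes)
    ceil <- ceiling_category_info(cum_s, length(unique(grouping)))
    cii_series(cum_c, flo, expd, ceil, time_ms = cum_s$time_ms)
  })
  fits <- stage("fits", {
    if (significance_mask(cum_s)$any_significant) {
      list(stim = fit_exponential(cum_s, log2(nrow(br$mu))),
           cat = fit_exponential(cum_c,
                                 log2(length(unique(grouping)))))
    } else NULL
  })
  diag <- stage("diagnostics", {
    bc <- bin_counts(spikes, config$bin_ms)
    gof <- poisson_gof(bc, br, n_boot = 200, seed = config$seed)
    list(gof_rejected_fraction = gof$rejected_fraction,
         fano_mean = fano_series(bc)$mean,
         noise_corr = noise_correlation(bc)$mean,
         stim_corr = stimulus_correlation(bc)$mean,
         coherence_fraction = if (min(n_trials(spikes)) >= 4)
           as.numeric(coherence_info_fraction(spikes, f_cut = config$f_cut,
                                              seed = config$seed))
           else NA_real_,
         power_fraction = power_fraction(ens, f_cut = config$f_cut))
  })
  if (!is.null(out_dir)) {
    utils::write.table(as.data.frame(cii), file.path(out_dir, "cii.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(metric = names(diag),
                                  value = unlist(diag)),
                       file.path(out_dir, "diagnostics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(fits)) {
      fdf <- do.call(rbind, lapply(names(fits), function(nm) {
        f <- fits[[nm]]
        data.frame(series = nm, k = f$k, tau = f$tau, dt = f$dt,
                   i_max = f$i_max, mse = f$mse, k300 = f$k300)
      }))
      utils::write.table(fdf, file.path(out_dir, "fits.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  invisible(list(rates = ens, binned = br, instant_stim = inst_s,
                 instant_cat = inst_c, cum_stim = cum_s, cum_cat = cum_c,
                 cii = cii, fits = fits, diagnostics = diag))
}
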