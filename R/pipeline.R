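#' Run configuration for an end-to-end analysis
#'
#' @param generator a [generator_config()] (or NULL with \code{store} set).
#' @param store path to an epochs store directory plus a ratings TSV
#'   (\code{list(epochs = ..., ratings = ...)}); used when \code{generator}
#'   is NULL.
#' @param analyses analyses to run, a subset of \code{"main"},
#'   \code{"induced"}, \code{"auc_variant"}, \code{"window_sensitivity"},
#'   \code{"noise_sweep"}, \code{"power_maps"}, \code{"matching"},
#'   \code{"bands"}, \code{"intra"}, \code{"sensitivity"}.
#' @param out_dir output directory for TSVs and the JSON summary.
#' @param seed integer seed applied to every stochastic stage.
#' @param alpha FDR level.
#' @param window_ms main sliding-window length; the window-sensitivity
#'   stage also runs \code{sensitivity_windows}.
#' @param sensitivity_windows alternative window lengths (ms).
#' @param power_sizes trial counts for the trial-axis power map.
#' @param power_reps bootstrap repetitions per size.
#' @return A \code{run_config} list.
#' @export
run_config <- function(generator = generator_config(), store = NULL,
                       analyses = c("main", "induced"), out_dir = tempfile("painvar_run_"),
                       seed = 1, alpha = 0.05, window_ms = 100,
                       sensitivity_windows = c(50, 200),
                       power_sizes = seq(2, 14, by = 4), power_reps = 50) {
  valid <- c("main", "induced", "auc_variant", "window_sensitivity",
             "noise_sweep", "power_maps", "matching", "bands", "intra",
             "sensitivity")
  bad <- setdiff(analyses, valid)
  if (length(bad))
    stop("unknown analysis name(s): ", paste(bad, collapse = ", "),
         "; valid names are: ", paste(valid, collapse = ", "))
  if (!length(analyses)) stop("at least one analysis is required")
  if (any(c(window_ms, sensitivity_windows) <= 0))
    stop("window sizes must be positive")
  structure(as.list(environment())[
    c("generator", "store", "analyses", "out_dir", "seed", "alpha",
      "window_ms", "sensitivity_windows", "power_sizes", "power_reps")],
    class = "run_config")
}

write_tsv <- function(df, dir, name) {
  data.table::fwrite(df, file.path(dir, paste0(name, ".tsv")), sep = "\t")
}

#' Execute an end-to-end analysis run
#'
#' Generates (or loads) the cohort, computes difference tracks and
#' discriminability scores, and executes the requested stages in
#' dependency order. Every stage writes a TSV under \code{out_dir}; a
#' machine-readable \code{summary.json} collects per-analysis ROI
#' statistics (r, p, Bayes factor) and the design defaults in effect.
#' Identical configuration and seed reproduce the summary exactly.
#'
#' @param config a [run_config()].
#' @return The summary list (invisibly also written as JSON).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$generator)) {
    gen <- config$generator
    gen$seed <- config$seed
    sim <- generate_cohort(gen)
    cohort <- sim$epochs
    ratings <- sim$ratings
  } else {
    cohort <- read_epochs(config$store$epochs)
    ratings <- read_ratings(config$store$ratings)
  }
  scores <- discrim_scores(ratings, "delta_rating")
  dvar <- cohort_diff_tracks(cohort, "tempSD", window_ms = config$window_ms)
  damp <- cohort_diff_tracks(cohort, "amplitude", window_ms = config$window_ms)
  summary <- list(seed = config$seed, alpha = config$alpha,
                  n_subjects = length(cohort),
                  window_ms = config$window_ms,
                  fdr_family = sum(dvar$times >= 0),
                  analyses = list())
  add_roi <- function(name, res) {
    summary$analyses[[name]] <<- list(
      roi_ms = unname(as.numeric(res$roi)), r = res$r, p = res$p,
      bf = res$bf, n = res$n)
  }
  for (an in config$analyses) {
    switch(an,
      main = {
        tr <- track_association(dvar, scores, covariate_tracks = damp,
                                alpha = config$alpha)
        write_tsv(as.data.frame(tr), config$out_dir, "main_partial_track")
        add_roi("main", roi_association(dvar, scores, covariate_tracks = damp))
      },
      induced = {
        ind <- lapply(cohort, induced_epochs)
        div <- cohort_diff_tracks(ind, "tempSD", window_ms = config$window_ms)
        tr <- track_association(div, scores, alpha = config$alpha)
        write_tsv(as.data.frame(tr), config$out_dir, "induced_track")
        add_roi("induced", roi_association(div, scores))
      },
      auc_variant = {
        sc <- discrim_scores(ratings, "auc")
        tr <- track_association(dvar, sc, covariate_tracks = damp,
                                alpha = config$alpha)
        write_tsv(as.data.frame(tr), config$out_dir, "auc_partial_track")
        add_roi("auc_variant", roi_association(dvar, sc, covariate_tracks = damp))
      },
      window_sensitivity = {
        for (w in config$sensitivity_windows) {
          dv <- cohort_diff_tracks(cohort, "tempSD", window_ms = w)
          da <- cohort_diff_tracks(cohort, "amplitude", window_ms = w)
          add_roi(paste0("window_", w, "ms"),
                  roi_association(dv, scores, covariate_tracks = da))
        }
      },
      noise_sweep = {
        sw <- noise_sweep(cohort, scores,
                          noise_config(target = "both", seed = config$seed),
                          window_ms = config$window_ms)
        write_tsv(sw, config$out_dir, "noise_sweep")
        summary$analyses$noise_sweep <-
          list(n_scales = nrow(sw), min_log10_bf = min(sw$log10_bf))
      },
      power_maps = {
        for (met in c("tempSD", "amplitude")) {
          pm <- power_map(cohort, scores, axis = "trials",
                          sizes = config$power_sizes, metric = met,
                          n_reps = config$power_reps, alpha = config$alpha,
                          seed = config$seed, window_ms = config$window_ms)
          write_tsv(as.data.frame(pm), config$out_dir,
                    paste0("power_trials_", met))
          summary$analyses[[paste0("power_trials_", met)]] <-
            list(max_prob = max(pm$prob))
        }
      },
      matching = {
        mods <- generate_multimodal_ratings(config$generator,
                                            c("pain", "touch"),
                                            offsets = c(0, 1))
        mr <- match_ratings(rating_means(mods, "pain"),
                            rating_means(mods, "touch"), seed = config$seed)
        write_tsv(mr$pairs, config$out_dir, "matching_pairs")
        summary$analyses$matching <- list(
          n_pairs = nrow(mr$pairs),
          max_err = if (nrow(mr$pairs))
            max(mr$pairs$err_high, mr$pairs$err_low) else NA)
      },
      bands = {
        for (b in band_definition()$name) {
          bp <- band_profile(cohort, scores, b, window_ms = config$window_ms,
                             alpha = config$alpha, compute_bf = FALSE)
          write_tsv(as.data.frame(bp$sd_given_amp), config$out_dir,
                    paste0("band_", b, "_sd_given_amp"))
          summary$analyses[[paste0("band_", b)]] <- list(
            n_sig_sd = sum(bp$sd_given_amp$q_sig),
            n_sig_amp = sum(bp$amp_given_sd$q_sig))
        }
      },
      intra = {
        ii <- intra_individual(cohort, ratings, window_ms = config$window_ms,
                               alpha = config$alpha)
        write_tsv(data.frame(time_ms = ii$times, mean_z = ii$mean_z,
                             t = ii$t, p = ii$p, fdr_sig = ii$q_sig),
                  config$out_dir, "intra_individual")
        summary$analyses$intra <- list(n_sig = sum(ii$q_sig))
      },
      sensitivity = {
        sa <- sensitivity_analysis(cohort, ratings,
                                   window_ms = config$window_ms,
                                   alpha = config$alpha, compute_bf = FALSE)
        write_tsv(as.data.frame(sa), config$out_dir, "sensitivity_track")
        summary$analyses$sensitivity <- list(n_sig = sum(sa$q_sig))
      })
  }
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
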