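#' Run the full simulation study battery
#'
#' Chains the complete experiment: build the basal network; map its
#' unimodal auditory receptive field and measure the reaction-time-versus-
#' distance curve; train a synchronous and an asynchronous copy; repeat the
#' test batteries on both; fit the boundary sigmoid to each curve; and fit
#' the bundled behavioral before-training IN-sound means. This is the
#' programmatic equivalent of the figures' full test battery and the
#' workhorse behind the acceptance script and the command-line
#' `reproduce-paper` stage.
#'
#' @param seed integer seed controlling all randomness.
#' @param params network parameters.
#' @param n_rep repetitions per distance (default 30).
#' @param distances test distances, cm (default 15 values, 140 down to 0).
#' @param rf_distances receptive-field mapping distances, cm.
#' @param protocol_args extra arguments for [training_protocol()] applied
#'   to both training modes.
#' @param out_dir optional directory: summary tables, fit records and a
#'   manifest are written there as delimited/structured text.
#' @param conditions which trained conditions to run besides basal.
#' @param quiet suppress progress messages.
#' @return a `pps_study` list: `basal`, `sync`, `async` (each with `rf`,
#'   `rt`, `fit`, `extent` where applicable), `behavioral_fit`,
#'   `comparison`, `seed`.
#' @export
reproduce_pps_study <- function(seed = 1, params = network_params(),
                                n_rep = 30,
                                distances = seq(140, 0, by = -10),
                                rf_distances = seq(0, 140, by = 10),
                                protocol_args = list(),
                                out_dir = NULL,
                                conditions = c("synchronous", "asynchronous"),
                                quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  set.seed(seed)
  net <- build_network(params)
  res <- list(seed = seed)

  say("basal receptive-field mapping and RT battery ...")
  rf0 <- map_auditory_rf(net, rf_distances, n_rep)
  rc0 <- rt_vs_distance(net, distances, n_rep)
  res$basal <- list(rf = rf0, rt = rc0, fit = fit_rt_curve(rc0),
                    extent = rf_extent(rf0))

  if ("synchronous" %in% conditions) {
    say("synchronous training + post-training battery ...")
    proto <- do.call(training_protocol,
                     c(list(soa_mode = "synchronous"), protocol_args))
    sy <- run_training(net, proto)
    rf1 <- map_auditory_rf(sy, rf_distances, n_rep)
    rc1 <- rt_vs_distance(sy, distances, n_rep)
    res$sync <- list(net = sy, rf = rf1, rt = rc1, fit = fit_rt_curve(rc1),
                     extent = rf_extent(rf1))
  }
  if ("asynchronous" %in% conditions) {
    say("asynchronous training + post-training battery ...")
    proto <- do.call(training_protocol,
                     c(list(soa_mode = "asynchronous"), protocol_args))
    as_ <- run_training(net, proto)
    rc2 <- rt_vs_distance(as_, distances, n_rep)
    res$async <- list(net = as_, rt = rc2, fit = fit_rt_curve(rc2))
  }

  # behavioral worked example: before-training IN-sound group means
  m <- reference_rt_means()
  bm <- m[m$condition == "synchronous" & m$session == "before" &
            m$direction == "IN", ]
  res$behavioral_fit <- fit_sigmoid(unname(pps_delays), bm$mean)

  if (!is.null(res$sync))
    res$comparison <- list(
      before_vs_sync = compare_boundaries(res$basal$fit, res$sync$fit),
      before_vs_async = if (!is.null(res$async))
        compare_boundaries(res$basal$fit, res$async$fit))

  class(res) <- "pps_study"
  if (!is.null(out_dir)) write_study_outputs(res, out_dir, params)
  res
}

write_study_outputs <- function(res, out_dir, params) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in intersect(c("basal", "sync", "async"), names(res))) {
    r <- res[[cond]]
    if (!is.null(r$rf))
      write_tsv(r$rf$summary, file.path(out_dir, paste0(cond, "_rf.tsv")),
                overwrite = TRUE)
    if (!is.null(r$rt))
      write_tsv(r$rt$summary, file.path(out_dir, paste0(cond, "_rt.tsv")),
                overwrite = TRUE)
  }
  fits <- lapply(intersect(c("basal", "sync", "async"), names(res)),
                 function(cond) {
    f <- res[[cond]]$fit
    list(condition = cond, coef = as.list(f$coef), ci95_xc = f$ci95_xc,
         rss = f$rss, converged = f$converged,
         extent = res[[cond]]$extent)
  })
  jsonlite::write_json(fits, file.path(out_dir, "boundary_fits.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_run_manifest(out_dir, params, seed = res$seed)
  invisible(out_dir)
}

#' @export
print.pps_study <- function(x, ...) {
  cat("Peripersonal-space study battery (seed ", x$seed, ")\n", sep = "")
  fmt <- function(lbl, r) {
    if (is.null(r)) return()
    cat(sprintf("  %-14s xc = %6.2f cm, 95%% CI [%.2f, %.2f]%s\n", lbl,
                r$fit$coef["xc"], r$fit$ci95_xc[1], r$fit$ci95_xc[2],
                if (!is.null(r$extent))
                  sprintf(", RF extent %g cm", r$extent) else ""))
  }
  fmt("basal:", x$basal); fmt("synchronous:", x$sync)
  fmt("asynchronous:", x$async)
  if (!is.null(x$behavioral_fit))
    cat(sprintf("  behavioral before-training boundary: xc = %.0f ms\n",
                x$behavioral_fit$coef["xc"]))
  invisible(x)
}
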