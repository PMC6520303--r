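# End-to-end orchestration: simulate/load -> preprocess -> connectivity ->
# graph metrics -> reliability report.

#' Build a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one serializable
#' list. Input is either a synthetic \code{\link{cohort_spec}} or a
#' directory of recordings written by \code{\link{write_recording}}.
#'
#' @param spec A \code{\link{cohort_spec}} (ignored when \code{input_dir}
#'   is given).
#' @param input_dir Optional directory of \code{.tsv}/\code{.json}
#'   recording pairs; file names must pair sessions 1 and 2 per subject.
#' @param bands Band table (data.frame name/low/high).
#' @param target_rate Analysis sampling rate in Hz; recordings above it
#'   are resampled down.
#' @param broadband Length-2 vector, broadband filter edges in Hz.
#' @param jump_z,var_z Artifact-detection thresholds, see
#'   \code{\link{detect_artifacts}}.
#' @param epoch_length Epoch length in seconds.
#' @param n_epochs Number of epochs selected per subject-session.
#' @param methods Connectivity estimators, subset of
#'   \code{c("pli", "dwpli")}. Graph metrics are computed for PLI only
#'   (dwPLI matrices carry negative weights).
#' @param n_surrogates Surrogates for graph-metric normalization.
#' @param n_boot Bootstrap resamples for confidence intervals.
#' @param percentile Top-percentile edge selection (default 25).
#' @param icc_model \code{"twoway"} or \code{"oneway"}, see \code{\link{icc}}.
#' @param cov_session Session whose values feed the COV (default 1).
#' @param output_dir Optional directory for per-stage artifact files.
#' @param seed Global seed; expanded into per-stage substreams.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(spec = cohort_spec(), input_dir = NULL,
                            bands = eeg_bands(), target_rate = 512,
                            broadband = c(0.1, 70),
                            jump_z = 8, var_z = 4,
                            epoch_length = 5, n_epochs = 20,
                            methods = c("pli", "dwpli"),
                            n_surrogates = 100, n_boot = 10000,
                            percentile = 25, icc_model = "twoway",
                            cov_session = 1, output_dir = NULL, seed = 1) {
  structure(
    list(spec = spec, input_dir = input_dir, bands = bands,
         target_rate = target_rate, broadband = broadband,
         jump_z = jump_z, var_z = var_z,
         epoch_length = epoch_length, n_epochs = n_epochs,
         methods = methods, n_surrogates = n_surrogates, n_boot = n_boot,
         percentile = percentile, icc_model = icc_model,
         cov_session = cov_session, output_dir = output_dir, seed = seed),
    class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks the configuration without running anything. Problems are
#' returned, not thrown; an empty result means the configuration is
#' runnable.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Character vector of problems (empty if none), each naming the
#'   offending field.
#' @export
validate_config <- function(config) {
  p <- character(0)
  rate <- config$target_rate
  if (!is.numeric(rate) || rate <= 0)
    p <- c(p, "target_rate: must be a positive rate in Hz")
  nyq <- rate / 2
  b <- config$bands
  if (!all(c("name", "low", "high") %in% names(b))) {
    p <- c(p, "bands: must have columns name, low, high")
  } else if (nrow(b) > 0) {
    bad <- which(b$low <= 0 | b$high <= b$low | b$high >= nyq)
    for (i in bad)
      p <- c(p, sprintf("bands: band '%s' [%g, %g] Hz invalid at Nyquist %g Hz",
                        b$name[i], b$low[i], b$high[i], nyq))
  }
  if (length(config$broadband) != 2 ||
      config$broadband[1] <= 0 || config$broadband[2] <= config$broadband[1] ||
      config$broadband[2] >= nyq)
    p <- c(p, "broadband: edges must satisfy 0 < low < high < Nyquist")
  if (!all(config$methods %in% c("pli", "dwpli")) || length(config$methods) == 0)
    p <- c(p, "methods: must be a nonempty subset of {pli, dwpli}")
  if (config$percentile <= 0 || config$percentile >= 100)
    p <- c(p, "percentile: must lie in (0, 100)")
  if (config$n_boot < 1) p <- c(p, "n_boot: must be >= 1")
  if (config$n_surrogates < 1) p <- c(p, "n_surrogates: must be >= 1")
  if (!config$icc_model %in% c("twoway", "oneway"))
    p <- c(p, "icc_model: must be 'twoway' or 'oneway'")
  if (is.null(config$input_dir)) {
    sp <- tryCatch({ validate_cohort_spec(config$spec); NULL },
                   error = function(e) conditionMessage(e))
    if (!is.null(sp)) p <- c(p, paste0("spec: ", sp))
    else {
      need <- config$n_epochs * config$epoch_length
      if (config$spec$duration < need)
        p <- c(p, sprintf(
          "n_epochs: %d epochs of %g s need at least %g s per session (spec has %g s)",
          config$n_epochs, config$epoch_length, need, config$spec$duration))
      if (config$spec$n_subjects < 3)
        p <- c(p, "spec: n_subjects must be >= 3 for ICC estimation")
    }
  } else if (!dir.exists(config$input_dir)) {
    p <- c(p, sprintf("input_dir: directory '%s' does not exist", config$input_dir))
  }
  p
}

.subset_conn <- function(cm, labels) {
  keep <- match(labels, cm$channel_labels)
  conn_matrix(cm$values[keep, keep, drop = FALSE], cm$method, labels,
              cm$n_epochs, cm$subject_id, cm$session_id, cm$band_name)
}

#' Run the full reliability pipeline
#'
#' Executes all stages in order: simulate (or load) recordings; resample,
#' broadband-filter, detect artifacts and bad channels (removed from both
#' sessions of a subject); decompose into bands, epoch, and select;
#' estimate connectivity per band and method; compute graph metrics (PLI
#' only); compute three-level reliability statistics per band.
#'
#' @param config A \code{\link{pipeline_config}}; must validate cleanly.
#' @return An object of class \code{reliability_report}: a list of
#'   data.frames \code{global} (ICC and COV with CIs per band x method),
#'   \code{unitwise} (per-edge ICC medians, all edges and top-percentile),
#'   \code{graph} (ICC of Cw/Lw/normalized/SWI per band), \code{edges}
#'   (per-edge ICC values), \code{matrix_correlation} (per-subject r),
#'   \code{subject_metrics} (per-subject graph metrics), and a
#'   \code{manifest}. When \code{config$output_dir} is set, CSV/JSON
#'   artifacts are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))

  stage <- function(what, sid, sess, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed (subject %s, session %s): %s",
                   what, sid, sess, conditionMessage(e)), call. = FALSE))
  }

  recs <- if (is.null(config$input_dir)) generate_cohort(config$spec)
          else read_recording_dir(config$input_dir)
  subj_ids <- unique(vapply(recs, function(r) as.character(r$subject_id),
                            character(1)))
  manifest <- list(package_version = as.character(utils::packageVersion("eegnetrel")),
                   seed = config$seed, n_subjects = length(subj_ids),
                   bands = config$bands, methods = config$methods,
                   subjects = list())

  # -- preprocess per subject --------------------------------------------
  per_subject <- list()
  for (s_i in seq_along(subj_ids)) {
    sid <- subj_ids[s_i]
    pair <- recs[vapply(recs, function(r)
      identical(as.character(r$subject_id), sid), logical(1))]
    if (length(pair) != 2L)
      stop(sprintf("subject %s has %d session(s); need exactly 2", sid, length(pair)))
    sess_id <- vapply(pair, function(r) as.integer(r$session_id), integer(1))
    pair <- pair[order(sess_id)]

    prep <- lapply(1:2, function(k) {
      r <- pair[[k]]
      r <- stage("resample", sid, k, {
        if (r$sampling_rate > config$target_rate)
          resample_recording(r, config$target_rate) else r
      })
      r <- stage("broadband_filter", sid, k,
                 broadband_filter(r, config$broadband[1], config$broadband[2]))
      mask <- stage("detect_artifacts", sid, k,
                    detect_artifacts(r, config$jump_z, config$var_z,
                                     window_s = config$epoch_length))
      list(rec = r, mask = mask,
           bad = detect_bad_channels(r, mask))
    })
    harmonized <- stage("harmonize_channels", sid, "both",
                        harmonize_channels(prep[[1]]$rec, prep[[2]]$rec,
                                           prep[[1]]$bad, prep[[2]]$bad))
    keep <- harmonized$session1$channel_labels
    masks <- lapply(1:2, function(k)
      prep[[k]]$mask[keep, , drop = FALSE])
    manifest$subjects[[sid]] <- list(
      removed_channels = union(prep[[1]]$bad, prep[[2]]$bad),
      retained_channels = length(keep),
      n_pairs = length(keep) * (length(keep) - 1) / 2)
    per_subject[[sid]] <- list(recs = list(harmonized$session1,
                                           harmonized$session2),
                               masks = masks)
  }

  # -- connectivity per subject-session-band-method ----------------------
  conn <- list()   # conn[[method]][[band]][[session]] = list per subject
  for (m in config$methods)
    for (b in config$bands$name)
      conn[[m]][[b]] <- list(`1` = list(), `2` = list())
  epochs_used <- list()

  for (sid in names(per_subject)) {
    ps <- per_subject[[sid]]
    for (k in 1:2) {
      r <- ps$recs[[k]]
      bands_rec <- stage("band_decompose", sid, k,
                         band_decompose(r, config$bands))
      sel_seed <- derive_seed(config$seed,
                              200000L + 2L * match(sid, subj_ids) + k)
      for (b in config$bands$name) {
        ep <- stage("epoch_and_select", sid, k,
                    epoch_and_select(bands_rec[[b]], config$epoch_length,
                                     config$n_epochs, seed = sel_seed,
                                     artifact_mask = ps$masks[[k]],
                                     band_name = b))
        for (m in config$methods) {
          cm <- stage(paste0("connectivity_", m), sid, k,
                      connectivity_matrix(ep, method = m))
          conn[[m]][[b]][[as.character(k)]][[sid]] <- cm
        }
      }
      epochs_used[[paste(sid, k, sep = "_")]] <- config$n_epochs
    }
  }

  # common channel set across subjects (intersection) for edge-level stats
  all_labels <- lapply(per_subject, function(ps) ps$recs[[1]]$channel_labels)
  common <- Reduce(intersect, all_labels)
  manifest$common_channels <- length(common)
  manifest$common_pairs <- length(common) * (length(common) - 1) / 2

  # -- graph metrics (PLI only) ------------------------------------------
  subject_metrics <- NULL
  if ("pli" %in% config$methods) {
    rows <- list()
    for (b in config$bands$name) {
      for (k in c("1", "2")) {
        for (sid in names(conn$pli[[b]][[k]])) {
          g_seed <- derive_seed(config$seed,
                                300000L + match(sid, subj_ids) * 13L +
                                  as.integer(k) + match(b, config$bands$name) * 131L)
          rows[[length(rows) + 1L]] <-
            stage("graph_metrics", sid, k,
                  graph_metrics(conn$pli[[b]][[k]][[sid]],
                                n_surrogates = config$n_surrogates,
                                seed = g_seed))
        }
      }
    }
    subject_metrics <- do.call(rbind, rows)
  }

  # -- reliability -------------------------------------------------------
  boot_i <- 0L
  next_boot_seed <- function() {
    boot_i <<- boot_i + 1L
    derive_seed(config$seed, 400000L + boot_i)
  }
  glob_rows <- list(); unit_rows <- list(); corr_rows <- list()
  edge_rows <- list()
  for (m in config$methods) {
    for (b in config$bands$name) {
      s1 <- conn[[m]][[b]][["1"]]; s2 <- conn[[m]][[b]][["2"]]
      s1c <- lapply(s1, .subset_conn, labels = common)
      s2c <- lapply(s2, .subset_conn, labels = common)

      # per-subject matrix correlations
      for (sid in names(s1)) {
        corr_rows[[length(corr_rows) + 1L]] <- data.frame(
          band = b, method = m, subject = sid,
          r = matrix_correlation(s1[[sid]], s2[[sid]]),
          stringsAsFactors = FALSE)
      }

      gl <- icc_global(s1, s2, n_boot = config$n_boot,
                       seed = next_boot_seed(), model = config$icc_model)
      cov_vals <- gl$table[, config$cov_session]
      cov_est <- cov_subjects(cov_vals)
      cov_ci <- bootstrap_ci(function(d) cov_subjects(d[, 1]),
                             cbind(cov_vals), n_boot = config$n_boot,
                             seed = next_boot_seed())
      glob_rows[[length(glob_rows) + 1L]] <- data.frame(
        band = b, method = m, icc = gl$icc,
        icc_lo = gl$ci[["lo"]], icc_hi = gl$ci[["hi"]],
        reliability = classify_reliability(gl$icc),
        cov = cov_est, cov_lo = cov_ci[["lo"]], cov_hi = cov_ci[["hi"]],
        n_subjects = nrow(gl$table), stringsAsFactors = FALSE)

      uw <- icc_unitwise(s1c, s2c, model = config$icc_model)
      mask <- top_percentile_edges(s1c, s2c, config$percentile)
      sel <- mask[upper.tri(mask)]
      top_median <- stats::median(uw$per_edge$icc[sel], na.rm = TRUE)
      unit_rows[[length(unit_rows) + 1L]] <- data.frame(
        band = b, method = m, median_icc = uw$median,
        top_median_icc = top_median, n_edges = uw$n_edges,
        n_top_edges = sum(sel), stringsAsFactors = FALSE)
      edge_rows[[length(edge_rows) + 1L]] <-
        cbind(band = b, method = m, uw$per_edge,
              top_selected = sel, stringsAsFactors = FALSE)
    }
  }

  graph_rows <- list()
  if (!is.null(subject_metrics)) {
    for (b in config$bands$name) {
      sm <- subject_metrics[subject_metrics$band == b, ]
      for (metric in c("Cw", "Lw", "Cw_nrm", "Lw_nrm", "SWI")) {
        tab <- matrix(NA_real_, length(subj_ids), 2)
        for (s_i in seq_along(subj_ids)) for (k in 1:2) {
          v <- sm[sm$subject == subj_ids[s_i] & sm$session == k, metric]
          if (length(v) == 1) tab[s_i, k] <- v
        }
        tab <- tab[stats::complete.cases(tab), , drop = FALSE]
        est <- icc(tab, model = config$icc_model)
        ci <- bootstrap_ci(function(d) icc(d, model = config$icc_model),
                           tab, n_boot = config$n_boot,
                           seed = next_boot_seed())
        graph_rows[[length(graph_rows) + 1L]] <- data.frame(
          band = b, metric = metric, icc = est,
          icc_lo = ci[["lo"]], icc_hi = ci[["hi"]],
          reliability = classify_reliability(est),
          stringsAsFactors = FALSE)
      }
    }
  }

  report <- structure(
    list(global = do.call(rbind, glob_rows),
         unitwise = do.call(rbind, unit_rows),
         graph = if (length(graph_rows)) do.call(rbind, graph_rows) else NULL,
         edges = do.call(rbind, edge_rows),
         matrix_correlation = do.call(rbind, corr_rows),
         subject_metrics = subject_metrics,
         manifest = manifest),
    class = "reliability_report")

  if (!is.null(config$output_dir)) {
    out <- config$output_dir
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    utils::write.csv(report$global, file.path(out, "global_reliability.csv"),
                     row.names = FALSE)
    utils::write.csv(report$unitwise, file.path(out, "unitwise_reliability.csv"),
                     row.names = FALSE)
    if (!is.null(report$graph))
      utils::write.csv(report$graph, file.path(out, "graph_reliability.csv"),
                       row.names = FALSE)
    utils::write.csv(report$edges, file.path(out, "edge_icc.csv"),
                     row.names = FALSE)
    utils::write.csv(report$matrix_correlation,
                     file.path(out, "matrix_correlation.csv"), row.names = FALSE)
    if (!is.null(report$subject_metrics))
      utils::write.csv(report$subject_metrics,
                       file.path(out, "subject_graph_metrics.csv"),
                       row.names = FALSE)
    all_cms <- list()
    for (m in config$methods) for (b in config$bands$name)
      for (k in c("1", "2")) all_cms <- c(all_cms, conn[[m]][[b]][[k]])
    write_connectivity(all_cms, file.path(out, "connectivity.csv"))
    if (is.null(config$input_dir))
      utils::write.csv(couplings_table(recs),
                       file.path(out, "true_couplings.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("<reliability_report>\n")
  cat(sprintf("  %d subjects, %d common channels (%d pairs)\n",
              x$manifest$n_subjects, x$manifest$common_channels,
              x$manifest$common_pairs))
  cat("\nGlobal connectivity reliability (ICC with 95% bootstrap CI):\n")
  print(x$global, row.names = FALSE, digits = 3)
  cat("\nUnit-wise (per-edge) reliability, median ICC:\n")
  print(x$unitwise, row.names = FALSE, digits = 3)
  if (!is.null(x$graph)) {
    cat("\nGraph-metric reliability (PLI):\n")
    print(x$graph, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
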