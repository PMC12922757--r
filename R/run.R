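# End-to-end orchestration: simulate -> write -> re-read -> analyze -> report.

#' Fraction of cells with a detected post-constriction calcium spike
#'
#' Counts a trace as spiking when [detect_spikes()] finds at least one spike
#' located within `window_factor` cell lengths past the pillar exit. The
#' denominator is the traces that cover the post window (cells that crossed).
#'
#' @param traces list of `cta_trace`
#' @param geometry a [device_geometry()]
#' @param k_mad,min_separation passed to [detect_spikes()]
#' @param window_factor post-window size in cell lengths
#' @return list with `fraction`, `n_spiking`, `n_evaluable`
#' @export
post_spike_fraction <- function(traces, geometry = device_geometry(),
                                k_mad = 5, min_separation = 60,
                                window_factor = 2) {
  ex <- constriction_exit(geometry)
  wend <- ex + window_factor * geometry$cell_length
  evaluable <- spiking <- 0L
  for (tr in traces) {
    if (max(tr$x) <= ex) next
    evaluable <- evaluable + 1L
    sp <- detect_spikes(tr, k_mad = k_mad, min_separation = min_separation,
                        geometry = geometry)
    if (any(sp$post & sp$x <= wend)) spiking <- spiking + 1L
  }
  list(fraction = if (evaluable > 0) spiking / evaluable else NA_real_,
       n_spiking = spiking, n_evaluable = evaluable)
}

.analyze_phenotype <- function(label, cohort, cfg, run_dir) {
  geom <- cohort$geometry
  an <- cfg$analysis
  tracks_csv <- file.path(run_dir, paste0("tracks_", label, ".csv"))
  write_tracks(cohort, tracks_csv)
  jsonlite::write_json(cohort$ground_truth,
                       file.path(run_dir, paste0("ground_truth_", label, ".json")),
                       auto_unbox = TRUE, digits = NA, na = "null")

  # round-trip: the analysis consumes the written spots table
  ts <- read_tracks(tracks_csv, frame_interval = cohort$dt, geometry = geom)
  ts <- filter_tracks(ts, min_final_x = an$min_final_x)
  peri <- peri_summary(ts, n_boot = an$n_boot, seed = cfg$seed,
                       min_points = an$min_points, trim_arrest = an$trim_arrest)
  ecc <- tryCatch(eccentricity_timecourse(ts), error = function(e) NULL)

  fold <- vapply(cohort$traces %||% list(), calcium_fold_change, 0,
                 geometry = geom)
  spikes <- if (!is.null(cohort$traces))
    post_spike_fraction(cohort$traces, geom, k_mad = an$k_mad,
                        min_separation = an$min_separation_s,
                        window_factor = an$spike_window_factor)
  else list(fraction = NA_real_, n_spiking = 0L, n_evaluable = 0L)

  gt <- cohort$ground_truth
  vesicles <- list(
    median_pre = stats::median(gt$vesicle_pre),
    median_post = stats::median(gt$vesicle_post),
    pmlc_vesicle_cor = if (all(is.na(gt$vesicle_post))) NA_real_ else
      suppressWarnings(stats::cor(gt$pmlc_ratio, gt$vesicle_post)))

  kera <- NULL
  if (isTRUE(cfg$render$enabled)) {
    n_rf <- cfg$render$n_frames
    all_fr <- cohort$tracks$tracks[[1]]$frames
    fr <- all_fr[unique(round(seq(length(all_fr) * 0.35, length(all_fr) * 0.6,
                                  length.out = n_rf)))]
    # draw a spatially sparse subset: dense late-movie fields near the
    # saturation arrest cannot be tiled without overlap
    n_draw <- min(20L, length(cohort$tracks$tracks))
    rendered <- render_frames(cohort, pixel_size = cfg$render$pixel_size,
                              frames = fr, cells = seq_len(n_draw),
                              cortical_ratio = cfg$render$cortical_ratio,
                              band_width = an$band_width_px,
                              seed = cfg$seed + 7L, max_retries = 50)
    met <- do.call(rbind, lapply(rendered, function(f) {
      if (is.null(f$cells)) return(NULL)
      sm <- shape_metrics(f$cell_mask, pixel_size = f$pixel_size)
      sm$cell <- sm$label
      pos <- f$cells$x[match(sm$label, f$cells$cell)]
      sm$region <- as.character(classify_position(
        pmin(pmax(pos, 0), geom$chamber_length), geom))
      sm$region[sm$region == "before"] <- "before"
      sm$region[sm$region == "after"] <- "after"
      sm$frame <- f$frame_index
      sm
    }))
    kera <- list(fraction_after = keratocyte_fraction(met, "after",
                                                      an$classifier),
                 n_after = length(unique(met$cell[met$region == "after"])))
    data.table::fwrite(met, file.path(run_dir, paste0("morphology_", label, ".csv")))
  }

  pc <- peri$per_cell
  if (length(fold)) {
    ids <- vapply(cohort$traces, function(t) as.character(t$track_id), "")
    pc$calcium_fold <- fold[match(pc$track_id, ids)]
  }
  data.table::fwrite(pc, file.path(run_dir, paste0("percell_", label, ".csv")))

  list(population = peri$population, eccentricity_by_region = as.list(ecc),
       calcium = list(median_fold_change = stats::median(fold, na.rm = TRUE),
                      spike_fraction = spikes$fraction,
                      n_evaluable = spikes$n_evaluable),
       vesicles = vesicles, keratocyte = kera)
}

#' Run a full synthetic experiment from a configuration
#'
#' Solves the chemoattractant gradient, simulates one cohort per configured
#' phenotype (tracks, calcium traces, vesicle counts), writes every artifact
#' (spots CSVs, ground-truth JSON, per-cell CSVs) into `out_dir`, re-reads the
#' written tracks for analysis, and assembles `summary.json` (deterministic:
#' identical config + seed give a byte-identical file) plus `manifest.json`.
#'
#' @param config nested config list (see [default_config()] / [read_config()])
#' @param out_dir run directory (created)
#' @param quiet suppress progress messages
#' @return the run directory, invisibly; `summary.json` holds the results
#' @export
run_experiment <- function(config = default_config(), out_dir, quiet = FALSE) {
  if (missing(out_dir)) cta_stop("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  geom <- .geometry_from_config(config)
  seed <- as.integer(config$seed)

  say("solving chemoattractant gradient ...")
  d <- config$device
  field <- solve_gradient(geom, D = d$D_cm2s, t_end = d$t_end_s,
                          dx = d$dx_um, dt = d$dt_s)
  write_field_csv(field, file.path(out_dir, "gradient.csv"))
  t_est <- gradient_establishment_time(field, tol = d$establish_tol)

  results <- list(gradient = list(
    establishment_time_s = t_est, establishment_time_min = t_est / 60,
    tol = d$establish_tol, D_cm2s = d$D_cm2s))

  i <- 0L
  for (label in names(config$phenotypes)) {
    i <- i + 1L
    say("simulating cohort '", label, "' ...")
    ph <- .phenotype_from_config(label, config$phenotypes[[label]])
    co <- simulate_cohort(ph, n_cells = config$simulate$n_cells,
                          geometry = geom, dt = config$simulate$dt_s,
                          n_frames = config$simulate$n_frames,
                          seed = seed + 100L * i)
    co <- generate_calcium_traces(co, baseline = config$traces$baseline,
                                  noise_cv = config$traces$noise_cv,
                                  spike_amp = config$traces$spike_amp,
                                  spike_decay = config$traces$spike_decay_s,
                                  seed = seed + 100L * i + 1L)
    co <- generate_vesicle_counts(co, dispersion = config$vesicles$dispersion,
                                  seed = seed + 100L * i + 2L)
    say("analyzing cohort '", label, "' ...")
    results$phenotypes[[label]] <- .analyze_phenotype(label, co, config, out_dir)
  }

  jsonlite::write_json(results, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  manifest <- list(package = "constrictaxis",
                   version = as.character(utils::packageVersion("constrictaxis")),
                   r_version = as.character(getRversion()),
                   seed = seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   generated = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("run complete: ", out_dir)
  invisible(out_dir)
}

#' Assemble figures and a cross-checked summary from a run directory
#'
#' Reads the run's `summary.json` and per-cell CSVs, recomputes the population
#' medians from the per-cell tables (consistency check), and draws the report
#' figures (time-colored tracks, before-after speed/directionality, calcium
#' traces along the chemotaxis axis, pMLC-vs-vesicle scatter) into
#' `report.pdf`.
#'
#' @param run_dir a directory produced by [run_experiment()]
#' @return the parsed summary list, invisibly
#' @export
make_report <- function(run_dir) {
  sj <- file.path(run_dir, "summary.json")
  if (!file.exists(sj)) cta_stop("missing stage output: summary.json (run the analysis first)")
  summary <- jsonlite::read_json(sj, simplifyVector = TRUE)
  labels <- names(summary$phenotypes)

  # consistency: medians in the JSON equal medians recomputed from per-cell CSVs
  for (label in labels) {
    f <- file.path(run_dir, paste0("percell_", label, ".csv"))
    if (!file.exists(f)) cta_stop("missing stage output: ", basename(f))
    pc <- data.table::fread(f)
    jmed <- summary$phenotypes[[label]]$population$median_post_speed
    cmed <- stats::median(pc$post_speed, na.rm = TRUE)
    if (is.finite(jmed) && abs(jmed - cmed) > 1e-8)
      cta_stop("summary/per-cell median mismatch for '", label, "'")
  }

  pdf_path <- file.path(run_dir, "report.pdf")
  grDevices::pdf(pdf_path, width = 7, height = 6)
  on.exit(grDevices::dev.off(), add = TRUE)
  pal <- grDevices::hcl.colors(64, "viridis")

  for (label in labels) {
    tf <- file.path(run_dir, paste0("tracks_", label, ".csv"))
    if (!file.exists(tf)) next
    tr <- data.table::fread(tf)
    sub <- tr[tr$TRACK_ID %in% utils::head(unique(tr$TRACK_ID), 40), ]
    graphics::plot(NA, xlim = c(0, max(tr$POSITION_X)),
                   ylim = range(sub$POSITION_Y),
                   xlab = "x (um)", ylab = "y (um)",
                   main = paste0(label, ": tracks colored by time"))
    tcol <- pal[pmax(1, ceiling(64 * sub$POSITION_T / max(sub$POSITION_T)))]
    for (id in unique(sub$TRACK_ID)) {
      g <- sub[sub$TRACK_ID == id, ]
      graphics::segments(utils::head(g$POSITION_X, -1), utils::head(g$POSITION_Y, -1),
                         g$POSITION_X[-1], g$POSITION_Y[-1],
                         col = utils::head(tcol[sub$TRACK_ID == id], -1))
    }
    graphics::abline(v = 100, col = "red", lty = 2)

    pc <- data.table::fread(file.path(run_dir, paste0("percell_", label, ".csv")))
    ok <- stats::complete.cases(pc[, c("pre_dir", "post_dir")])
    if (any(ok)) {
      graphics::matplot(t(cbind(pc$pre_dir[ok], pc$post_dir[ok])), type = "l",
                        lty = 1, col = grDevices::adjustcolor("grey40", 0.4),
                        xaxt = "n", ylab = "directionality",
                        main = paste0(label, ": before-after directionality"))
      graphics::axis(1, at = c(1, 2), labels = c("pre", "post"))
    }
    if ("calcium_fold" %in% names(pc) && any(is.finite(pc$calcium_fold))) {
      graphics::hist(pc$calcium_fold, breaks = 30,
                     main = paste0(label, ": post/pre calcium fold change"),
                     xlab = "fold change")
    }
    gtf <- file.path(run_dir, paste0("ground_truth_", label, ".json"))
    if (file.exists(gtf)) {
      gt <- jsonlite::read_json(gtf, simplifyVector = TRUE)
      if (!all(is.na(gt$vesicle_post)))
        graphics::plot(gt$vesicle_post, gt$pmlc_ratio,
                       xlab = "post-constriction NE vesicles",
                       ylab = "cortical pMLC II ratio",
                       main = paste0(label, ": polarity vs vesicle count"))
    }
  }
  invisible(summary)
}
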