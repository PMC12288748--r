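# Orchestration: simulate -> calibrate -> extract -> measure -> analyze.

#' Pipeline configuration
#'
#' Bundles the extraction, symmetry-search and analysis settings used by
#' [run_pipeline()]. Unknown fields are rejected.
#'
#' @param extraction An [extraction_config()].
#' @param symmetry A [symmetry_grid()].
#' @param calibration_target Reflectance value the gray card is mapped to;
#'   default 0.18.
#' @param cv_normalization `"pair"` or `"population"`, passed to
#'   [within_individual_cv()].
#' @param taus Threshold ratios for the sensitivity analysis, or `NULL` to
#'   skip it; default `NULL` (the sensitivity re-runs the extraction once per
#'   ratio and image).
#' @param seed Integer seed recorded in the run manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(extraction = extraction_config(),
                            symmetry = symmetry_grid(),
                            calibration_target = 0.18,
                            cv_normalization = c("pair", "population"),
                            taus = NULL, seed = 1L) {
  cv_normalization <- match.arg(cv_normalization)
  stopifnot(inherits(extraction, "extraction_config"),
            inherits(symmetry, "symmetry_grid"),
            calibration_target > 0, calibration_target <= 1)
  structure(list(extraction = extraction, symmetry = symmetry,
                 calibration_target = calibration_target,
                 cv_normalization = cv_normalization,
                 taus = taus, seed = as.integer(seed)),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(config)), f)
  unname(tools::md5sum(f))
}

.write_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  utils::write.csv(df, path, row.names = FALSE)
}

#' Write a synthetic study dataset to disk
#'
#' Generates `n_turtles` turtles x five views x `n_replicates` jittered
#' replicate scenes, writes each as a PNG plus a sidecar manifest CSV
#' (columns `image_path, turtle_id, view, replicate, source, card_x, card_y,
#' card_w, card_h, card_edge_px`), the exact ground truth per image as
#' `ground_truth.csv`, and a simulated consensus survey as `survey.csv`.
#' Turtles differ in disc count, size and placement, drawn from the seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_turtles Number of simulated turtles; default 3.
#' @param n_replicates Replicates per view; default 2.
#' @param views Views to render; default all five.
#' @param n_volunteers Simulated survey volunteers; default 31.
#' @param jitter A [jitter_spec()] template (its `n_replicates` and `seed`
#'   are overridden per group).
#' @param seed Integer master seed.
#' @return Invisibly, the manifest data frame.
#' @export
simulate_dataset <- function(out_dir, n_turtles = 3L, n_replicates = 2L,
                             views = c("top", "left", "right", "front", "back"),
                             n_volunteers = 31L,
                             jitter = jitter_spec(gain_sd = 0.03,
                                                  shift_px_sd = 1.0,
                                                  rot_deg_sd = 1.0),
                             seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(); truth_rows <- list()
  draw <- with_seed(seed, list(
    n_obj = sample(2:4, n_turtles, replace = TRUE),
    jseed = sample.int(1e6, n_turtles * length(views)),
    oseed = sample.int(1e6, n_turtles)))
  for (ti in seq_len(n_turtles)) {
    tid <- sprintf("t%03d", ti)
    objects <- with_seed(draw$oseed[ti], {
      k <- draw$n_obj[ti]
      # rejection-sample disjoint placements: gaps wide enough that the
      # objects stay separate under the opening and the replicate jitter
      for (try in 1:200) {
        ctr_r <- stats::runif(k, 80, 180)
        ctr_c <- stats::runif(k, 80, 220)
        rad <- stats::runif(k, 3, 5)
        rad_px <- rad / 0.2
        ok <- TRUE
        if (k > 1L) {
          dd <- as.matrix(stats::dist(cbind(ctr_r, ctr_c)))
          for (a in 1:(k - 1L)) for (b in (a + 1L):k)
            if (dd[a, b] < rad_px[a] + rad_px[b] + 12) ok <- FALSE
        }
        if (ok) break
      }
      lapply(seq_len(k), function(j)
        object_spec("disc", center = c(ctr_r[j], ctr_c[j]),
                    radius_mm = rad[j]))
    })
    base <- default_scene_spec(seed = seed + ti, objects = objects)
    for (vi in seq_along(views)) {
      jt <- jitter
      jt$n_replicates <- as.integer(n_replicates)
      jt$seed <- draw$jseed[(ti - 1L) * length(views) + vi]
      reps <- generate_replicates(base, jt)
      for (ri in seq_along(reps)) {
        sc <- reps[[ri]]
        fn <- sprintf("%s_%s_r%d.png", tid, views[vi], ri)
        png::writePNG(sc$image, file.path(out_dir, fn))
        cr <- sc$truth$card_rect
        manifest[[length(manifest) + 1L]] <- data.frame(
          image_path = fn, turtle_id = tid, view = views[vi],
          replicate = ri, source = "synthetic",
          card_x = cr[2L], card_y = cr[1L], card_w = cr[4L], card_h = cr[3L],
          card_edge_px = sc$truth$card_edge_px)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          image_path = fn, turtle_id = tid, view = views[vi], replicate = ri,
          n_objects = sc$truth$n_objects,
          pattern_px = sc$truth$pattern_px,
          interior_px = sc$truth$interior_px,
          fractional_area = sc$truth$fractional_area,
          mm_per_pixel = sc$truth$mm_per_pixel)
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  .write_csv(manifest, file.path(out_dir, "manifest.csv"))
  .write_csv(do.call(rbind, truth_rows), file.path(out_dir, "ground_truth.csv"))
  survey <- generate_survey(n_turtles, n_volunteers, seed = seed + 7L)
  survey_long <- data.frame(
    turtle_id = rep(sprintf("t%03d", seq_len(n_turtles)),
                    times = n_volunteers * 9L),
    volunteer = rep(rep(sprintf("v%02d", seq_len(n_volunteers)),
                        each = n_turtles), times = 9L),
    category = rep(pattern_categories(), each = n_turtles * n_volunteers),
    vote = as.integer(survey$votes))
  .write_csv(survey_long, file.path(out_dir, "survey.csv"))
  invisible(manifest)
}

#' Run the full analysis pipeline over an image manifest
#'
#' For every manifest row: read the image, gray-card calibrate it, estimate
#' the mm scale from the card edge, extract the scute mask from the green
#' outline, run the four-step pattern extraction, and compute the 19
#' measurements. Then derives the replicate (within) and across-individual
#' CV tables and the noise ratios, group comparisons when two sources are
#' present, the threshold sensitivity table when `config$taus` is set, and
#' consensus scores and correlations when a survey is supplied. Per-image
#' failures are logged and skipped; the run fails only if no image succeeds.
#'
#' @param manifest Data frame with the sidecar columns of
#'   [simulate_dataset()], or the path to such a CSV.
#' @param out_dir Output directory for CSV results; `NULL` for none.
#' @param config A [pipeline_config()].
#' @param image_dir Directory image paths are relative to; defaults to the
#'   manifest's directory when `manifest` is a path, else `"."`.
#' @param survey Optional `survey_matrix` or survey CSV path.
#' @return A `pipeline_result` list: `measures` (long table), `objects`,
#'   `cv_within`, `cv_across`, `noise`, `tests`, `sensitivity`, `consensus`,
#'   `correlations`, `log`, `run_info`.
#' @export
run_pipeline <- function(manifest, out_dir = NULL,
                         config = pipeline_config(), image_dir = NULL,
                         survey = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(manifest)) {
    if (is.null(image_dir)) image_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (is.null(image_dir)) image_dir <- "."
  if (!nrow(manifest)) stop("empty manifest")
  log <- list(); meas_rows <- list(); scutes <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    status <- tryCatch({
      img <- read_image_rgb(file.path(image_dir, row$image_path))
      # the outline is an exact digital color: locate it before the
      # channel-wise calibration rescales it
      msk <- extract_scute_mask(img)
      cal <- calibrate_gray_card(
        img, c(row$card_y, row$card_x, row$card_h, row$card_w),
        target = config$calibration_target,
        mm_per_pixel = estimate_scale(row$card_edge_px),
        turtle_id = row$turtle_id, view = row$view,
        replicate = row$replicate, source = row$source)
      pat <- extract_pattern(cal, msk, config$extraction)
      ms <- measure_all(cal, msk, pat, grid = config$symmetry,
                        connectivity = config$extraction$connectivity)
      meas_rows[[length(meas_rows) + 1L]] <- data.frame(
        turtle_id = row$turtle_id, view = row$view,
        replicate = row$replicate, source = row$source,
        measure = measure_names(), value = as.numeric(unclass(ms)))
      scutes[[length(scutes) + 1L]] <- list(
        image = cal, mask = msk, view = row$view, turtle_id = row$turtle_id)
      "ok"
    }, error = function(e) paste("error:", conditionMessage(e)))
    log[[i]] <- data.frame(image_path = row$image_path, status = status)
  }
  log <- do.call(rbind, log)
  if (!length(meas_rows)) stop("no image processed successfully")
  measures <- do.call(rbind, meas_rows)
  cvw <- within_individual_cv(measures, config$cv_normalization)
  cva <- across_individual_cv(measures)
  noise <- if (!is.null(cvw) && !is.null(cva)) noise_ratio(cvw, cva) else NULL
  tests <- if ("source" %in% names(measures) &&
               length(unique(measures$source)) == 2L) {
    tryCatch(group_comparison(measures), error = function(e) NULL)
  } else NULL
  sens <- if (!is.null(config$taus)) {
    threshold_sensitivity(scutes, taus = config$taus,
                          baseline = config$extraction$tau,
                          config = config$extraction)
  } else NULL
  cons <- corr <- NULL
  if (!is.null(survey)) {
    if (is.character(survey)) survey <- read_survey(survey)
    cons <- consensus_table(survey)
    corr <- tryCatch(correlate_measures(cons, measures),
                     error = function(e) NULL)
  }
  run_info <- list(config_hash = .config_hash(config), seed = config$seed,
                   n_images = nrow(manifest), n_ok = sum(log$status == "ok"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_csv(measures, file.path(out_dir, "measures.csv"))
    if (!is.null(cvw)) .write_csv(cvw, file.path(out_dir, "cv_within.csv"))
    if (!is.null(cva)) .write_csv(cva, file.path(out_dir, "cv_across.csv"))
    if (!is.null(noise)) .write_csv(noise, file.path(out_dir, "cv_ratio.csv"))
    if (!is.null(tests)) .write_csv(tests, file.path(out_dir, "tests.csv"))
    if (!is.null(sens)) .write_csv(sens, file.path(out_dir, "sensitivity.csv"))
    if (!is.null(cons)) .write_csv(cons$per_turtle,
                                   file.path(out_dir, "consensus.csv"))
    if (!is.null(corr)) .write_csv(corr, file.path(out_dir, "correlations.csv"))
    .write_csv(log, file.path(out_dir, "run_log.csv"))
    jsonlite::write_json(run_info, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE)
  }
  structure(list(measures = measures, cv_within = cvw, cv_across = cva,
                 noise = noise, tests = tests, sensitivity = sens,
                 consensus = cons, correlations = corr, log = log,
                 run_info = run_info),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d/%d image(s) processed\n",
              x$run_info$n_ok, x$run_info$n_images))
  cat(sprintf("  %d measure rows (%d turtles)\n", nrow(x$measures),
              length(unique(x$measures$turtle_id))))
  invisible(x)
}

# Minimal command-line dispatcher behind inst/cli/scutepattern.
# Subcommands: simulate, run, consensus. Returns 0 on success.
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: scutepattern <simulate|run|consensus> [--key value ...]",
    "  simulate  --out DIR [--n-turtles N] [--replicates K] [--seed S]",
    "  run       --manifest CSV --out DIR [--survey CSV] [--seed S]",
    "  consensus --survey CSV --out DIR", sep = "\n")
  if (!length(args)) { cat(usage, "\n"); return(1L) }
  cmd <- args[1L]
  kv <- list()
  rest <- args[-1L]
  while (length(rest) >= 2L) {
    key <- sub("^--", "", rest[1L])
    kv[[gsub("-", "_", key)]] <- rest[2L]
    rest <- rest[-(1:2)]
  }
  get <- function(name, default = NULL) {
    if (!is.null(kv[[name]])) kv[[name]] else default
  }
  switch(cmd,
    simulate = {
      simulate_dataset(get("out", "."),
                       n_turtles = as.integer(get("n_turtles", "3")),
                       n_replicates = as.integer(get("replicates", "2")),
                       seed = as.integer(get("seed", "1")))
      0L
    },
    run = {
      cfg <- pipeline_config(seed = as.integer(get("seed", "1")))
      run_pipeline(get("manifest"), out_dir = get("out", "results"),
                   config = cfg, survey = get("survey"))
      0L
    },
    consensus = {
      cons <- consensus_table(read_survey(get("survey")))
      out <- get("out", ".")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      .write_csv(cons$per_turtle, file.path(out, "consensus.csv"))
      print(cons)
      0L
    },
    { cat("unknown subcommand: ", cmd, "\n", usage, "\n", sep = ""); 1L })
}
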