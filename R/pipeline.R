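#' Study configuration for the full phantom replica
#'
#' Settings for an end-to-end cohort run: cohort size, per-subject phantom
#' variation, classifier settings, the akinesis cutoff, and the
#' reviewer-simulation model. Per-subject infarct angular extents are drawn
#' uniformly from `extent_range`, giving infarct fractions spanning roughly
#' 5-17% of the imaged LV (mean ~11%).
#'
#' @param cohort number of subjects (default 11).
#' @param seed master seed; every subject and every reviewer perturbation is
#'   derived from it.
#' @param extent_range range (deg) of the per-subject infarct angular extent.
#' @param n_sd threshold-classifier SD multiplier (default 6).
#' @param fwhm_fraction FWHM half-maximum fraction (default 0.5).
#' @param akinesis_cutoff akinesis cutoff in mm (default 3).
#' @param remote_center_deg,remote_width_deg remote-ROI sector (anatomical
#'   degrees) on the most basal slice, default the lateral wall.
#' @param reviewer_roi_jitter_deg uniform jitter (+/- deg) of the second
#'   reviewer's remote-ROI centre.
#' @param reviewer_seed_jitter uniform integer jitter (+/- voxels) of the
#'   second reviewer's FWHM seed placement.
#' @param bonferroni_m Bonferroni divisor for the spatial-location test
#'   family (default 11).
#' @param grid_spacing,lambda B-spline registration settings (mm, weight).
#' @param landmarks_per_contour landmarks sampled per contour for the
#'   registration fit.
#' @param phantom_args named list of overrides passed to [phantom_config()]
#'   for every subject (e.g. `list(snr = Inf)` for a noise-free cohort).
#' @param verbose log per-stage timing to stderr.
#' @return A `study_config` list.
#' @export
study_config <- function(cohort = 11,
                         seed = 1L,
                         extent_range = c(25, 95),
                         n_sd = 6,
                         fwhm_fraction = 0.5,
                         akinesis_cutoff = 3,
                         remote_center_deg = 285,
                         remote_width_deg = 60,
                         reviewer_roi_jitter_deg = 10,
                         reviewer_seed_jitter = 2L,
                         bonferroni_m = 11,
                         grid_spacing = 25,
                         lambda = 1e-3,
                         landmarks_per_contour = 50,
                         phantom_args = list(),
                         verbose = FALSE) {
  cfg <- as.list(environment())
  if (cfg$cohort < 1) stop_dwcmr("cohort size must be at least 1")
  if (cfg$akinesis_cutoff <= 0 || cfg$n_sd <= 0 || cfg$fwhm_fraction <= 0) {
    stop_dwcmr("cutoffs must be positive")
  }
  class(cfg) <- "study_config"
  cfg
}

# Phantom configuration for subject i of the cohort.
subject_phantom_config <- function(config, i) {
  extent <- with_seed(phantom_seed(config$seed, 500L + i), {
    stats::runif(1, config$extent_range[1], config$extent_range[2])
  })
  args <- utils::modifyList(
    list(infarct_extent_deg = extent,
         seed = phantom_seed(config$seed, 1000L + i),
         store_cine_images = FALSE),
    config$phantom_args)
  do.call(phantom_config, args)
}

#' Remote-myocardium ROI mask
#'
#' The standardized remote region: an angular sector of the myocardium of
#' the most basal slice, by default 60 degrees centred on the lateral wall,
#' which is the territory farthest from an anteroseptal LAD infarct.
#'
#' @param myocardium myocardium [image_stack()].
#' @param reference_angle anterior reference angle (deg, image coords).
#' @param center LV centre (mm).
#' @param center_deg,width_deg sector centre and width in anatomical degrees.
#' @param slice slice index (default 1, the base).
#' @return Logical array of the ROI.
#' @export
remote_roi_mask <- function(myocardium, reference_angle, center,
                            center_deg = 285, width_deg = 60, slice = 1L) {
  arr <- as_mask_array(myocardium)
  d <- dim(arr)
  idx <- which(arr[, , slice], arr.ind = TRUE)
  sp <- myocardium$spacing
  alpha <- wrap360(angle_deg((idx[, 1] - 0.5) * sp[1], (idx[, 2] - 0.5) * sp[2],
                             center[1], center[2]) - reference_angle)
  keep <- in_sector(alpha, center_deg - width_deg / 2, width_deg)
  roi <- array(FALSE, d)
  roi[cbind(idx[keep, , drop = FALSE], slice)] <- TRUE
  roi
}

#' Nominal FWHM seed voxels from a lesion mask
#'
#' For each slice carrying lesion, the lesion voxel nearest the in-plane
#' lesion centroid — the package's standardized "manual" seed placement,
#' which reviewer replicas then jitter.
#'
#' @param lesion_stack binary lesion mask ([image_stack()] or array).
#' @return A k x 3 integer matrix of `(i, j, slice)` seeds.
#' @export
infarct_seeds <- function(lesion_stack) {
  arr <- as_mask_array(lesion_stack)
  out <- NULL
  for (s in seq_len(dim(arr)[3])) {
    idx <- which(arr[, , s], arr.ind = TRUE)
    if (!nrow(idx)) next
    ctr <- colMeans(idx)
    k <- which.min((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
    out <- rbind(out, c(idx[k, ], s))
  }
  if (is.null(out)) stop_dwcmr("no lesion voxels to seed from")
  out
}

# Jitter seeds within the myocardium; resamples (with a warning) if a draw
# lands outside.
jitter_seeds <- function(seeds, myo, amount, seed) {
  if (amount == 0) return(seeds)
  with_seed(seed, {
    for (r in seq_len(nrow(seeds))) {
      for (try in 1:20) {
        di <- sample(-amount:amount, 1)
        dj <- sample(-amount:amount, 1)
        cand <- c(seeds[r, 1] + di, seeds[r, 2] + dj, seeds[r, 3])
        inside <- cand[1] >= 1 && cand[2] >= 1 &&
          cand[1] <= dim(myo)[1] && cand[2] <= dim(myo)[2] &&
          myo[cand[1], cand[2], cand[3]]
        if (inside) {
          seeds[r, 1:2] <- cand[1:2]
          break
        }
        if (try == 20) {
          warning("seed jitter kept leaving the myocardium; seed not moved")
        }
      }
    }
    seeds
  })
}

#' Simulate reviewer placements
#'
#' The reviewer-replica model: reviewer 1 uses the nominal remote-ROI centre
#' and lesion-centroid seeds; reviewer 2 and the repeat analysis of reviewer
#' 1 perturb the ROI centre by a uniform angular jitter and the FWHM seeds
#' by a uniform in-plane voxel jitter (resampled if a seed leaves the
#' myocardium). This probes pipeline sensitivity to placement, not human
#' behaviour.
#'
#' @param config a [study_config()].
#' @param subject subject index (decorrelates the jitter across subjects).
#' @return Named list (`r1`, `r2`, `r1re`) of placements: `roi_shift_deg`
#'   and `seed_jitter` plus a derived RNG seed.
#' @export
simulate_reviewers <- function(config, subject = 1L) {
  draw <- function(tag, k) {
    sd <- phantom_seed(config$seed, 2000L + 37L * subject + k)
    shift <- with_seed(sd, stats::runif(1, -config$reviewer_roi_jitter_deg,
                                        config$reviewer_roi_jitter_deg))
    list(roi_shift_deg = shift, seed_jitter = config$reviewer_seed_jitter,
         rng = phantom_seed(config$seed, 3000L + 37L * subject + k), tag = tag)
  }
  list(
    r1 = list(roi_shift_deg = 0, seed_jitter = 0L,
              rng = phantom_seed(config$seed, 3000L + 37L * subject), tag = "r1"),
    r2 = draw("r2", 1L),
    r1re = draw("r1re", 2L)
  )
}

# Classify one map with both criteria for one reviewer placement.
# Classification runs on the remote-baseline-subtracted map (signal
# elevation above remote): a no-op for the n-SD threshold mask, and the
# lesion-relative form of the FWHM rule that works on maps with a nonzero
# tissue baseline (an ADC map) as well as on nulled-background LGE.
classify_map <- function(map, myo_stack, truth_lesion, config, placement,
                         reference_angle, center) {
  myo <- as_mask_array(myo_stack)
  roi <- remote_roi_mask(myo_stack, reference_angle, center,
                         center_deg = config$remote_center_deg +
                           placement$roi_shift_deg,
                         width_deg = config$remote_width_deg)
  remote_vals <- map$data[roi]
  remote_vals <- remote_vals[!is.na(remote_vals)]
  elev <- map
  elev$data <- map$data - mean(remote_vals)
  thr <- threshold_classify(map, roi, myo, n_sd = config$n_sd)
  seeds <- infarct_seeds(truth_lesion)
  seeds <- jitter_seeds(seeds, myo, placement$seed_jitter, placement$rng)
  fw <- fwhm_classify(elev, seeds, myo, fraction = config$fwhm_fraction)
  list(threshold = thr, fwhm = fw, roi = roi,
       remote_mean = mean(remote_vals),
       remote_sd = stats::sd(remote_vals))
}

#' Run the full phantom study replica
#'
#' Executes the study pipeline end to end on a seeded phantom cohort, in the
#' fixed stage order: phantom generation, ADC fitting, cine phase matching,
#' B-spline registration of the LGE acquisition into the b0 phase, infarct
#' classification (threshold and FWHM, identically on the ADC map and the
#' co-registered LGE), volume normalization, AHA segment scoring, chord wall
#' motion, and the agreement battery — with reviewer replicas for the
#' inter-/intra-observer comparisons. Fully deterministic for a fixed seed.
#'
#' @param config a [study_config()].
#' @return A `study_report` with elements `regional` (group ADC/RWM means a
#'   la a regional-values table), `volumes` (per-subject long table and the
#'   paired comparisons with ICC, R^2 and Bland-Altman bias), `location`
#'   (per reviewer/method contingency, kappa, agreement, diagnostics,
#'   akinetic counts), `truth` (ground-truth columns), `per_subject`, and
#'   `config`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  t_start <- proc.time()[["elapsed"]]
  log_stage <- function(...) {
    if (isTRUE(config$verbose)) {
      message(sprintf("[%7.2fs] ", proc.time()[["elapsed"]] - t_start), ...)
    }
  }
  subjects <- vector("list", config$cohort)
  for (i in seq_len(config$cohort)) {
    log_stage("subject ", i, ": phantom")
    study <- generate_phantom(subject_phantom_config(config, i))
    subjects[[i]] <- analyze_subject(study, config, i, log_stage)
  }
  log_stage("assembling report")
  report <- assemble_report(subjects, config)
  log_stage("done")
  report
}

# Full single-subject analysis, all reviewers.
analyze_subject <- function(study, config, i, log_stage = function(...) NULL) {
  cfg <- study$config
  truth <- study$truth

  # ADC mapping
  maps <- lapply(study$dwi, function(d) fit_adc(study$b0, d, cfg$b_value))
  adc <- trace_adc(maps$x, maps$y, maps$z)

  # phase matching + registration (cine pair; transform applied to LGE)
  log_stage("subject ", i, ": registration")
  p_b0 <- select_matching_phase(study$cine, study$b0)
  p_lge <- select_matching_phase(study$cine, study$lge)
  src <- list(); dst <- list()
  for (s in seq_len(n_slices(study$b0))) {
    cb <- study$cine$contours[[p_b0 + 1L]][[s]]
    cl <- study$cine$contours[[p_lge + 1L]][[s]]
    src[[s]] <- rbind(contour_landmarks(cb$endo, config$landmarks_per_contour),
                      contour_landmarks(cb$epi, config$landmarks_per_contour))
    dst[[s]] <- rbind(contour_landmarks(cl$endo, config$landmarks_per_contour),
                      contour_landmarks(cl$epi, config$landmarks_per_contour))
  }
  xfm <- fit_bspline(src, dst, grid_spacing = config$grid_spacing,
                     lambda = config$lambda,
                     domain = c(0, cfg$fov, 0, cfg$fov))
  lge_reg <- apply_transform(study$lge, xfm)

  # classification, per reviewer and modality
  log_stage("subject ", i, ": classification")
  reviewers <- simulate_reviewers(config, i)
  ref <- truth$reference_angle
  ctr <- truth$center
  labels_dwi <- assign_segments_stack(truth$myocardium, ref, center = ctr)
  labels_lge <- assign_segments_stack(truth$myocardium_lge, ref, center = ctr)

  res <- list()
  for (rv in names(reviewers)) {
    pl <- reviewers[[rv]]
    cl_adc <- classify_map(adc, truth$myocardium, truth$infarct, config, pl,
                           ref, ctr)
    cl_lge <- classify_map(lge_reg, truth$myocardium_lge, truth$infarct_lge,
                           config, pl, ref, ctr)
    for (meth in c("threshold", "fwhm")) {
      res[[paste(rv, meth, "ADC", sep = ".")]] <- list(
        mask = cl_adc[[meth]],
        volume = infarct_volume_pct(cl_adc[[meth]], truth$myocardium),
        score = score_segments(cl_adc[[meth]], labels_dwi, "ADC", rv))
      res[[paste(rv, meth, "LGE", sep = ".")]] <- list(
        mask = cl_lge[[meth]],
        volume = infarct_volume_pct(cl_lge[[meth]], truth$myocardium_lge),
        score = score_segments(cl_lge[[meth]], labels_lge, "LGE", rv))
    }
    if (rv == "r1") {
      r1_adc <- cl_adc
      r1_roi <- cl_adc$roi
    }
  }

  # wall motion
  log_stage("subject ", i, ": wall motion")
  rwm <- chord_displacement(study$cine)
  chord_labels <- lapply(seq_along(rwm$slices), function(s) {
    aha_chord_segments(rwm$slices[[s]]$angles, aha_levels[s], ref)
  })
  akinetic <- classify_akinetic(rwm, chord_labels,
                                cutoff = config$akinesis_cutoff)

  # regional summaries (reviewer 1): ADC and RWM in remote vs infarct zones
  wedge_from <- cfg$infarct_center_deg - cfg$infarct_extent_deg / 2
  regional <- list(
    adc_remote = mean_region_adc(adc, r1_roi),
    adc_threshold = mean_region_adc(adc, r1_adc$threshold$mask),
    adc_fwhm = mean_region_adc(adc, r1_adc$fwhm$mask),
    rwm_remote = sector_rwm(rwm, config$remote_center_deg -
                              config$remote_width_deg / 2,
                            config$remote_width_deg, ref, slices = 1L),
    rwm_infarct = sector_rwm(rwm, wedge_from, cfg$infarct_extent_deg, ref,
                             slices = cfg$infarct_slices)
  )

  truth_volume <- 100 * truth$infarct_fraction
  truth_score <- score_segments(truth$infarct, labels_dwi, "truth")

  trans <- transmurality(res[["r1.fwhm.ADC"]]$mask,
                         study$b0$contours, center = ctr)

  list(results = res, akinetic = akinetic, regional = regional,
       truth_volume = truth_volume, truth_score = truth_score,
       transmural = all(trans$transmural),
       phases = c(b0 = p_b0, lge = p_lge),
       registration_rmse = xfm$residuals)
}

# Cohort-level tables.
assemble_report <- function(subjects, config) {
  nsub <- length(subjects)
  get_vols <- function(key) vapply(subjects, function(s) s$results[[key]]$volume,
                                   numeric(1))
  get_scores <- function(key) lapply(subjects, function(s) s$results[[key]]$score)
  reg <- function(field, stat) {
    vapply(subjects, function(s) s$regional[[field]][[stat]], numeric(1))
  }

  # regional table (per-subject means, summarized across the cohort)
  regional <- data.frame(
    region = c("remote", "infarct_fwhm", "infarct_threshold"),
    adc_mean = c(mean(reg("adc_remote", "mean")),
                 mean(reg("adc_fwhm", "mean")),
                 mean(reg("adc_threshold", "mean"))),
    adc_sd = c(stats::sd(reg("adc_remote", "mean")),
               stats::sd(reg("adc_fwhm", "mean")),
               stats::sd(reg("adc_threshold", "mean"))),
    rwm_mean = c(mean(reg("rwm_remote", "mean")), mean(reg("rwm_infarct", "mean")),
                 mean(reg("rwm_infarct", "mean"))),
    rwm_sd = c(stats::sd(reg("rwm_remote", "mean")),
               stats::sd(reg("rwm_infarct", "mean")),
               stats::sd(reg("rwm_infarct", "mean")))
  )
  regional_tests <- if (nsub >= 5) {
    list(
      adc_fwhm_vs_remote = wilcoxon_signed_rank(reg("adc_fwhm", "mean"),
                                                reg("adc_remote", "mean")),
      adc_threshold_vs_remote = wilcoxon_signed_rank(
        reg("adc_threshold", "mean"), reg("adc_remote", "mean")),
      rwm_infarct_vs_remote = wilcoxon_signed_rank(reg("rwm_infarct", "mean"),
                                                   reg("rwm_remote", "mean"))
    )
  } else {
    NULL
  }

  # per-subject volumes, long format, with ground truth
  vol_rows <- list()
  for (rv in c("r1", "r2", "r1re")) {
    for (meth in c("threshold", "fwhm")) {
      for (mod in c("ADC", "LGE")) {
        key <- paste(rv, meth, mod, sep = ".")
        vol_rows[[key]] <- data.frame(
          subject = seq_len(nsub), reviewer = rv, method = meth,
          modality = mod, volume_pct = get_vols(key),
          truth_pct = vapply(subjects, `[[`, numeric(1), "truth_volume"))
      }
    }
  }
  volumes <- do.call(rbind, c(vol_rows, list(make.row.names = FALSE)))

  # paired volume comparisons
  pair_report <- function(xkey, ykey, label) {
    x <- get_vols(xkey); y <- get_vols(ykey)
    data.frame(comparison = label,
               icc = tryCatch(icc(x, y), error = function(e) NA_real_),
               r_squared = stats::cor(x, y)^2,
               bias_pct = mean(x - y))
  }
  volume_comparisons <- rbind(
    pair_report("r1.fwhm.ADC", "r1.fwhm.LGE", "ADC vs LGE, FWHM, R1"),
    pair_report("r1.threshold.ADC", "r1.threshold.LGE", "ADC vs LGE, threshold, R1"),
    pair_report("r1re.fwhm.ADC", "r1re.fwhm.LGE", "ADC vs LGE, FWHM, R1 repeat"),
    pair_report("r1re.threshold.ADC", "r1re.threshold.LGE",
                "ADC vs LGE, threshold, R1 repeat"),
    pair_report("r2.fwhm.ADC", "r2.fwhm.LGE", "ADC vs LGE, FWHM, R2"),
    pair_report("r2.threshold.ADC", "r2.threshold.LGE", "ADC vs LGE, threshold, R2"),
    pair_report("r1.fwhm.ADC", "r2.fwhm.ADC", "ADC R1 vs R2, FWHM"),
    pair_report("r1.threshold.ADC", "r2.threshold.ADC", "ADC R1 vs R2, threshold"),
    pair_report("r1.fwhm.LGE", "r2.fwhm.LGE", "LGE R1 vs R2, FWHM"),
    pair_report("r1.threshold.LGE", "r2.threshold.LGE", "LGE R1 vs R2, threshold"),
    pair_report("r1.fwhm.ADC", "r1re.fwhm.ADC", "ADC R1 vs R1 repeat, FWHM"),
    pair_report("r1.fwhm.LGE", "r1re.fwhm.LGE", "LGE R1 vs R1 repeat, FWHM")
  )

  # location agreement per reviewer and method (ADC vs LGE gold standard)
  alpha_loc <- 0.05 / config$bonferroni_m
  loc_rows <- list()
  for (rv in c("r1", "r2")) {
    for (meth in c("fwhm", "threshold")) {
      sa <- get_scores(paste(rv, meth, "ADC", sep = "."))
      sl <- get_scores(paste(rv, meth, "LGE", sep = "."))
      rep_ <- agreement_report(
        get_vols(paste(rv, meth, "ADC", sep = ".")),
        get_vols(paste(rv, meth, "LGE", sep = ".")),
        sa, sl, alpha = 0.05, m = config$bonferroni_m)
      n_adc <- sum(unlist(sa)); n_lge <- sum(unlist(sl))
      seg_test <- if (nsub >= 5) {
        tryCatch(wilcoxon_signed_rank(
          vapply(sa, sum, numeric(1)), vapply(sl, sum, numeric(1)),
          alpha = alpha_loc),
          error = function(e) list(p = NA_real_, significant = FALSE))
      } else {
        list(p = NA_real_, significant = FALSE)
      }
      loc_rows[[paste(rv, meth)]] <- data.frame(
        reviewer = rv, method = meth,
        a = rep_$table$a, b = rep_$table$b, c = rep_$table$c, d = rep_$table$d,
        n_segments = rep_$table$n,
        agreement_count = rep_$agreement$count,
        agreement_pct = rep_$agreement$percent,
        kappa = rep_$kappa,
        wilcoxon_p = seg_test$p,
        significant = seg_test$significant,
        n_lge_segments = n_lge, n_adc_segments = n_adc,
        sensitivity = rep_$diagnostics$sensitivity,
        specificity = rep_$diagnostics$specificity,
        ppv = rep_$diagnostics$ppv, npv = rep_$diagnostics$npv)
    }
  }
  location <- do.call(rbind, c(loc_rows, list(make.row.names = FALSE)))

  akinetic_scores <- lapply(subjects, `[[`, "akinetic")
  n_akinetic <- sum(unlist(akinetic_scores))
  truth_scores <- lapply(subjects, `[[`, "truth_score")

  structure(list(
    regional = regional,
    regional_tests = regional_tests,
    volumes = volumes,
    volume_comparisons = volume_comparisons,
    location = location,
    akinetic = list(scores = akinetic_scores, n_segments = n_akinetic),
    truth = list(scores = truth_scores,
                 volume_pct = vapply(subjects, `[[`, numeric(1), "truth_volume")),
    transmural = vapply(subjects, `[[`, logical(1), "transmural"),
    per_subject = subjects,
    config = config
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", length(x$per_subject), "subjects\n\nRegional values:\n")
  print(x$regional, row.names = FALSE, digits = 3)
  cat("\nVolume comparisons:\n")
  print(x$volume_comparisons, row.names = FALSE, digits = 3)
  cat("\nLocation agreement (ADC vs LGE):\n")
  print(x$location[, c("reviewer", "method", "agreement_count", "n_segments",
                       "kappa", "n_lge_segments", "n_adc_segments")],
        row.names = FALSE, digits = 3)
  cat("\nAkinetic segments:", x$akinetic$n_segments, "\n")
  invisible(x)
}

#' Write the study report to disk
#'
#' CSV tables plus a versioned JSON summary.
#'
#' @param report a `study_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$regional, file.path(dir, "regional.csv"),
                   row.names = FALSE)
  utils::write.csv(report$volumes, file.path(dir, "volumes.csv"),
                   row.names = FALSE)
  utils::write.csv(report$volume_comparisons,
                   file.path(dir, "volume_comparisons.csv"), row.names = FALSE)
  utils::write.csv(report$location, file.path(dir, "location.csv"),
                   row.names = FALSE)
  scores <- do.call(rbind, lapply(seq_along(report$truth$scores), function(i) {
    data.frame(subject = i, segment = 1:16,
               truth = as.integer(report$truth$scores[[i]]),
               akinetic = as.integer(report$akinetic$scores[[i]]))
  }))
  utils::write.csv(scores, file.path(dir, "segment_scores.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(schema_version = "1.0",
         cohort = report$config$cohort,
         seed = report$config$seed,
         regional = report$regional,
         volume_comparisons = report$volume_comparisons,
         location = report$location,
         n_akinetic_segments = report$akinetic$n_segments,
         all_transmural = all(report$transmural)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(dir)
}
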