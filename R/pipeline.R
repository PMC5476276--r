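# Orchestration: simulate -> (segment) -> quantify -> compare -> report.

#' Pipeline run configuration
#'
#' @param cohort a [cohort_spec()] describing the cohort to simulate.
#' @param analysis an [analysis_config()].
#' @param mode `"truth"` quantifies each subject from its generator ground
#'   truth using the closed-form signal model (the scale at which replicated
#'   cohort studies run); `"volumes"` renders full voxel volumes and runs the
#'   built-in segmentation for every subject.
#' @param seg a [segmentation_config()] (volumes mode).
#' @param alpha significance level used when reporting.
#' @param seed integer seed; recorded in all outputs.
#' @param out_dir optional output directory; when set, all result tables are
#'   written as CSV alongside a JSON copy of the configuration and a run log.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_spec(), analysis = analysis_config(),
                       mode = c("truth", "volumes"),
                       seg = segmentation_config(),
                       alpha = 0.05, seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  structure(list(cohort = cohort, analysis = analysis, mode = mode,
                 seg = seg, alpha = alpha, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Quantify one subject
#'
#' Produces the per-subject records: thickness (um) for mRNFL, GCIPL, GCC
#' and total retina, and intensity ratio plus OIAC (1/mm) for mRNFL and
#' GCIPL, each summarized over SN/IN/ST/IT and the global average of the
#' 5 mm fovea-centered square. In truth mode, layer signals come from the
#' generator's closed-form Beer-Lambert integrals (with speckle-equivalent
#' measurement noise if the cohort requested it); in volumes mode the voxel
#' volume is segmented and integrated directly.
#'
#' @param subject one element of an `oct_cohort`.
#' @param analysis an [analysis_config()].
#' @param mode `"truth"` or `"volumes"`.
#' @param seg a [segmentation_config()] (volumes mode).
#' @param measurement_noise add per-A-line noise to truth-mode integrals.
#' @return Data frame with columns `subject_id, group, metric, layer,
#'   region, value, n_alines, n_excluded`.
#' @export
subject_metrics <- function(subject, analysis = analysis_config(),
                            mode = "truth", seg = segmentation_config(),
                            measurement_noise = TRUE) {
  spec <- subject$truth$spec
  vs <- spec$voxel_size
  if (mode == "volumes") {
    stopifnot(!is.null(subject$volume))
    segres <- segment_surfaces(subject$volume, seg)
    if (is.null(segres$surfaces))
      stop("segmentation failed for subject ", subject$meta$subject_id)
    surfaces <- segres$surfaces
  } else {
    surfaces <- subject$truth$surfaces
  }
  fov <- locate_fovea(surfaces, vs)
  grid <- make_quadrant_grid(fov, dim(surfaces)[1:2], vs,
                             subject$meta$laterality)
  th <- lapply(names(analysis_layers()), function(l)
    thickness_map(surfaces, l, vs))
  names(th) <- names(analysis_layers())

  if (mode == "volumes") {
    ratio <- list(
      mRNFL = intensity_ratio_map(subject$volume, surfaces, "mRNFL",
                                  analysis$reference_layer),
      GCIPL = intensity_ratio_map(subject$volume, surfaces, "GCIPL",
                                  analysis$reference_layer))
    oiac <- list(
      mRNFL = oiac_map(subject$volume, surfaces, "mRNFL", analysis),
      GCIPL = oiac_map(subject$volume, surfaces, "GCIPL", analysis))
  } else {
    sig <- sampled_layer_signals(subject$truth,
                                 measurement_noise = measurement_noise)
    dmm <- lapply(th, function(m) m / 1000)
    comp <- function(members) {
      S <- sig[, , members[1]]
      for (m in members[-1]) S <- S + sig[, , m]
      S
    }
    d_single <- lapply(oct_layers(), function(l)
      thickness_map(surfaces, l, vs) / 1000)
    names(d_single) <- oct_layers()
    S_ref <- comp(analysis$reference_layer)
    d_ref <- d_single[[analysis$reference_layer]]
    members <- list(mRNFL = "RNFL", GCIPL = c("GCL", "IPL"))
    ratio <- list(); oiac <- list()
    for (l in names(members)) {
      S <- comp(members[[l]])
      d <- dmm[[l]]
      mean_ratio <- (S / d) / (S_ref / d_ref)
      bad <- !is.finite(mean_ratio) | S_ref <= 0 | d_ref <= 0
      mean_ratio[bad] <- NA_real_
      mu <- oiac_from_rd(S / S_ref, d, analysis$beta, analysis$log_base)
      mu[!is.finite(mu) | d < analysis$min_thickness_um / 1000] <- NA_real_
      ratio[[l]] <- mean_ratio
      oiac[[l]] <- mu
    }
  }

  rows <- list()
  add <- function(metric, layer, map) {
    rv <- region_values(map, grid)
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = subject$meta$subject_id, group = subject$meta$group,
      metric = metric, layer = layer,
      region = names(rv$values), value = unname(rv$values),
      n_alines = unname(rv$n), n_excluded = rv$n_excluded,
      stringsAsFactors = FALSE)
  }
  for (l in names(th)) add("thickness", l, th[[l]])
  for (l in names(ratio)) add("intensity_ratio", l, ratio[[l]])
  for (l in names(oiac)) add("oiac", l, oiac[[l]])
  do.call(rbind, rows)
}

#' Group comparison table over all metric/layer/region combinations
#'
#' One [compare_groups()] row per metric x layer x region present in the
#' records; mean +/- SD per group, the test used, and the p-value.
#'
#' @param records row-bound [subject_metrics()] output for a cohort.
#' @return Data frame, one row per comparison.
#' @export
compare_metrics <- function(records) {
  keys <- unique(records[, c("metric", "layer", "region")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sel <- records$metric == k$metric & records$layer == k$layer &
      records$region == k$region
    x <- records$value[sel & records$group == "patient"]
    y <- records$value[sel & records$group == "control"]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    cg <- compare_groups(x, y)
    data.frame(metric = k$metric, layer = k$layer, region = k$region,
               patient_mean = cg$mean[1], patient_sd = cg$sd[1],
               control_mean = cg$mean[2], control_sd = cg$sd[2],
               test = cg$test, statistic = cg$statistic, p = cg$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# intensity-ratio vs thickness correlations per group (mRNFL, GCIPL)
.correlation_table <- function(records) {
  out <- list()
  for (g in c("patient", "control")) for (l in c("mRNFL", "GCIPL")) {
    for (r in c(REGIONS, "Average")) {
      sel <- records$group == g & records$layer == l & records$region == r
      th <- records$value[sel & records$metric == "thickness"]
      ir <- records$value[sel & records$metric == "intensity_ratio"]
      ids_t <- records$subject_id[sel & records$metric == "thickness"]
      ids_r <- records$subject_id[sel & records$metric == "intensity_ratio"]
      stopifnot(identical(ids_t, ids_r))
      pr <- pearson_r(ir, th)
      out[[length(out) + 1L]] <- data.frame(
        group = g, layer = l, region = r, r = pr$r, p = pr$p, n = pr$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# ROC table (thickness mRNFL/GCC, OIAC mRNFL) + paired thickness-vs-OIAC
.roc_tables <- function(records) {
  vars <- rbind(
    expand.grid(metric = "thickness", layer = c("mRNFL", "GCC"),
                region = c(REGIONS, "Average"), stringsAsFactors = FALSE),
    expand.grid(metric = "oiac", layer = "mRNFL",
                region = c(REGIONS, "Average"), stringsAsFactors = FALSE))
  rocs <- list()
  tab <- lapply(seq_len(nrow(vars)), function(i) {
    k <- vars[i, ]
    sel <- records$metric == k$metric & records$layer == k$layer &
      records$region == k$region
    rr <- roc_auc_delong(records$value[sel], records$group[sel])
    rocs[[paste(k$metric, k$layer, k$region, sep = "_")]] <<- rr
    data.frame(metric = k$metric, layer = k$layer, region = k$region,
               auc = rr$auc, se = rr$se, ci_lo = rr$ci[1], ci_hi = rr$ci[2],
               z = rr$z, p = rr$p, direction = rr$direction,
               stringsAsFactors = FALSE)
  })
  pairs <- lapply(c("SN", "ST", "Average"), function(r) {
    a <- rocs[[paste("thickness", "mRNFL", r, sep = "_")]]
    b <- rocs[[paste("oiac", "mRNFL", r, sep = "_")]]
    dd <- delong_paired_compare(a, b)
    data.frame(region = r, delta_auc = dd$delta_auc, se = dd$se,
               ci_lo = dd$ci[1], ci_hi = dd$ci[2], z = dd$z, p = dd$p,
               stringsAsFactors = FALSE)
  })
  list(roc = do.call(rbind, tab), roc_pairs = do.call(rbind, pairs))
}

# demographics and image-quality comparison (age t, sex chi-square, quality t)
.demographics_table <- function(meta) {
  xs <- meta[meta$group == "patient", ]
  ys <- meta[meta$group == "control", ]
  age <- compare_groups(xs$age, ys$age)
  qual <- compare_groups(xs$quality, ys$quality)
  sex_tab <- table(factor(meta$group, c("patient", "control")),
                   factor(meta$sex, c("M", "F")))
  sex <- chi_square_2x2(sex_tab)
  data.frame(
    variable = c("age", "sex_male_female", "quality"),
    patient = c(sprintf("%.2f±%.2f", age$mean[1], age$sd[1]),
                sprintf("%d/%d", sex_tab[1, 1], sex_tab[1, 2]),
                sprintf("%.2f±%.2f", qual$mean[1], qual$sd[1])),
    control = c(sprintf("%.2f±%.2f", age$mean[2], age$sd[2]),
                sprintf("%d/%d", sex_tab[2, 1], sex_tab[2, 2]),
                sprintf("%.2f±%.2f", qual$mean[2], qual$sd[2])),
    test = c(age$test, "chisq", qual$test),
    p = c(age$p, sex$p, qual$p),
    stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Simulate -> (segment) -> quantify -> compare: generates the cohort,
#' quantifies every subject ([subject_metrics()]), and assembles the
#' demographics table, group-comparison tables for thickness, intensity
#' ratio and OIAC, the intensity-ratio-vs-thickness correlation table, the
#' ROC table with DeLong confidence intervals, and the paired
#' thickness-vs-OIAC AUC comparisons. Deterministic given the seed; with
#' `out_dir` set, all tables are written as CSV together with the
#' configuration and a run log. Precomputed `records` can be passed so
#' statistics options can change without re-simulating.
#'
#' @param config a [run_config()].
#' @param records optional precomputed [subject_metrics()] rows.
#' @return List of class `oct_result_bundle` with elements `records`,
#'   `meta`, `demographics`, `comparisons`, `correlations`, `roc`,
#'   `roc_pairs`, `qc`, `seed`, `config`.
#' @export
run_pipeline <- function(config = run_config(), records = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_lines <- c(sprintf("octquant run, seed %d, mode %s",
                         config$seed, config$mode))
  set.seed(config$seed)
  cohort_sp <- config$cohort
  cohort_sp$seed <- config$seed
  cohort <- generate_cohort(cohort_sp, volumes = config$mode == "volumes")
  meta <- cohort_meta(cohort)
  log_lines <- c(log_lines, sprintf("simulated %d subjects (%s)",
                                    nrow(meta), format(Sys.time() - t0)))
  if (is.null(records)) {
    set.seed(config$seed + 1L)
    records <- do.call(rbind, lapply(cohort, function(s) {
      tryCatch(
        subject_metrics(s, config$analysis, config$mode, config$seg,
                        measurement_noise = cohort_sp$measurement_noise),
        error = function(e) stop("quantification failed for subject ",
                                 s$meta$subject_id, ": ",
                                 conditionMessage(e)))
    }))
  }
  log_lines <- c(log_lines,
                 sprintf("quantified: %d records, %d masked A-line groups",
                         nrow(records), sum(records$n_excluded > 0)))
  demographics <- .demographics_table(meta)
  comparisons <- compare_metrics(records)
  correlations <- .correlation_table(records)
  rt <- .roc_tables(records)
  qc <- data.frame(subject_id = meta$subject_id,
                   clamped_alines = vapply(cohort, function(s)
                     as.numeric(s$meta$clamped_alines), numeric(1)))
  bundle <- structure(list(records = records, meta = meta,
                           demographics = demographics,
                           comparisons = comparisons,
                           correlations = correlations,
                           roc = rt$roc, roc_pairs = rt$roc_pairs,
                           qc = qc, seed = config$seed, config = config,
                           log = c(log_lines,
                                   sprintf("done (%s)",
                                           format(Sys.time() - t0)))),
                      class = "oct_result_bundle")
  if (!is.null(config$out_dir)) .write_bundle(bundle, config$out_dir)
  bundle
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  wr(bundle$records, "records")
  wr(bundle$meta, "subjects")
  wr(bundle$demographics, "demographics")
  wr(bundle$comparisons, "comparisons")
  wr(bundle$correlations, "correlations")
  wr(bundle$roc, "roc")
  wr(bundle$roc_pairs, "roc_pairs")
  wr(bundle$qc, "qc")
  cfg <- bundle$config
  jsonlite::write_json(
    list(seed = bundle$seed, mode = cfg$mode, alpha = cfg$alpha,
         beta = cfg$analysis$beta,
         reference_layer = cfg$analysis$reference_layer,
         n_patient = cfg$cohort$n_patient,
         n_control = cfg$cohort$n_control),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
  writeLines(bundle$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Render a human-readable summary of a result bundle
#'
#' Markdown summary with the study-style mean +/- SD formatting (two
#' decimals). Missing tables are listed explicitly rather than silently
#' skipped.
#'
#' @param bundle an `oct_result_bundle`.
#' @param path optional file to write the text to.
#' @return Character vector of markdown lines, invisibly if `path` given.
#' @export
render_report <- function(bundle, path = NULL) {
  fmt <- function(m, s) sprintf("%.2f±%.2f", m, s)
  lines <- c(sprintf("# octquant report (seed %d)", bundle$seed), "")
  need <- c("demographics", "comparisons", "correlations", "roc",
            "roc_pairs", "records")
  missing <- need[vapply(need, function(n)
    is.null(bundle[[n]]) || nrow(bundle[[n]]) == 0, logical(1))]
  if (length(missing))
    lines <- c(lines,
               paste("**Missing tables:**", paste(missing, collapse = ", ")),
               "")
  if (!"demographics" %in% missing) {
    lines <- c(lines, "## Demographics and image quality", "",
               "| Variable | Patient | Control | p |", "|---|---|---|---|",
               sprintf("| %s | %s | %s | %.3f |",
                       bundle$demographics$variable, bundle$demographics$patient,
                       bundle$demographics$control, bundle$demographics$p), "")
  }
  if (!"comparisons" %in% missing) {
    for (met in unique(bundle$comparisons$metric)) {
      cm <- bundle$comparisons[bundle$comparisons$metric == met, ]
      lines <- c(lines, sprintf("## Group comparison: %s", met), "",
                 "| Layer | Region | Patient | Control | Test | p |",
                 "|---|---|---|---|---|---|",
                 sprintf("| %s | %s | %s | %s | %s | %.3f |",
                         cm$layer, cm$region,
                         fmt(cm$patient_mean, cm$patient_sd),
                         fmt(cm$control_mean, cm$control_sd),
                         cm$test, cm$p), "")
    }
  }
  if (!"correlations" %in% missing) {
    co <- bundle$correlations
    lines <- c(lines, "## Intensity ratio vs thickness (Pearson)", "",
               "| Group | Layer | Region | r | p |", "|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %.3f | %.3f |",
                       co$group, co$layer, co$region, co$r, co$p), "")
  }
  if (!"roc" %in% missing) {
    ro <- bundle$roc
    lines <- c(lines, "## ROC analysis (DeLong)", "",
               "| Metric | Layer | Region | AUC (SE) | 95% CI | z | p |",
               "|---|---|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %.3f (%.4f) | %.3f-%.3f | %.3f | %.4f |",
                       ro$metric, ro$layer, ro$region, ro$auc, ro$se,
                       ro$ci_lo, ro$ci_hi, ro$z, ro$p), "")
  }
  if (!"roc_pairs" %in% missing) {
    rp <- bundle$roc_pairs
    lines <- c(lines, "## Paired AUC: mRNFL thickness vs OIAC", "",
               "| Region | dAUC (SE) | 95% CI | z | p |", "|---|---|---|---|---|",
               sprintf("| %s | %.3f (%.4f) | %.3f-%.3f | %.3f | %.4f |",
                       rp$region, rp$delta_auc, rp$se, rp$ci_lo, rp$ci_hi,
                       rp$z, rp$p), "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
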