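## Orchestration of the study designs at desk scale: intra-site
## age-group cross-testing with fine-tuning, inter-site harmonization
## versus fine-tuning with 1/2/5/10 target subjects, the from-scratch
## ablation, and split-half gold-standard consistency.

#' Experiment configuration
#'
#' Bundles the two site profiles, the shared FA maturation model,
#' cohort sizes and splits, age-group bounds, the estimator and
#' harmonization settings, and the master seed.  Desk-scale defaults
#' (24^3 volumes, 20 subjects per site split 14/3/3, 12 subjects per
#' intra-site age group split 8/2/2) keep a full inter-site run in the
#' minutes range on one CPU while preserving the study's split ratios.
#'
#' @param source_site,target_site [site_profile()]s (defaults: a
#'   dHCP-like neonatal site and a BCP-like baby site with a smooth
#'   gain/offset signal shift).
#' @param model shared [age_model()] FA maturation curve.
#' @param source_age_range,target_age_range postnatal-month ranges.
#' @param n_per_site,split cohort size and train/val/test counts.
#' @param n_per_group,group_split intra-site age-group cohort sizing.
#' @param age_groups named list: per site, `young` and `old` month
#'   ranges.
#' @param n_target target-subject counts for harmonization/fine-tuning.
#' @param n_finetune_intra target subjects for intra-site fine-tuning.
#' @param estimator an [estimator_config()].
#' @param smoothing_sigma,var_floor harmonization settings.
#' @param spec a [region_spec()].
#' @param grid_shape phantom dimensions.
#' @param peak_params peak-extraction arguments used by every arm.
#' @param seed master seed.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(source_site = NULL, target_site = NULL,
                              model = age_model(),
                              source_age_range = c(-2.5, 1.0),
                              target_age_range = c(1.5, 60),
                              n_per_site = 20L,
                              split = c(train = 14L, val = 3L, test = 3L),
                              n_per_group = 12L,
                              group_split = c(train = 8L, val = 2L, test = 2L),
                              age_groups = list(
                                dhcp = list(young = c(-3.1, -1.2),
                                            old = c(0.0, 1.0)),
                                bcp = list(young = c(0.5, 11),
                                           old = c(20, 36))),
                              n_target = c(1L, 2L, 5L, 10L),
                              n_finetune_intra = 5L,
                              estimator = estimator_config(),
                              smoothing_sigma = 1, var_floor = 1e-6,
                              spec = region_spec(),
                              grid_shape = c(24L, 24L, 24L),
                              peak_params = list(), seed = 1L) {
  source_site <- source_site %||%
    site_profile("dhcp", dhcp_scheme(), rician_sigma = 0.02,
                 gain_amp = 0.05, subject_jitter = 0.05)
  ## the target site differs in gradient scheme, smooth gain field and a
  ## strong additive baseline; because the six-direction pipeline
  ## normalizes by b0, a large offset is what actually shifts the input
  ## contrast the model sees
  target_site <- target_site %||%
    site_profile("bcp", bcp_scheme(), rician_sigma = 0.02,
                 gain_base = 1.0, gain_amp = 0.25,
                 offset_frac = 0.45, offset_amp = 0.05,
                 subject_jitter = 0.05)
  if (sum(split) > n_per_site) stop2("split exceeds cohort size")
  if (sum(group_split) > n_per_group) stop2("group_split exceeds group size")
  structure(list(source_site = source_site, target_site = target_site,
                 model = model,
                 source_age_range = source_age_range,
                 target_age_range = target_age_range,
                 n_per_site = as.integer(n_per_site), split = split,
                 n_per_group = as.integer(n_per_group),
                 group_split = group_split, age_groups = age_groups,
                 n_target = as.integer(n_target),
                 n_finetune_intra = as.integer(n_finetune_intra),
                 estimator = estimator, smoothing_sigma = smoothing_sigma,
                 var_floor = var_floor, spec = spec,
                 grid_shape = as.integer(grid_shape),
                 peak_params = peak_params, seed = as.integer(seed)),
            class = "experiment_config")
}

## Stable short hash of a configuration (provenance only).
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

## Split a cohort into train/val/test sublists (seeded shuffle).
split_cohort <- function(cohort, split, seed) {
  n <- length(cohort)
  o <- with_seed(seed, sample(n))
  tr <- o[seq_len(split[["train"]])]
  vl <- o[split[["train"]] + seq_len(split[["val"]])]
  te <- o[split[["train"]] + split[["val"]] + seq_len(split[["test"]])]
  list(train = cohort[tr], val = cohort[vl], test = cohort[te])
}

subject_ids <- function(subjects) vapply(subjects, `[[`, 0, "seed")

## Evaluate a model on test subjects; GT peaks are extracted once per
## subject and shared across arms through the cache environment.
eval_arm <- function(model, subjects, six_indices, peak_params, cache) {
  reports <- lapply(subjects, function(s) {
    key <- paste0("gt-", s$seed)
    if (is.null(cache[[key]])) {
      vox <- which(s$wm_mask)
      cache[[key]] <- do.call(extract_peaks_field,
                              c(list(s$gt_fod$coefficients[, vox, drop = FALSE]),
                                peak_params))
    }
    pred <- predict_fod(model, s, six_indices = six_indices)
    evaluate_fods(s$gt_fod, pred, s$wm_mask, peak_params = peak_params,
                  gt_peaks = cache[[key]])
  })
  mean_metrics(reports)
}

assert_no_leakage <- function(test_subjects, ...) {
  test_ids <- subject_ids(test_subjects)
  for (set in list(...)) {
    if (length(set) && any(subject_ids(set) %in% test_ids)) {
      stop2("data leakage: a test subject appears in a training set")
    }
  }
  invisible(TRUE)
}

#' Inter-site domain-shift experiment
#'
#' Trains a baseline model on the source site, then for the source-to-
#' target direction evaluates: self-test (source test subjects, upper
#' bound), raw cross-test (target test subjects, lower bound),
#' Method-of-Moments harmonization with n target training subjects
#' (test data mapped toward the source site, original model), fine-
#' tuning with the same n (original test data, adapted model), and the
#' from-scratch ablation (a model trained only on 10 target training
#' subjects).  Target-subject subsets are nested across n.  MoM arms
#' never modify model parameters and FT arms never modify test signals.
#'
#' @param config an [experiment_config()].
#' @param directions which transfer directions to run:
#'   `"source_to_target"`, `"target_to_source"` or both.
#' @param cohorts optional precomputed list with `source` and `target`
#'   cohorts (regenerated from the config seed when NULL).
#' @return object of class `study_report`.
#' @export
run_inter_site <- function(config,
                           directions = c("source_to_target",
                                          "target_to_source"),
                           cohorts = NULL) {
  directions <- match.arg(directions, several.ok = TRUE)
  seed <- config$seed
  if (is.null(cohorts)) {
    cohorts <- list(
      source = generate_cohort(config$n_per_site, config$source_age_range,
                               config$source_site, config$model,
                               spec = config$spec, seed = seed,
                               grid_shape = config$grid_shape),
      target = generate_cohort(config$n_per_site, config$target_age_range,
                               config$target_site, config$model,
                               spec = config$spec, seed = seed,
                               grid_shape = config$grid_shape))
  }
  arms <- list()
  prov_dirs <- list()
  for (dir_ in directions) {
    if (dir_ == "source_to_target") {
      src_prof <- config$source_site; tgt_prof <- config$target_site
      src_coh <- cohorts$source; tgt_coh <- cohorts$target
    } else {
      src_prof <- config$target_site; tgt_prof <- config$source_site
      src_coh <- cohorts$target; tgt_coh <- cohorts$source
    }
    tag <- function(x) paste0(dir_, ".", x)
    six_src <- select_six_directions(src_prof$scheme)
    six_tgt <- select_six_directions(tgt_prof$scheme)
    src <- split_cohort(src_coh, config$split, derive_seed(seed, tag("split-src")))
    tgt <- split_cohort(tgt_coh, config$split, derive_seed(seed, tag("split-tgt")))
    assert_no_leakage(c(src$test, tgt$test), src$train, src$val, tgt$train, tgt$val)

    est_cfg <- config$estimator
    est_cfg$seed <- derive_seed(seed, tag("train"))
    base <- train_estimator(est_cfg, src$train, src$val, six_src)
    cache <- new.env(parent = emptyenv())
    pp <- config$peak_params

    arms[[tag("self")]] <- eval_arm(base, src$test, six_src, pp, cache)
    arms[[tag("cross")]] <- eval_arm(base, tgt$test, six_tgt, pp, cache)

    ## nested target-subject sampling: the n-subject set is the first n
    ## of one seeded shuffle of the target training split
    ord <- with_seed(derive_seed(seed, tag("nested")), sample(length(tgt$train)))
    ref_maps <- compute_moment_maps(src$train, six_src,
                                    smoothing_sigma = config$smoothing_sigma)
    for (n in config$n_target) {
      if (n > length(tgt$train)) stop2("n_target exceeds target training split")
      tgt_n <- tgt$train[ord[seq_len(n)]]
      ## --- MoM(n): harmonize test data toward the source site ---
      tgt_maps <- compute_moment_maps(tgt_n, six_tgt,
                                      smoothing_sigma = config$smoothing_sigma)
      hfield <- derive_mapping(tgt_maps, ref_maps, var_floor = config$var_floor)
      harm_test <- lapply(tgt$test, harmonize_subject, field = hfield,
                          six_indices = six_tgt)
      arms[[tag(paste0("mom_", n))]] <-
        eval_arm(base, harm_test, six_tgt, pp, cache)
      ## --- FT(n): adapt the model, keep test data original ---
      ft <- finetune_estimator(base, tgt_n, six_indices = six_tgt)
      arms[[tag(paste0("ft_", n))]] <- eval_arm(ft, tgt$test, six_tgt, pp, cache)
    }
    ## --- scratch ablation: train only on 10 target training subjects ---
    n_scr <- min(10L, length(tgt$train))
    scr_cfg <- config$estimator
    scr_cfg$seed <- derive_seed(seed, tag("scratch"))
    scratch <- train_estimator(scr_cfg, tgt$train[ord[seq_len(n_scr)]],
                               tgt$val, six_tgt)
    arms[[tag(paste0("scratch_", n_scr))]] <-
      eval_arm(scratch, tgt$test, six_tgt, pp, cache)

    prov_dirs[[dir_]] <- list(
      source = src_prof$name, target = tgt_prof$name,
      six_source = six_src, six_target = six_tgt,
      train_ids = subject_ids(src$train), val_ids = subject_ids(src$val),
      test_ids = subject_ids(src$test),
      target_train_ids = subject_ids(tgt$train),
      target_val_ids = subject_ids(tgt$val),
      target_test_ids = subject_ids(tgt$test),
      nested_order = ord)
  }
  structure(list(kind = "inter_site", arms = arms,
                 provenance = list(seed = seed,
                                   config_hash = config_hash(config),
                                   directions = prov_dirs)),
            class = "study_report")
}

#' Intra-site age-group experiment
#'
#' Generates young and old cohorts for one site, trains an estimator
#' per age group, and evaluates the four train-test combinations
#' (self-tests as upper bounds, cross-age tests) plus fine-tuned
#' cross-age arms using `n_finetune_intra` subjects from the target age
#' group's training split.
#'
#' @param config an [experiment_config()].
#' @param site `"source"` or `"target"` (which site profile to use).
#' @return a `study_report` with arms `y_to_y`, `y_to_o`, `o_to_y`,
#'   `o_to_o`, `y_to_o_ft`, `o_to_y_ft`.
#' @export
run_intra_site <- function(config, site = c("source", "target")) {
  site <- match.arg(site)
  prof <- if (site == "source") config$source_site else config$target_site
  groups <- config$age_groups[[prof$name]] %||% config$age_groups[[1]]
  seed <- config$seed
  six <- select_six_directions(prof$scheme)
  coh <- lapply(c(young = "young", old = "old"), function(g) {
    generate_cohort(config$n_per_group, groups[[g]], prof, config$model,
                    spec = config$spec,
                    seed = derive_seed(seed, paste0("intra-", prof$name, "-", g)),
                    grid_shape = config$grid_shape)
  })
  sp <- lapply(names(coh), function(g) {
    split_cohort(coh[[g]], config$group_split,
                 derive_seed(seed, paste0("intra-split-", g)))
  })
  names(sp) <- names(coh)
  assert_no_leakage(c(sp$young$test, sp$old$test),
                    sp$young$train, sp$young$val, sp$old$train, sp$old$val)
  models <- lapply(names(sp), function(g) {
    cfg <- config$estimator
    cfg$seed <- derive_seed(seed, paste0("intra-train-", g))
    train_estimator(cfg, sp[[g]]$train, sp[[g]]$val, six)
  })
  names(models) <- names(sp)
  cache <- new.env(parent = emptyenv())
  pp <- config$peak_params
  short <- c(young = "y", old = "o")
  arms <- list()
  for (a in names(sp)) {
    for (b in names(sp)) {
      arms[[paste0(short[a], "_to_", short[b])]] <-
        eval_arm(models[[a]], sp[[b]]$test, six, pp, cache)
    }
  }
  for (pair in list(c("young", "old"), c("old", "young"))) {
    a <- pair[1]; b <- pair[2]
    n_ft <- min(config$n_finetune_intra, length(sp[[b]]$train))
    ft <- finetune_estimator(models[[a]], sp[[b]]$train[seq_len(n_ft)],
                             six_indices = six)
    arms[[paste0(short[a], "_to_", short[b], "_ft")]] <-
      eval_arm(ft, sp[[b]]$test, six, pp, cache)
  }
  structure(list(kind = "intra_site", arms = arms,
                 provenance = list(seed = seed, site = prof$name,
                                   config_hash = config_hash(config),
                                   young_ids = subject_ids(coh$young),
                                   old_ids = subject_ids(coh$old))),
            class = "study_report")
}

#' Split-half gold-standard consistency for a site
#'
#' For each test subject of a freshly generated cohort (or supplied
#' subjects), estimates the single-fiber response from ground-truth
#' single-fiber voxels, runs the split-half CSD consistency procedure
#' and reports the unweighted mean metrics across subjects.
#'
#' @param config an [experiment_config()].
#' @param site `"source"` or `"target"`.
#' @param subjects optional list of `subject_phantom`s (with fiber
#'   configurations) overriding cohort generation.
#' @param lmax CSD order.
#' @return a `metrics_report` (the GS row).
#' @export
run_gs_consistency <- function(config, site = c("source", "target"),
                               subjects = NULL, lmax = 8L) {
  site <- match.arg(site)
  prof <- if (site == "source") config$source_site else config$target_site
  if (is.null(subjects)) {
    rng <- if (site == "source") config$source_age_range else config$target_age_range
    coh <- generate_cohort(config$split[["test"]], rng, prof, config$model,
                           spec = config$spec,
                           seed = derive_seed(config$seed, "gs"),
                           grid_shape = config$grid_shape)
    subjects <- coh
  }
  reports <- lapply(subjects, function(s) {
    sf_mask <- array(s$fiber_config$n_fibers == 1L, dim = dim(s$wm_mask))
    resp <- estimate_response(s$dwi, s$scheme, sf_mask, lmax = lmax)
    split_half_consistency(s$dwi, s$scheme, resp, s$wm_mask, lmax = lmax,
                           peak_params = config$peak_params)
  })
  mean_metrics(reports)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", x$kind, "\n", sep = "")
  print(report_table(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Flatten a study report into a metrics table
#'
#' One row per arm with AR/AE columns per fiber stratum and the AFD
#' error (the layout of the standard results table).
#'
#' @param report a `study_report`.
#' @return data.frame.
#' @export
report_table <- function(report) {
  rows <- lapply(names(report$arms), function(a) {
    r <- report$arms[[a]]
    data.frame(arm = a,
               ar_1f = r$ar_by_k[1], ar_2f = r$ar_by_k[2], ar_3f = r$ar_by_k[3],
               ae_1f = r$ae_by_k[1], ae_2f = r$ae_by_k[2], ae_3f = r$ae_by_k[3],
               afd_error = r$afd_error,
               n_1f = r$n_voxels_by_k[1], n_2f = r$n_voxels_by_k[2],
               n_3f = r$n_voxels_by_k[3])
  })
  do.call(rbind, rows)
}

#' Write a study report to CSV and JSON
#'
#' @param report a `study_report` (or single `metrics_report`).
#' @param dir output directory.
#' @param formats subset of `c("csv", "json")`.
#' @return invisibly, the written paths.
#' @export
write_report <- function(report, dir, formats = c("csv", "json")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if ("csv" %in% formats) {
    p <- file.path(dir, "report.csv")
    utils::write.csv(report_table(report), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(
      list(kind = report$kind,
           arms = lapply(report$arms, unclass),
           provenance = report$provenance),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read back a study report written by [write_report()]
#'
#' @param path path to the `report.json` file.
#' @return a `study_report`.
#' @export
read_report <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  arms <- lapply(j$arms, function(a) {
    structure(list(ar_by_k = as.numeric(a$ar_by_k),
                   ae_by_k = as.numeric(a$ae_by_k),
                   afd_error = a$afd_error,
                   n_voxels_by_k = as.integer(a$n_voxels_by_k),
                   n_matched_pairs_by_k = as.integer(a$n_matched_pairs_by_k),
                   n_zero_peak_gt = as.integer(a$n_zero_peak_gt),
                   exclude_3f = a$exclude_3f),
              class = "metrics_report")
  })
  structure(list(kind = j$kind, arms = arms, provenance = j$provenance),
            class = "study_report")
}

#' Bar plot of one metric across study arms
#'
#' @param report a `study_report`.
#' @param metric `"ar"`, `"ae"` or `"afd"`.
#' @param k fiber stratum for AR/AE (default 1).
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the plotted values.
#' @export
plot_study_report <- function(report, metric = c("ar", "ae", "afd"), k = 1,
                              ...) {
  metric <- match.arg(metric)
  tab <- report_table(report)
  vals <- switch(metric,
                 ar = tab[[paste0("ar_", k, "f")]],
                 ae = tab[[paste0("ae_", k, "f")]],
                 afd = tab$afd_error)
  names(vals) <- tab$arm
  ylab <- switch(metric, ar = sprintf("Agreement rate %d-F (%%)", k),
                 ae = sprintf("Angular error %d-F (deg)", k),
                 afd = "AFD error")
  graphics::barplot(vals, las = 2, ylab = ylab, ...)
  invisible(vals)
}
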