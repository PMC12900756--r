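#' Configuration of a full pipeline run
#'
#' Collects every stage parameter with the study defaults: rings at 1-5 mm,
#' habitat k selected over 2-10, ICC threshold 0.75, correlation threshold
#' 0.9, univariate alpha 0.05, 10-fold LASSO CV, 5-fold tuning CV, 7:3
#' stratified split. All stage seeds derive deterministically from
#' `master_seed`.
#'
#' @param cohort a [cohort_config()] (default: 40 patients on a 48-voxel
#'   grid — the demo scale).
#' @param out_dir run directory for artifacts.
#' @param ring_distances_mm peritumoral distances (default 1:5).
#' @param k_range habitat cluster-count candidates (default 2:10).
#' @param icc_threshold,r_threshold,alpha,lasso_folds,cv_folds cascade and
#'   tuning thresholds.
#' @param split_ratio,stratified cohort split settings.
#' @param policy algorithm-selection policy, `"cv"` or `"paper_faithful"`.
#' @param write_images write NIfTI volumes/masks/habitat maps (default
#'   FALSE; tables and reports are always written).
#' @param master_seed master RNG seed.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = NULL, out_dir = tempfile("habrun"),
                       ring_distances_mm = 1:5, k_range = 2:10,
                       icc_threshold = 0.75, r_threshold = 0.9, alpha = 0.05,
                       lasso_folds = 10, cv_folds = 5, split_ratio = 0.7,
                       stratified = TRUE, policy = "cv",
                       write_images = FALSE, master_seed = 1L) {
  if (is.null(cohort))
    cohort <- cohort_config(n_patients = 40, grid_dim = 48,
                            tumor_radius_range_mm = list(low = c(9, 12),
                                                         high = c(11, 14)),
                            seed = master_seed)
  structure(list(cohort = cohort, out_dir = out_dir,
                 ring_distances_mm = ring_distances_mm, k_range = k_range,
                 icc_threshold = icc_threshold, r_threshold = r_threshold,
                 alpha = alpha, lasso_folds = lasso_folds,
                 cv_folds = cv_folds, split_ratio = split_ratio,
                 stratified = stratified, policy = policy,
                 write_images = write_images,
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

stage_seed <- function(config, stage) {
  offsets <- c(simulate = 11L, split = 23L, habitat = 37L, select = 53L,
               train = 71L, evaluate = 89L)
  config$master_seed * 101L + offsets[[stage]]
}

#' Run the full habitat-radiomics analysis
#'
#' Executes simulate, split, preprocess, rings, habitat, extract, impute/ICC,
#' select, train, and evaluate in order; writes per-stage artifacts and a
#' manifest to `config$out_dir`; returns the 12-model evaluation report
#' (Clinic, Intra, Peri1-5mm, HabitatH1-H3, Habitat, Combined) for the
#' training and test cohorts. Reruns with the same configuration are
#' bit-identical.
#'
#' @param config a [run_config()].
#' @param verbose print per-stage progress.
#' @return list(report = list(train, test), models, selection, habitat_model,
#'   scores, manifest).
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  # --- simulate -------------------------------------------------------------
  say("stage simulate: %d patients", config$cohort$n_patients)
  cohort <- generate_cohort(config$cohort)
  ids <- vapply(cohort, `[[`, "", "id")
  clinical <- do.call(rbind, lapply(cohort, `[[`, "clinical"))
  labels <- setNames(clinical$grade, clinical$id)
  split <- split_cohort(cohort, ratio = config$split_ratio,
                        stratified = config$stratified,
                        seed = stage_seed(config, "split"))
  train_ids <- split$train; test_ids <- split$test
  write.csv(clinical, file.path(config$out_dir, "clinical.csv"),
            row.names = FALSE)

  # --- preprocess + rings + local features ----------------------------------
  say("stage preprocess/rings/habitat features")
  pats <- lapply(cohort, function(p) {
    pp <- preprocess_volume(p$volume,
                            masks = list(m1 = p$mask_reader1,
                                         m2 = p$mask_reader2))
    rings1 <- lapply(config$ring_distances_mm, function(d)
      peritumoral_ring(pp$masks$m1, d))
    names(rings1) <- sprintf("peri%dmm", config$ring_distances_mm)
    rings2 <- lapply(config$ring_distances_mm, function(d)
      peritumoral_ring(pp$masks$m2, d))
    names(rings2) <- sprintf("peri%dmm", config$ring_distances_mm)
    fmap <- local_feature_maps(pp$volume, pp$masks$m1)
    list(id = p$id, volume = pp$volume, m1 = pp$masks$m1, m2 = pp$masks$m2,
         rings1 = rings1, rings2 = rings2, fmap = fmap)
  })
  names(pats) <- ids

  # --- habitat model (training patients only) -------------------------------
  say("stage habitat: fit on %d training patients", length(train_ids))
  hmodel <- fit_habitat_model(lapply(pats[train_ids], `[[`, "fmap"),
                              k_range = config$k_range,
                              seed = stage_seed(config, "habitat"))
  ch_selected_k <- hmodel$k
  if (hmodel$k < 3 && any(config$k_range >= 3)) {
    # the downstream model set (HabitatH1-H3 + integrated region) is defined
    # on three habitats; refit with the candidate range clipped to >= 3 and
    # record both selections in the manifest
    hmodel <- fit_habitat_model(lapply(pats[train_ids], `[[`, "fmap"),
                                k_range = config$k_range[config$k_range >= 3],
                                seed = stage_seed(config, "habitat"))
  }
  hab_fracs <- list()
  for (id in ids) {
    hm <- assign_habitats(hmodel, pats[[id]]$fmap, pats[[id]]$m1)
    pats[[id]]$habitat_map <- hm
    pats[[id]]$hmasks <- habitat_masks(hm, pats[[id]]$m1)
    hab_fracs[[id]] <- hm$fractions
  }
  write.csv(data.frame(id = ids, do.call(rbind, hab_fracs)),
            file.path(config$out_dir, "habitat_fractions.csv"),
            row.names = FALSE)

  # --- extraction -----------------------------------------------------------
  say("stage extract")
  xcfg <- extraction_config()
  region_names <- c("intra", names(pats[[1]]$rings1))
  hab_names <- paste0("h", seq_len(min(hmodel$k, 3)))
  vec1 <- list(); vec2 <- list(); vec_h <- list()
  for (id in ids) {
    p <- pats[[id]]
    bank <- filter_bank(p$volume, xcfg$log_sigmas_mm)
    v1 <- list(intra = extract_features(p$volume, p$m1, xcfg, "intra", bank))
    for (rn in names(p$rings1))
      v1[[rn]] <- extract_features(p$volume, p$rings1[[rn]], xcfg, rn, bank)
    v2 <- list(intra = extract_features(p$volume, p$m2, xcfg, "intra", bank))
    for (rn in names(p$rings2))
      v2[[rn]] <- extract_features(p$volume, p$rings2[[rn]], xcfg, rn, bank)
    vh <- lapply(hab_names, function(h)
      extract_features(p$volume, p$hmasks[[h]], xcfg, h, bank))
    names(vh) <- hab_names
    vec1[[id]] <- v1; vec2[[id]] <- v2; vec_h[[id]] <- vh
    if (config$write_images) {
      dir.create(file.path(config$out_dir, "images"), showWarnings = FALSE)
      write_volume(p$volume,
                   file.path(config$out_dir, "images",
                             paste0(id, "_preprocessed.nii.gz")))
      write_volume(volume(p$habitat_map$labels + 0, p$volume$spacing,
                          p$volume$origin),
                   file.path(config$out_dir, "images",
                             paste0(id, "_habitats.nii.gz")))
    }
  }
  tables1 <- lapply(region_names, function(rn)
    feature_table(lapply(vec1, `[[`, rn)))
  names(tables1) <- region_names
  tables2 <- lapply(region_names, function(rn)
    feature_table(lapply(vec2, `[[`, rn)))
  names(tables2) <- region_names
  hab_tables <- lapply(hab_names, function(h)
    feature_table(lapply(vec_h, `[[`, h)))
  names(hab_tables) <- hab_names
  integrated <- feature_table(setNames(lapply(ids, function(id)
    integrated_habitat_features(vec_h[[id]]$h1, vec_h[[id]]$h2,
                                vec_h[[id]]$h3)), ids))

  # --- imputation (habitat regions) + ICC filtering (reader-covered) --------
  say("stage impute/ICC")
  hab_tables <- lapply(hab_tables, knn_impute, train_ids = train_ids)
  integrated <- knn_impute(integrated, train_ids = train_ids)
  icc_reports <- list()
  for (rn in region_names) {
    tr1 <- tables1[[rn]][tables1[[rn]]$id %in% train_ids, , drop = FALSE]
    tr2 <- tables2[[rn]][tables2[[rn]]$id %in% train_ids, , drop = FALSE]
    flt <- filter_by_icc(tr1, tr2, threshold = config$icc_threshold,
                         exempt_regions = character(0))
    keep <- colnames(flt$table)
    tables1[[rn]] <- tables1[[rn]][, keep, drop = FALSE]
    icc_reports[[rn]] <- flt$report
  }
  write.csv(do.call(rbind, icc_reports),
            file.path(config$out_dir, "icc_report.csv"), row.names = FALSE)

  # --- selection + modeling per region --------------------------------------
  say("stage select/train")
  region_tables <- c(tables1, hab_tables, list(habitat_integrated = integrated))
  model_of_region <- c(intra = "Intra",
                       setNames(sprintf("Peri%dmm", config$ring_distances_mm),
                                sprintf("peri%dmm", config$ring_distances_mm)),
                       setNames(paste0("HabitatH", seq_along(hab_names)),
                                hab_names),
                       habitat_integrated = "Habitat")
  y_train <- labels[train_ids]
  y_test <- labels[test_ids]
  selections <- list(); region_models <- list()
  scores_train <- list(); scores_test <- list()
  for (rn in names(region_tables)) {
    tab <- region_tables[[rn]]
    trt <- tab[match(train_ids, tab$id), , drop = FALSE]
    tet <- tab[match(test_ids, tab$id), , drop = FALSE]
    sel <- select_cascade(trt, tet, y_train, alpha = config$alpha,
                          r_threshold = config$r_threshold,
                          n_folds = config$lasso_folds,
                          seed = stage_seed(config, "select"))
    selections[[rn]] <- sel$selection
    if (length(sel$selection$selected) == 0) {
      # degenerate region: fall back to the full standardized table
      z <- zscore_fit_apply(trt, list(test = tet))
      sel$train <- z$train; sel$test <- z$others$test
    }
    cands <- list()
    for (alg in names(algorithm_set())) {
      cands[[alg]] <- train_region_model(sel$train, y_train, alg,
                                         cv_folds = config$cv_folds,
                                         seed = stage_seed(config, "train"))
    }
    test_aucs <- vapply(cands, function(m)
      tryCatch(roc_auc(predict_probability(m, sel$test), y_test),
               error = function(e) NA_real_), 0)
    pick <- if (config$policy == "paper_faithful") {
      suppressWarnings(select_best_algorithm(cands, test_aucs,
                                             policy = "paper_faithful"))
    } else {
      select_best_algorithm(cands, policy = "cv")
    }
    mdl <- model_of_region[[rn]]
    region_models[[mdl]] <- pick
    scores_train[[mdl]] <- predict_probability(pick$model, sel$train)
    scores_test[[mdl]] <- predict_probability(pick$model, sel$test)
  }

  # --- clinical model -------------------------------------------------------
  say("stage clinical")
  clin_train <- clinical[match(train_ids, clinical$id), , drop = FALSE]
  clin_test <- clinical[match(test_ids, clinical$id), , drop = FALSE]
  scr <- screen_clinical(clin_train, y_train)
  clin_vars <- scr$independent
  if (length(clin_vars) == 0)
    clin_vars <- scr$univariate$covariate[which.min(scr$univariate$p)]
  cfit <- suppressWarnings(glm(
    as.formula(paste("y ~", paste(clin_vars, collapse = "+"))),
    data = cbind(y = y_train, clin_train), family = binomial()))
  scores_train$Clinic <- as.numeric(predict(cfit, clin_train,
                                            type = "response"))
  scores_test$Clinic <- as.numeric(predict(cfit, clin_test,
                                           type = "response"))

  # --- nomogram (Combined) --------------------------------------------------
  say("stage nomogram")
  num_clin <- clin_vars[vapply(clin_vars, function(v)
    is.numeric(clinical[[v]]), TRUE)]
  nomo_inputs <- function(idset, scores) {
    df <- data.frame(id = idset,
                     clinical[match(idset, clinical$id), num_clin,
                              drop = FALSE],
                     radscore_intra = scores$Intra,
                     radscore_peri2mm = scores$Peri2mm,
                     radscore_habitat = scores$Habitat,
                     check.names = FALSE, row.names = NULL)
    df
  }
  nomo <- build_nomogram(nomo_inputs(train_ids, scores_train), y_train)
  scores_train$Combined <-
    as.numeric(predict_probability(nomo, nomo_inputs(train_ids, scores_train)))
  scores_test$Combined <-
    as.numeric(predict_probability(nomo, nomo_inputs(test_ids, scores_test)))

  # --- evaluation -----------------------------------------------------------
  say("stage evaluate")
  model_order <- c("Clinic", "Intra",
                   sprintf("Peri%dmm", config$ring_distances_mm),
                   paste0("HabitatH", seq_along(hab_names)), "Habitat",
                   "Combined")
  scores_train <- scores_train[model_order]
  scores_test <- scores_test[model_order]
  thresholds <- vapply(model_order, function(m)
    youden_threshold(scores_train[[m]], y_train), 0)
  report <- list(train = eval_report(scores_train, y_train, thresholds),
                 test = eval_report(scores_test, y_test, thresholds))
  for (coh in names(report)) {
    write.csv(report[[coh]]$metrics,
              file.path(config$out_dir, sprintf("metrics_%s.csv", coh)),
              row.names = FALSE)
    write.csv(as.data.frame(report[[coh]]$delong_p),
              file.path(config$out_dir, sprintf("delong_%s.csv", coh)),
              row.names = TRUE)
  }

  # --- manifest -------------------------------------------------------------
  manifest <- list(
    master_seed = config$master_seed,
    n_patients = config$cohort$n_patients,
    train_ids = train_ids, test_ids = test_ids,
    k_selected = hmodel$k, ch_selected_k = ch_selected_k,
    thresholds = as.list(thresholds),
    selected_algorithms = lapply(region_models, `[[`, "algorithm"),
    clinical_predictors = clin_vars,
    stage_params = list(rings = config$ring_distances_mm,
                        k_range = range(config$k_range),
                        icc = config$icc_threshold, r = config$r_threshold,
                        alpha = config$alpha,
                        lasso_folds = config$lasso_folds,
                        cv_folds = config$cv_folds, policy = config$policy),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest[names(manifest) != "elapsed_s"],
                       manifest_path, auto_unbox = TRUE, digits = NA)
  manifest$hash <- unname(tools::md5sum(manifest_path))

  list(report = report, models = region_models, nomogram = nomo,
       clinical_screen = scr, selection = selections,
       habitat_model = hmodel, scores = list(train = scores_train,
                                             test = scores_test),
       labels = list(train = y_train, test = y_test),
       manifest = manifest)
}
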