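#' Classify a train/test site combination
#'
#' Site-set algebra for evaluation rows: `internal` when the test sites
#' equal the train sites, `subset` when the test sites are a strict subset
#' of the train sites, `superset` when they strictly contain them (same
#' distribution plus external data), `external` when disjoint, and
#' `mixed` otherwise.
#'
#' @param train_sites,test_sites Character vectors of site ids.
#' @return One of `"internal"`, `"subset"`, `"superset"`, `"external"`,
#'   `"mixed"`.
#' @export
comparison_type <- function(train_sites, test_sites) {
  tr <- unique(train_sites); te <- unique(test_sites)
  if (setequal(tr, te)) return("internal")
  if (all(te %in% tr)) return("subset")
  if (all(tr %in% te)) return("superset")
  if (length(intersect(tr, te)) == 0L) return("external")
  "mixed"
}

# Train a multilabel nine-finding model on the frontal train/tune studies
# of the given sites.
.train_findings_model <- function(set, split, sites, channels, schedule) {
  meta <- set$meta
  sp <- unname(split[meta$patient_id])
  sel <- function(which_split)
    which(meta$site %in% sites & sp == which_split & meta$view == "frontal")
  tr <- sel("train"); tu <- sel("tune")
  spec <- classifier_spec("multilabel", length(FINDINGS),
                          input_size = dim(set$images)[1],
                          channels = channels, class_names = FINDINGS)
  train_classifier(set$images[, , tr],
                   as.matrix(meta[tr, FINDINGS]),
                   set$images[, , tu],
                   as.matrix(meta[tu, FINDINGS]),
                   spec, schedule)
}

# One evaluation row: AUC with CI plus screening operating-point metrics.
# A test set that ended up one-class (possible for a tiny rare-disease
# split) yields an NA row rather than an error.
.eval_row <- function(train_name, test_name, ctype, scores, labels,
                      sens_target) {
  row <- data.frame(train = train_name, comparison = ctype, test = test_name,
                    n = length(labels), n_pos = sum(labels == 1),
                    auc = NA_real_, auc_lo = NA_real_, auc_hi = NA_real_,
                    stringsAsFactors = FALSE)
  for (mname in c("accuracy", "sensitivity", "specificity", "ppv", "npv")) {
    row[[mname]] <- NA_real_
    row[[paste0(mname, "_lo")]] <- NA_real_
    row[[paste0(mname, "_hi")]] <- NA_real_
  }
  if (length(unique(labels)) < 2L) return(row)
  a <- auc_estimate(scores, labels)
  op <- operating_point_at_sensitivity(scores, labels, sens_target)
  row$auc <- a$auc; row$auc_lo <- a$ci[1]; row$auc_hi <- a$ci[2]
  for (mname in c("accuracy", "sensitivity", "specificity", "ppv", "npv")) {
    v <- op[[mname]]
    row[[mname]] <- v[["estimate"]]
    row[[paste0(mname, "_lo")]] <- v[["lower"]]
    row[[paste0(mname, "_hi")]] <- v[["upper"]]
  }
  row
}

#' Site-generalization study: internal vs external pneumonia screening
#'
#' End-to-end run of the core study design on synthetic data: generate a
#' multi-site study set, (optionally) filter to frontal views with a
#' trained view classifier, split patients 70/10/20, train one nine-finding
#' model per train-site combination, and evaluate pneumonia screening on
#' the joint internal test set, each single-site test set, and the fully
#' external site (all of whose studies are reserved for testing). Every
#' evaluation reports Mann-Whitney AUC with DeLong CI and the
#' 95%-sensitivity screening operating point; internal performance is
#' compared against every other test set with the unpaired DeLong test,
#' and a trivial prevalence-only ranker is evaluated on the joint test set.
#'
#' @param config A [generator_config()]; its seed is replaced by `seed`.
#' @param profiles Site profiles (default [default_site_profiles()]).
#' @param seed Master seed for the run.
#' @param internal_sites Two (or more) sites contributing training data.
#' @param external_site Site used only for external testing.
#' @param train_combos List of train-site combinations (default: each
#'   internal site alone plus the joint set).
#' @param channels CNN channel widths.
#' @param apply_view_filter Run the frontal-view filter stage.
#' @param sens_target Screening sensitivity target.
#' @return List of class `site_generalization_result`: `results` (one row
#'   per train x test evaluation), `comparisons` (DeLong tests, internal
#'   vs other), `trivial_auc` (prevalence-only ranker on the joint test
#'   set), `train_prevalence`, `scores` (per-case score frames), and
#'   `view_filter` accuracy.
#' @export
run_site_generalization <- function(config = generator_config(),
                                    profiles = default_site_profiles(),
                                    seed = 1L,
                                    internal_sites = c("site_a", "site_b"),
                                    external_site = "site_c",
                                    train_combos = NULL,
                                    channels = c(4L, 8L),
                                    apply_view_filter = TRUE,
                                    sens_target = 0.95) {
  config$seed <- as.integer(seed)
  set <- generate_study_set(config, profiles)
  vf <- NULL
  if (apply_view_filter && any(set$meta$view == "lateral")) {
    vf <- view_filter(set, seed = seed + 101L, channels = channels)
    set <- vf$set
  }
  split <- split_by_patient(set, seed = seed + 202L)
  meta <- set$meta
  sp <- unname(split[meta$patient_id])
  if (is.null(train_combos))
    train_combos <- c(as.list(internal_sites), list(internal_sites))
  test_sets <- c(list(joint = internal_sites),
                 setNames(as.list(internal_sites), internal_sites),
                 setNames(list(external_site), external_site))
  test_idx <- lapply(test_sets, function(sites) {
    if (identical(sites, external_site))
      which(meta$site %in% sites & meta$view == "frontal")
    else
      which(meta$site %in% sites & sp == "test" & meta$view == "frontal")
  })
  results <- list(); comparisons <- list(); scores_out <- list()
  for (ci in seq_along(train_combos)) {
    sites <- train_combos[[ci]]
    train_name <- paste(sites, collapse = "+")
    model <- .train_findings_model(set, split, sites, channels,
                                   train_schedule(seed = seed + 300L + ci))
    scored <- lapply(test_idx, function(idx) {
      data.frame(study_id = meta$study_id[idx], site = meta$site[idx],
                 score = predict_proba(
                   model, set$images[, , idx, drop = FALSE])[, "pneumonia"],
                 label = meta$pneumonia[idx], stringsAsFactors = FALSE)
    })
    internal_name <- names(test_sets)[vapply(test_sets, function(ts)
      comparison_type(sites, ts) == "internal", TRUE)][1]
    for (tn in names(test_sets)) {
      ctype <- comparison_type(sites, test_sets[[tn]])
      results[[paste(train_name, tn)]] <-
        .eval_row(train_name, tn, ctype, scored[[tn]]$score,
                  scored[[tn]]$label, sens_target)
      if (tn != internal_name &&
          length(unique(scored[[tn]]$label)) > 1L &&
          length(unique(scored[[internal_name]]$label)) > 1L) {
        cmp <- delong_unpaired(scored[[internal_name]]$score,
                               scored[[internal_name]]$label,
                               scored[[tn]]$score, scored[[tn]]$label)
        comparisons[[paste(train_name, tn)]] <-
          data.frame(train = train_name, test_a = internal_name,
                     test_b = tn, type_b = ctype, mode = cmp$mode,
                     auc_a = cmp$auc_a, auc_b = cmp$auc_b,
                     delta_auc = cmp$delta_auc, z = cmp$z,
                     p_value = cmp$p_value, stringsAsFactors = FALSE)
      }
    }
    scores_out[[train_name]] <- scored
  }
  train_prev <- vapply(c(internal_sites, external_site), function(s)
    mean(meta$pneumonia[meta$site == s & sp == "train"]), 0)
  joint <- scores_out[[1]][["joint"]]
  triv_scores <- trivial_prevalence_ranker(joint$site, train_prev)
  structure(list(results = do.call(rbind, c(results, make.row.names = FALSE)),
                 comparisons = do.call(rbind, c(comparisons,
                                                make.row.names = FALSE)),
                 trivial_auc = auc_estimate(triv_scores, joint$label),
                 train_prevalence = train_prev,
                 scores = scores_out,
                 view_filter = if (is.null(vf)) NULL else
                   vf[c("accuracy", "n_test")],
                 seed = seed),
            class = "site_generalization_result")
}

#' Site and department detection with activation-map audit
#'
#' Trains a multiclass CNN to predict the hospital site directly from the
#' image, reports held-out per-site accuracy with Clopper-Pearson CIs,
#' optionally repeats the exercise for departments within one site, and
#' audits what the site classifier looks at: the number of `g x g`
#' subregions that individually predict the target site decisively
#' (cellwise softmax probability >= `tau`), influence heatmaps, and -- when
#' the target site has a corner token -- how often the heatmap argmax falls
#' on the token's grid cell.
#'
#' @param config A [generator_config()]; seed replaced by `seed`.
#' @param profiles Site profiles.
#' @param seed Master seed.
#' @param target_site Site whose test images feed the activation-map audit.
#' @param cam_sample Number of audited test images (default 100).
#' @param tau Decisiveness threshold (default 0.95).
#' @param channels CNN channel widths.
#' @param department_site Site for the department sub-experiment, or
#'   `NULL` to skip.
#' @return List of class `site_detection_result`: `site_accuracy` (per-site
#'   counts and CIs), `overall_accuracy`, `department_accuracy`,
#'   `decisive` (a `decisive_summary`), `localization` (fraction of audited
#'   images whose influence-heatmap argmax hits the token cell, `NA`
#'   without a token), `heatmap` (mean influence heatmap), and the fitted
#'   `model`.
#' @export
run_site_detection <- function(config = generator_config(),
                               profiles = default_site_profiles(),
                               seed = 1L, target_site = "site_b",
                               cam_sample = 100L, tau = 0.95,
                               channels = c(4L, 8L),
                               department_site = "site_a") {
  config$seed <- as.integer(seed)
  set <- generate_study_set(config, profiles)
  split <- split_by_patient(set, seed = seed + 202L)
  meta <- set$meta
  sp <- unname(split[meta$patient_id])
  frontal <- meta$view == "frontal"
  sites <- sort(unique(meta$site))
  spec <- classifier_spec("multiclass", length(sites),
                          input_size = dim(set$images)[1],
                          channels = channels, class_names = sites)
  tr <- which(sp == "train" & frontal); tu <- which(sp == "tune" & frontal)
  model <- train_classifier(set$images[, , tr], meta$site[tr],
                            set$images[, , tu], meta$site[tu],
                            spec, train_schedule(seed = seed + 303L))
  te <- which(sp == "test" & frontal)
  pr <- predict_proba(model, set$images[, , te, drop = FALSE])
  pred <- colnames(pr)[max.col(pr, ties.method = "first")]
  site_acc <- do.call(rbind, lapply(sites, function(s) {
    idx <- meta$site[te] == s
    cp <- clopper_pearson(sum(pred[idx] == s), sum(idx))
    data.frame(site = s, correct = sum(pred[idx] == s), n = sum(idx),
               accuracy = cp[["estimate"]], lo = cp[["lower"]],
               hi = cp[["upper"]], stringsAsFactors = FALSE)
  }))
  dept_acc <- NULL
  if (!is.null(department_site)) {
    dmeta <- meta$department[meta$site == department_site]
    if (length(unique(dmeta)) >= 2L) {
      didx <- function(which_split)
        which(meta$site == department_site & sp == which_split & frontal)
      depts <- sort(unique(meta$department[meta$site == department_site]))
      dspec <- classifier_spec("multiclass", length(depts),
                               input_size = dim(set$images)[1],
                               channels = channels, class_names = depts)
      dmodel <- train_classifier(set$images[, , didx("train")],
                                 meta$department[didx("train")],
                                 set$images[, , didx("tune")],
                                 meta$department[didx("tune")],
                                 dspec, train_schedule(seed = seed + 404L))
      dte <- didx("test")
      dpr <- predict_proba(dmodel, set$images[, , dte, drop = FALSE])
      dpred <- colnames(dpr)[max.col(dpr, ties.method = "first")]
      dept_acc <- do.call(rbind, lapply(depts, function(d) {
        idx <- meta$department[dte] == d
        cp <- clopper_pearson(sum(dpred[idx] == d), sum(idx))
        data.frame(department = d, correct = sum(dpred[idx] == d),
                   n = sum(idx), accuracy = cp[["estimate"]],
                   lo = cp[["lower"]], hi = cp[["upper"]],
                   stringsAsFactors = FALSE)
      }))
    }
  }
  cam_pool <- te[meta$site[te] == target_site]
  cam_idx <- cam_pool[seq_len(min(cam_sample, length(cam_pool)))]
  decisive <- summarize_decisive(model, set$images[, , cam_idx, drop = FALSE],
                                 target_site, tau)
  tok <- profiles[[target_site]]$token
  loc <- NA_real_
  heat_sum <- 0
  hits <- 0L
  for (i in cam_idx) {
    ft <- extract_final_features(model, set$images[, , i])
    D <- influence_heatmap(subregion_scores(ft), target_site)
    heat_sum <- heat_sum + D
    if (!is.null(tok) && tok$intensity > 0) {
      cell <- which(D == max(D), arr.ind = TRUE)[1, ]
      want <- token_grid_cells(profiles[[target_site]],
                               dim(set$images)[1], ft$g)
      hits <- hits + as.integer(any(cell[1] == want[, "row"] &
                                      cell[2] == want[, "col"]))
    }
  }
  if (!is.null(tok) && tok$intensity > 0) loc <- hits / length(cam_idx)
  structure(list(site_accuracy = site_acc,
                 overall_accuracy = mean(pred == meta$site[te]),
                 department_accuracy = dept_acc,
                 decisive = decisive, localization = loc,
                 heatmap = heat_sum / length(cam_idx),
                 model = model, seed = seed),
            class = "site_detection_result")
}

#' Engineered relative-risk study
#'
#' For each engineered-prevalence design and each seed: sample the cohort
#' from the per-site pools, train a nine-finding model on the cohort's
#' train/tune patients, and compare pneumonia AUC on the cohort's internal
#' joint two-site test data against the fully external site (unpaired
#' DeLong test). Demonstrates that prevalence imbalance between pooled
#' training sites inflates internal but not external performance.
#'
#' @param config A [generator_config()] for the source pools; its
#'   `n_patients_per_site` should exceed the cohort demand. Seed replaced
#'   per run seed.
#' @param profiles Site profiles; the two pooled sites should share one
#'   generous pool prevalence so every design is feasible.
#' @param specs List of [cohort_spec()]s (default the five standard designs
#'   at 10,000 patients/site -- pass scaled-down specs for desk-size runs).
#' @param seeds Integer vector of replicate seeds.
#' @param external_site Fully external evaluation site.
#' @param channels CNN channel widths.
#' @return Data frame of class `engineered_prevalence_result`: one row per
#'   cohort x seed with internal/external AUCs, CIs, and the DeLong
#'   internal-vs-external comparison.
#' @export
run_engineered_prevalence <- function(config, profiles,
                                      specs = standard_specs(),
                                      seeds = 1:5,
                                      external_site = "site_c",
                                      channels = c(4L, 8L)) {
  rows <- list()
  for (seed in seeds) {
    config$seed <- as.integer(seed)
    pool <- generate_study_set(config, profiles)
    split <- split_by_patient(pool, seed = seed + 202L)
    meta <- pool$meta
    sp <- unname(split[meta$patient_id])
    frontal <- meta$view == "frontal"
    ext_idx <- which(meta$site == external_site & frontal)
    for (si in seq_along(specs)) {
      spec <- specs[[si]]
      cohort <- engineer_prevalence_cohort(meta, spec,
                                           seed = seed + 500L + si)
      in_cohort <- logical(nrow(meta))
      in_cohort[cohort$study_idx] <- TRUE
      idx_of <- function(which_split)
        which(in_cohort & sp == which_split & frontal)
      model <- .train_findings_model(
        subset_study_set(pool, sort(c(idx_of("train"), idx_of("tune")))),
        split, c(spec$site_a, spec$site_b), channels,
        train_schedule(seed = seed * 100L + si))
      te <- idx_of("test")
      s_int <- predict_proba(model,
                             pool$images[, , te, drop = FALSE])[, "pneumonia"]
      s_ext <- predict_proba(model,
                             pool$images[, , ext_idx, drop = FALSE])[, "pneumonia"]
      a_int <- auc_estimate(s_int, meta$pneumonia[te])
      a_ext <- auc_estimate(s_ext, meta$pneumonia[ext_idx])
      cmp <- delong_unpaired(s_int, meta$pneumonia[te],
                             s_ext, meta$pneumonia[ext_idx])
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = spec$name, seed = seed,
        prevalence_a = spec$prevalence_a, prevalence_b = spec$prevalence_b,
        n_train = length(idx_of("train")), n_internal_test = length(te),
        n_external = length(ext_idx),
        internal_auc = a_int$auc, internal_lo = a_int$ci[1],
        internal_hi = a_int$ci[2],
        external_auc = a_ext$auc, external_lo = a_ext$ci[1],
        external_hi = a_ext$ci[2],
        delta_auc = cmp$delta_auc, z = cmp$z, p_value = cmp$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("engineered_prevalence_result", class(out))
  out
}
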