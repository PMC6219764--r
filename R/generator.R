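#' The nine radiographic findings carried by every study record
#'
#' Binary labels generated for each synthetic study, in fixed column order.
#' Only pneumonia has a rendered image correlate (a diffuse lung-field
#' opacity); the remaining findings exist as report/label structure for
#' multi-label training.
#' @export
FINDINGS <- c("cardiomegaly", "emphysema", "effusion", "hernia", "nodule",
              "atelectasis", "pneumonia", "edema", "consolidation")

# Background rates for the eight findings without an image correlate.
.OTHER_FINDING_RATES <- c(cardiomegaly = 0.10, emphysema = 0.025,
                          effusion = 0.15, hernia = 0.01, nodule = 0.03,
                          atelectasis = 0.12, edema = 0.05,
                          consolidation = 0.10)

#' Configuration for the synthetic study-set generator
#'
#' @param n_patients_per_site Number of patients at each site; a scalar, or
#'   a vector named by site id.
#' @param studies_per_patient_mean Mean of the truncated-geometric
#'   studies-per-patient distribution (1 + geometric, truncated at
#'   `studies_per_patient_max`). The default 3.5 reflects the roughly
#'   3.6 studies per patient seen in large public chest-radiograph archives.
#' @param studies_per_patient_max Upper truncation for studies per patient.
#' @param image_size Side length of the square grayscale images, in pixels.
#' @param effect_size Amplitude of the additive elliptical pneumonia opacity,
#'   in intensity units; 0 removes the disease signal entirely.
#' @param lateral_fraction Probability that a study is a lateral view.
#' @param other_finding_rates Named rates for the eight findings other than
#'   pneumonia (report-only labels).
#' @param seed Integer seed fixing all downstream randomness.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_patients_per_site = 200,
                             studies_per_patient_mean = 3.5,
                             studies_per_patient_max = 10L,
                             image_size = 64L,
                             effect_size = 0.15,
                             lateral_fraction = 0.1,
                             other_finding_rates = .OTHER_FINDING_RATES,
                             seed = 1L) {
  stopifnot(all(n_patients_per_site > 0), studies_per_patient_mean >= 1,
            studies_per_patient_max >= 1, image_size >= 16,
            effect_size >= 0, lateral_fraction >= 0, lateral_fraction <= 1)
  stopifnot(all(sort(names(other_finding_rates)) ==
                  sort(setdiff(FINDINGS, "pneumonia"))))
  structure(list(n_patients_per_site = n_patients_per_site,
                 studies_per_patient_mean = studies_per_patient_mean,
                 studies_per_patient_max = as.integer(studies_per_patient_max),
                 image_size = as.integer(image_size),
                 effect_size = effect_size,
                 lateral_fraction = lateral_fraction,
                 other_finding_rates = other_finding_rates,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Soft elliptical bump on the unit square: 1 at the center, 0 at the
# boundary, linear in squared normalized radius.
.soft_ellipse <- function(xg, yg, cx, cy, rx, ry) {
  d2 <- ((xg - cx) / rx)^2 + ((yg - cy) / ry)^2
  pmax(1 - d2, 0)
}

# Normalized pixel-center coordinate grids for an S x S image, cached by size.
.grid_cache <- new.env(parent = emptyenv())
.coord_grids <- function(S) {
  key <- as.character(S)
  if (is.null(.grid_cache[[key]])) {
    u <- (seq_len(S) - 0.5) / S
    .grid_cache[[key]] <- list(x = matrix(u, S, S, byrow = TRUE),
                               y = matrix(u, S, S))
  }
  .grid_cache[[key]]
}

# Anatomy-like base silhouette: a bright torso with dark air-filled lung
# fields. Frontal views carry two lung ellipses; laterals a narrower torso
# with a single offset lung, a deliberately distinct geometry so a view
# classifier has something to learn. Cached by (size, view).
.silhouette <- function(S, view) {
  key <- paste0(view, S)
  if (is.null(.grid_cache[[key]])) {
    g <- .coord_grids(S)
    if (view == "frontal") {
      img <- 0.35 * .soft_ellipse(g$x, g$y, 0.50, 0.55, 0.42, 0.46) -
        0.25 * .soft_ellipse(g$x, g$y, 0.35, 0.45, 0.15, 0.23) -
        0.25 * .soft_ellipse(g$x, g$y, 0.65, 0.45, 0.15, 0.23)
    } else {
      # narrower torso, single lung, the bright spine column that dominates
      # a lateral projection, and a globally brighter exposure (the beam
      # traverses more tissue, shifting the archived histogram)
      img <- 0.12 + 0.35 * .soft_ellipse(g$x, g$y, 0.52, 0.55, 0.28, 0.47) -
        0.30 * .soft_ellipse(g$x, g$y, 0.45, 0.42, 0.17, 0.26) +
        0.45 * .soft_ellipse(g$x, g$y, 0.66, 0.55, 0.055, 0.42)
    }
    .grid_cache[[key]] <- img
  }
  .grid_cache[[key]]
}

# Lung-field centers used to place the pneumonia opacity.
.LUNGS_FRONTAL <- list(c(0.35, 0.45), c(0.65, 0.45))

#' Render one synthetic radiograph
#'
#' Composes the image for a single study from its metadata and the site's
#' acquisition profile, consuming the current R random-number stream (so the
#' result is reproducible under `set.seed()`). Layers, in order: background
#' offset + anatomical silhouette; for frontal views an elliptical
#' pneumonia opacity of amplitude `effect_size` at a randomized lung-field
#' location (drawn for every frontal study but added with weight equal to
#' the pneumonia label, so positive and negative renders consume identical
#' randomness); Gaussian pixel noise; clipping to `[0, 1]`; color inversion
#' (`1 - pixel`) if the acquiring department archives inverted; finally the
#' corner token and edge banner are overdrawn (metal and burned-in text are
#' bright in either color scheme).
#'
#' @param view `"frontal"` or `"lateral"`.
#' @param department Department acquiring the study; must appear in
#'   `profile$department_mix`.
#' @param labels Named binary vector including `pneumonia`.
#' @param profile A [site_profile()].
#' @param config A [generator_config()] (for `image_size` and `effect_size`).
#' @return `image_size` x `image_size` matrix of pixel intensities in
#'   `[0, 1]`.
#' @export
render_image <- function(view, department, labels, profile, config) {
  S <- config$image_size
  g <- .coord_grids(S)
  img <- profile$background_offset + .silhouette(S, view)
  if (view == "frontal") {
    lung <- .LUNGS_FRONTAL[[sample.int(2L, 1L)]]
    cx <- lung[1] + runif(1, -0.08, 0.08)
    cy <- lung[2] + runif(1, -0.12, 0.12)
    rx <- runif(1, 0.07, 0.11)
    ry <- runif(1, 0.08, 0.13)
    amp <- config$effect_size * as.numeric(labels[["pneumonia"]])
    img <- img + amp * .soft_ellipse(g$x, g$y, cx, cy, rx, ry)
  }
  img <- img + matrix(rnorm(S * S, 0, profile$noise_sd), S, S)
  img <- pmin(pmax(img, 0), 1)
  if (isTRUE(profile$invert_by_department[[department]])) img <- 1 - img
  tok <- profile$token
  if (!is.null(tok) && tok$intensity > 0) {
    rows <- switch(substr(tok$corner, 1, 1),
                   t = tok$margin + seq_len(tok$side),
                   b = S - tok$margin - tok$side + seq_len(tok$side))
    cols <- switch(substr(tok$corner, 2, 2),
                   l = tok$margin + seq_len(tok$side),
                   r = S - tok$margin - tok$side + seq_len(tok$side))
    img[rows, cols] <- tok$intensity
  }
  ban <- profile$banner
  if (!is.null(ban)) {
    rows <- if (ban$edge == "top") seq_len(ban$rows) else
      S - ban$rows + seq_len(ban$rows)
    img[rows, ] <- ban$intensity
  }
  pmin(pmax(img, 0), 1)
}

# Exact-count positive assignment within sex strata: each sex's prevalence
# matches the site prevalence to within one study. Positives are clustered
# by patient (disease episodes persist across a patient's studies): within
# each stratum, randomly ordered patients contribute all their studies
# until the exact count is reached, the boundary patient contributing a
# random subset. This keeps patient-level and study-level prevalence
# coherent, which the engineered-cohort sampler relies on. Returns a
# logical vector over studies; errors if a stratum is too small.
.assign_exact_positives <- function(sex, patient_id, prevalence, site_id) {
  n <- length(sex)
  m <- round(prevalence * n)
  is_f <- sex == "F"
  n_f <- sum(is_f)
  m_f <- round(m * n_f / n)
  m_m <- m - m_f
  if (m_f > n_f)
    stop(sprintf("site %s: %d positives required in female stratum but only %d studies",
                 site_id, m_f, n_f))
  if (m_m > n - n_f)
    stop(sprintf("site %s: %d positives required in male stratum but only %d studies",
                 site_id, m_m, n - n_f))
  pos <- logical(n)
  fill_stratum <- function(stratum_idx, need) {
    if (need == 0L) return(invisible())
    pids <- sample(unique(patient_id[stratum_idx]))
    for (pid in pids) {
      idx <- stratum_idx[patient_id[stratum_idx] == pid]
      if (length(idx) > need) idx <- sample(idx, need)
      pos[idx] <<- TRUE
      need <- need - length(idx)
      if (need == 0L) break
    }
  }
  fill_stratum(which(is_f), m_f)
  fill_stratum(which(!is_f), m_m)
  pos
}

#' Generate a multi-site synthetic study set
#'
#' Draws patients, studies, metadata, ground-truth labels and rendered
#' images for every site profile. Pneumonia-positive studies are assigned
#' as exact counts per site (`round(prevalence * n_studies)`), balanced
#' across sex strata; every patient's studies share one site; the whole set
#' is reproducible from `config$seed`.
#'
#' @param config A [generator_config()].
#' @param profiles List of [site_profile()] objects (e.g.
#'   [default_site_profiles()]).
#' @return An object of class `study_set`: a list with `meta` (one row per
#'   study: ids, site, department, view, sex, age, nine finding labels),
#'   `images` (`size x size x n_studies` array), `config`, and `profiles`.
#' @export
generate_study_set <- function(config, profiles) {
  stopifnot(inherits(config, "generator_config"), length(profiles) >= 1)
  set.seed(config$seed)
  npps <- config$n_patients_per_site
  meta_list <- vector("list", length(profiles))
  for (pi in seq_along(profiles)) {
    prof <- profiles[[pi]]
    n_pat <- if (length(npps) == 1L) npps else {
      if (!prof$site_id %in% names(npps))
        stop("n_patients_per_site has no entry for site ", prof$site_id)
      npps[[prof$site_id]]
    }
    sex_pat <- ifelse(runif(n_pat) < prof$sex_female_fraction, "F", "M")
    age_pat <- pmin(100, pmax(0, rnorm(n_pat, prof$age_mean, prof$age_sd)))
    p_geom <- 1 / config$studies_per_patient_mean
    n_stud <- pmin(config$studies_per_patient_max,
                   1L + stats::rgeom(n_pat, p_geom))
    idx <- rep(seq_len(n_pat), n_stud)
    n <- length(idx)
    meta <- data.frame(
      patient_id = sprintf("%s_p%05d", prof$site_id, idx),
      study_id = sprintf("%s_s%06d", prof$site_id, seq_len(n)),
      site = prof$site_id,
      department = sample(names(prof$department_mix), n, replace = TRUE,
                          prob = prof$department_mix),
      view = ifelse(runif(n) < config$lateral_fraction, "lateral", "frontal"),
      sex = sex_pat[idx],
      age = round(age_pat[idx], 1),
      stringsAsFactors = FALSE)
    for (f in FINDINGS) meta[[f]] <- 0L
    meta$pneumonia <- as.integer(
      .assign_exact_positives(meta$sex, meta$patient_id, prof$prevalence, prof$site_id))
    for (f in names(config$other_finding_rates))
      meta[[f]] <- stats::rbinom(n, 1L, config$other_finding_rates[[f]])
    meta_list[[pi]] <- meta
  }
  meta <- do.call(rbind, meta_list)
  rownames(meta) <- NULL
  S <- config$image_size
  images <- array(0, c(S, S, nrow(meta)))
  prof_by_id <- setNames(profiles, vapply(profiles, `[[`, "", "site_id"))
  for (i in seq_len(nrow(meta))) {
    images[, , i] <- render_image(meta$view[i], meta$department[i],
                                  c(pneumonia = meta$pneumonia[i]),
                                  prof_by_id[[meta$site[i]]], config)
  }
  structure(list(meta = meta, images = images, config = config,
                 profiles = prof_by_id),
            class = "study_set")
}

#' Subset a study set by row index or logical mask
#' @param set A `study_set`.
#' @param idx Integer or logical index over studies.
#' @return A `study_set` restricted to the selected studies.
#' @export
subset_study_set <- function(set, idx) {
  stopifnot(inherits(set, "study_set"))
  if (is.logical(idx)) idx <- which(idx)
  out <- set
  out$meta <- set$meta[idx, , drop = FALSE]
  rownames(out$meta) <- NULL
  out$images <- set$images[, , idx, drop = FALSE]
  out
}

#' @exportS3Method base::print
print.study_set <- function(x, ...) {
  cat(sprintf("<study_set> %d studies from %d patients across %d site(s), %dx%d px\n",
              nrow(x$meta), length(unique(x$meta$patient_id)),
              length(unique(x$meta$site)), dim(x$images)[1], dim(x$images)[2]))
  tab <- table(x$meta$site)
  prev <- vapply(names(tab), function(s)
    mean(x$meta$pneumonia[x$meta$site == s]), 0)
  for (s in names(tab))
    cat(sprintf("  %s: %d studies, pneumonia prevalence %.3f\n",
                s, tab[[s]], prev[[s]]))
  invisible(x)
}

#' Write a study set to disk as portable text/PNG artifacts
#'
#' Images are written as 8-bit grayscale PNG files, the metadata manifest as
#' CSV (with an `image` column of relative paths), and reports -- if present
#' in `reports` -- as JSON lines `{study_id, text}`.
#'
#' @param set A `study_set`.
#' @param dir Output directory (created if needed).
#' @param reports Optional data frame with columns `study_id`, `text`.
#' @return Invisibly, the manifest path.
#' @export
write_study_set <- function(set, dir, reports = NULL) {
  stopifnot(inherits(set, "study_set"))
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path("images", paste0(set$meta$study_id, ".png"))
  for (i in seq_len(nrow(set$meta)))
    png::writePNG(set$images[, , i], file.path(dir, paths[i]))
  manifest <- cbind(set$meta, image = paths)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(reports)) {
    con <- file(file.path(dir, "reports.jsonl"), "w")
    on.exit(close(con))
    for (i in seq_len(nrow(reports)))
      writeLines(jsonlite::toJSON(list(study_id = reports$study_id[i],
                                       text = reports$text[i]),
                                  auto_unbox = TRUE), con)
  }
  invisible(file.path(dir, "manifest.csv"))
}
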