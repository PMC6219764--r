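#' Acquisition profile for a simulated hospital site
#'
#' A `site_profile` bundles everything that makes one hospital system's
#' radiographs look and behave like that system's: the mix of acquiring
#' departments, the disease (pneumonia) prevalence among studies, the
#' acquisition artifacts ("confounds") burned into every image -- a corner
#' metal laterality token, an optional near-white text banner, and an
#' optional department-specific inverted color scheme (air rendered white,
#' as some portable scanners archive their images) -- plus demographic
#' structure (sex balance, age distribution) and global intensity offsets.
#'
#' @param site_id Short string identifying the site.
#' @param department_mix Named numeric vector of department probabilities;
#'   must sum to 1.
#' @param prevalence Fraction of studies at this site that are
#'   pneumonia-positive, in `[0, 1]`. Positives are assigned as exact counts
#'   (`round(prevalence * n_studies)`), not Bernoulli draws.
#' @param token Corner token specification from [token_spec()], or `NULL`
#'   for no token.
#' @param banner Edge banner specification from [banner_spec()], or `NULL`.
#' @param invert_by_department Named logical vector; departments mapped to
#'   `TRUE` archive images in an inverted color scheme (`1 - pixel`),
#'   applied before the token/banner overdraw.
#' @param background_offset Constant intensity added to the image background.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param sex_female_fraction Probability that a patient is female.
#' @param age_mean,age_sd Patient age distribution in years (normal,
#'   truncated to `[0, 100]`).
#' @return An object of class `site_profile`.
#' @export
site_profile <- function(site_id,
                         department_mix = c(outpatient = 1),
                         prevalence = 0.05,
                         token = token_spec(),
                         banner = NULL,
                         invert_by_department = NULL,
                         background_offset = 0,
                         noise_sd = 0.08,
                         sex_female_fraction = 0.5,
                         age_mean = 50,
                         age_sd = 17) {
  stopifnot(is.character(site_id), length(site_id) == 1L, nzchar(site_id))
  if (is.null(names(department_mix)) || any(!nzchar(names(department_mix))))
    stop("department_mix must be a named probability vector")
  if (abs(sum(department_mix) - 1) > 1e-9)
    stop("department_mix probabilities must sum to 1")
  if (any(department_mix < 0)) stop("department_mix probabilities must be >= 0")
  stopifnot(prevalence >= 0, prevalence <= 1, noise_sd >= 0,
            sex_female_fraction >= 0, sex_female_fraction <= 1)
  if (!is.null(token)) stopifnot(inherits(token, "token_spec"))
  if (!is.null(banner)) stopifnot(inherits(banner, "banner_spec"))
  inv <- setNames(rep(FALSE, length(department_mix)), names(department_mix))
  if (!is.null(invert_by_department)) {
    bad <- setdiff(names(invert_by_department), names(department_mix))
    if (length(bad)) stop("invert_by_department names unknown: ", paste(bad, collapse = ", "))
    inv[names(invert_by_department)] <- as.logical(invert_by_department)
  }
  structure(list(site_id = site_id, department_mix = department_mix,
                 prevalence = prevalence, token = token, banner = banner,
                 invert_by_department = inv,
                 background_offset = background_offset, noise_sd = noise_sd,
                 sex_female_fraction = sex_female_fraction,
                 age_mean = age_mean, age_sd = age_sd),
            class = "site_profile")
}

#' Corner metal-token specification
#'
#' Describes the radiopaque laterality token that technicians place in the
#' image field of view: a bright square block overdrawn in one corner
#' quadrant after any color inversion (metal stays bright in either scheme).
#'
#' @param corner One of `"tl"`, `"tr"`, `"bl"`, `"br"`.
#' @param side Side length of the square block, in pixels.
#' @param intensity Pixel value the block is set to, in `[0, 1]`;
#'   0 disables the token.
#' @param margin Pixels between the block and the image border.
#' @return An object of class `token_spec`.
#' @export
token_spec <- function(corner = "tl", side = 6, intensity = 1, margin = 2) {
  stopifnot(corner %in% c("tl", "tr", "bl", "br"),
            side >= 1, intensity >= 0, intensity <= 1, margin >= 0)
  structure(list(corner = corner, side = as.integer(side),
                 intensity = intensity, margin = as.integer(margin)),
            class = "token_spec")
}

#' Edge text-banner specification
#'
#' A strip of near-white rows at the top or bottom edge, standing in for the
#' burned-in text annotations (laterality, "PORTABLE") some scanners add.
#'
#' @param edge `"top"` or `"bottom"`.
#' @param rows Number of pixel rows.
#' @param intensity Pixel value of the strip, in `[0, 1]`.
#' @return An object of class `banner_spec`.
#' @export
banner_spec <- function(edge = "top", rows = 3, intensity = 0.95) {
  stopifnot(edge %in% c("top", "bottom"), rows >= 1,
            intensity >= 0, intensity <= 1)
  structure(list(edge = edge, rows = as.integer(rows), intensity = intensity),
            class = "banner_spec")
}

#' Default three-site study conditions
#'
#' Returns the three site profiles the package's experiments assume: one
#' high-prevalence urban inpatient-heavy site (`site_a`, prevalence 34.2%,
#' with an inverted-color emergency department), one large low-prevalence
#' research archive (`site_b`, 1.2%), and one small external outpatient
#' network (`site_c`, 1.0%). Prevalences, sex fractions and age
#' distributions follow the baseline characteristics of the three hospital
#' systems the simulation emulates. Each site carries a distinct corner
#' token and a site-specific detector noise level (a global acquisition
#' signature); `site_a` additionally has a text banner and
#' department-dependent inversion.
#'
#' @param confounds If `FALSE`, all acquisition artifacts are removed
#'   (no token, no banner, no inversion, equal background offsets and
#'   noise levels) so the sites differ only in demographics and
#'   prevalence.
#' @param equal_prevalence If `TRUE`, every site's prevalence is set to
#'   `prevalence_value`, for null-control experiments in which the site
#'   distributions are identical.
#' @param prevalence_value Common prevalence used when
#'   `equal_prevalence = TRUE`.
#' @return Named list of three [site_profile()] objects.
#' @export
default_site_profiles <- function(confounds = TRUE, equal_prevalence = FALSE,
                                  prevalence_value = 0.1) {
  profs <- list(
    site_a = site_profile(
      "site_a",
      department_mix = c(inpatient = 0.7, ed = 0.3),
      prevalence = 0.342,
      token = token_spec("br", side = 6, intensity = 1.0),
      banner = banner_spec("top", rows = 3, intensity = 0.95),
      invert_by_department = c(ed = TRUE),
      background_offset = 0.05, noise_sd = 0.09,
      sex_female_fraction = 0.448, age_mean = 63.2, age_sd = 16.5),
    site_b = site_profile(
      "site_b",
      department_mix = c(outpatient = 0.8, inpatient = 0.2),
      prevalence = 0.012,
      token = token_spec("tl", side = 6, intensity = 0.9),
      banner = NULL,
      background_offset = 0, noise_sd = 0.06,
      sex_female_fraction = 0.435, age_mean = 46.9, age_sd = 16.6),
    site_c = site_profile(
      "site_c",
      department_mix = c(outpatient = 1),
      prevalence = 0.010,
      token = token_spec("tr", side = 6, intensity = 0.8),
      banner = NULL,
      background_offset = 0.02, noise_sd = 0.11,
      sex_female_fraction = 0.573, age_mean = 49.6, age_sd = 17.0))
  if (!confounds) {
    profs <- lapply(profs, function(p) {
      p$token <- NULL
      p$banner <- NULL
      p$invert_by_department[] <- FALSE
      p$background_offset <- 0
      p$noise_sd <- 0.08
      p
    })
  }
  if (equal_prevalence) {
    profs <- lapply(profs, function(p) { p$prevalence <- prevalence_value; p })
  }
  profs
}

#' @exportS3Method base::print
print.site_profile <- function(x, ...) {
  cat(sprintf("<site_profile '%s'> prevalence %.3f, departments: %s\n",
              x$site_id, x$prevalence,
              paste(sprintf("%s=%.2f", names(x$department_mix),
                            x$department_mix), collapse = ", ")))
  if (!is.null(x$token) && x$token$intensity > 0)
    cat(sprintf("  token: %dpx @%.2f in %s corner\n",
                x$token$side, x$token$intensity, x$token$corner))
  if (!is.null(x$banner))
    cat(sprintf("  banner: %d rows at %s edge\n", x$banner$rows, x$banner$edge))
  if (any(x$invert_by_department))
    cat("  inverted departments:",
        paste(names(which(x$invert_by_department)), collapse = ", "), "\n")
  invisible(x)
}
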