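#' Patient-level train/tune/test split
#'
#' Assigns every patient (or other grouping unit) to exactly one of the
#' train, tune and test groups, so that no patient's studies straddle
#' splits. Realized group sizes follow the requested fractions by the
#' largest-remainder rule (within one unit of exact rounding).
#'
#' @param meta A `study_set` or its `meta` data frame.
#' @param fractions Named fractions summing to 1 (default 70/10/20).
#' @param seed Seed fixing the assignment.
#' @param group_key Column defining the grouping unit; `patient_id` by
#'   default, or an accession-style study-group column for data without
#'   patient identifiers.
#' @return Named character vector mapping each group id to
#'   `"train"`/`"tune"`/`"test"` (class `split_assignment`).
#' @export
split_by_patient <- function(meta,
                             fractions = c(train = 0.7, tune = 0.1, test = 0.2),
                             seed = 1L, group_key = "patient_id") {
  if (inherits(meta, "study_set")) meta <- meta$meta
  if (nrow(meta) == 0L) stop("empty record list")
  stopifnot(abs(sum(fractions) - 1) < 1e-9, !is.null(names(fractions)),
            group_key %in% names(meta))
  ids <- unique(meta[[group_key]])
  n <- length(ids)
  base <- floor(fractions * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- fractions * n - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  set.seed(seed)
  ids <- sample(ids)
  assignment <- rep(names(fractions), times = base)
  structure(setNames(assignment, ids), class = "split_assignment")
}

#' Engineered-prevalence cohort design
#'
#' A two-site cohort specification fixing the per-site disease prevalence
#' by design while holding the overall prevalence constant.
#'
#' @param name Cohort name.
#' @param site_a,site_b Site ids.
#' @param prevalence_a,prevalence_b Patient-level pneumonia prevalence set
#'   at each site.
#' @param patients_per_site Patients sampled per site (default 10,000).
#' @return An object of class `cohort_spec`. The overall target prevalence
#'   is `(prevalence_a + prevalence_b) / 2`.
#' @export
cohort_spec <- function(name, site_a, prevalence_a, site_b, prevalence_b,
                        patients_per_site = 10000L) {
  stopifnot(prevalence_a >= 0, prevalence_a <= 1,
            prevalence_b >= 0, prevalence_b <= 1, patients_per_site > 0)
  structure(list(name = name, site_a = site_a, prevalence_a = prevalence_a,
                 site_b = site_b, prevalence_b = prevalence_b,
                 patients_per_site = as.integer(patients_per_site),
                 overall = (prevalence_a + prevalence_b) / 2),
            class = "cohort_spec")
}

#' The five standard engineered-prevalence designs
#'
#' Five cohorts of `2 * patients_per_site` patients spanning relative risks
#' from 99:1 in favor of site A to 99:1 in favor of site B, all with a
#' constant 5% overall prevalence: A Severe (A 9.9%, B 0.1%), A Mild
#' (A 9%, B 1%), Balanced (5%, 5%), B Mild (A 1%, B 9%), and B Severe
#' (A 0.1%, B 9.9%).
#'
#' @param site_a,site_b Site ids the designs refer to.
#' @param patients_per_site Patients per site (default 10,000).
#' @return Named list of five [cohort_spec()] objects in severity order
#'   (site-A prevalence decreasing).
#' @export
standard_specs <- function(site_a = "site_a", site_b = "site_b",
                           patients_per_site = 10000L) {
  pa <- c(a_severe = 0.099, a_mild = 0.09, balanced = 0.05,
          b_mild = 0.01, b_severe = 0.001)
  pb <- c(a_severe = 0.001, a_mild = 0.01, balanced = 0.05,
          b_mild = 0.09, b_severe = 0.099)
  out <- lapply(names(pa), function(nm)
    cohort_spec(nm, site_a, pa[[nm]], site_b, pb[[nm]], patients_per_site))
  setNames(out, names(pa))
}

# Patient-level view of a study manifest: one row per patient with sex,
# site, and pneumonia status (positive if any study is positive).
.patient_table <- function(meta) {
  pos <- tapply(meta$pneumonia, meta$patient_id, max)
  first <- !duplicated(meta$patient_id)
  pt <- data.frame(patient_id = meta$patient_id[first],
                   site = meta$site[first], sex = meta$sex[first],
                   stringsAsFactors = FALSE)
  pt$positive <- as.integer(pos[pt$patient_id])
  pt
}

#' Sample an engineered-prevalence cohort
#'
#' Draws patients without replacement from the per-site pools so that each
#' site's patient-level pneumonia positives equal
#' `round(prevalence * patients_per_site)` exactly, with positives and
#' totals split evenly between female and male strata (each sex's
#' prevalence matches the site prevalence to within one patient). Any split
#' assignment already attached to the records is untouched, so train, tune
#' and test membership from prior modeling is maintained.
#'
#' @param meta A `study_set` or its `meta` data frame (the source pools).
#' @param spec A [cohort_spec()].
#' @param seed Seed fixing the sampling.
#' @param balance_sex If `FALSE`, positives are sampled from each site pool
#'   regardless of sex.
#' @return An object of class `engineered_cohort`: list with `spec`,
#'   `patients` (sampled patient table), and `study_idx` (row indices of
#'   the sampled patients' studies in the input manifest).
#' @export
engineer_prevalence_cohort <- function(meta, spec, seed = 1L,
                                       balance_sex = TRUE) {
  if (inherits(meta, "study_set")) meta <- meta$meta
  stopifnot(inherits(spec, "cohort_spec"))
  pt <- .patient_table(meta)
  set.seed(seed)
  take_stratum <- function(site, sex, positive, need) {
    pool <- pt$patient_id[pt$site == site & pt$positive == positive &
                            (is.null(sex) | pt$sex == sex)]
    if (length(pool) < need)
      stop(sprintf("infeasible cohort '%s': stratum %s/%s/%s needs %d patients, pool has %d",
                   spec$name, site, if (is.null(sex)) "any" else sex,
                   if (positive) "positive" else "negative",
                   need, length(pool)))
    if (need == 0L) character(0) else pool[sample.int(length(pool), need)]
  }
  sample_site <- function(site, prev) {
    n <- spec$patients_per_site
    npos <- round(prev * n)
    if (balance_sex) {
      n_f <- round(n / 2); n_m <- n - n_f
      npos_f <- round(npos / 2); npos_m <- npos - npos_f
      c(take_stratum(site, "F", 1L, npos_f),
        take_stratum(site, "M", 1L, npos_m),
        take_stratum(site, "F", 0L, n_f - npos_f),
        take_stratum(site, "M", 0L, n_m - npos_m))
    } else {
      c(take_stratum(site, NULL, 1L, npos),
        take_stratum(site, NULL, 0L, n - npos))
    }
  }
  chosen <- c(sample_site(spec$site_a, spec$prevalence_a),
              sample_site(spec$site_b, spec$prevalence_b))
  structure(list(spec = spec,
                 patients = pt[match(chosen, pt$patient_id), ],
                 study_idx = which(meta$patient_id %in% chosen)),
            class = "engineered_cohort")
}

#' @exportS3Method base::print
print.engineered_cohort <- function(x, ...) {
  cat(sprintf("<engineered_cohort '%s'> %s %.1f%% vs %s %.1f%%: %d patients, %d studies\n",
              x$spec$name, x$spec$site_a, 100 * x$spec$prevalence_a,
              x$spec$site_b, 100 * x$spec$prevalence_b,
              nrow(x$patients), length(x$study_idx)))
  invisible(x)
}

#' Write split or cohort assignments as CSV
#'
#' @param assignment A `split_assignment`, or an `engineered_cohort`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_assignment <- function(assignment, path) {
  df <- if (inherits(assignment, "split_assignment")) {
    data.frame(patient_id = names(assignment), split = unname(assignment))
  } else if (inherits(assignment, "engineered_cohort")) {
    cbind(assignment$patients, cohort_name = assignment$spec$name)
  } else stop("unsupported assignment object")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
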