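#' Consumption survey container
#'
#' A two-table representation of a 24-hour-recall food consumption survey:
#' one row per surveyed person (id, body weight) and one row per consumed
#' food item (person, recall day, food code, amount in g). Days are indexed
#' contiguously from 1; a person-day without records means nothing relevant
#' was consumed that day.
#'
#' @param persons data frame with columns `person_id`, `bw_kg` (> 0).
#' @param records data frame with columns `person_id`, `day`, `food_code`,
#'   `amount_g` (>= 0).
#' @param n_days number of recall days per person (default: max day index).
#' @return A `consumption_survey` list.
#' @export
consumption_survey <- function(persons, records, n_days = NULL) {
  need_p <- c("person_id", "bw_kg")
  need_r <- c("person_id", "day", "food_code", "amount_g")
  if (!all(need_p %in% names(persons))) {
    stop("persons needs columns: ", paste(need_p, collapse = ", "), call. = FALSE)
  }
  if (!all(need_r %in% names(records))) {
    stop("records needs columns: ", paste(need_r, collapse = ", "), call. = FALSE)
  }
  if (any(persons$bw_kg <= 0) || any(!is.finite(persons$bw_kg))) {
    stop("body weights must be positive", call. = FALSE)
  }
  if (nrow(records) > 0) {
    if (any(records$amount_g < 0)) stop("amounts must be >= 0", call. = FALSE)
    if (!all(records$person_id %in% persons$person_id)) {
      stop("record refers to unknown person", call. = FALSE)
    }
  }
  if (is.null(n_days)) n_days <- max(1L, suppressWarnings(max(records$day)))
  structure(list(persons = persons, records = records,
                 n_days = as.integer(n_days)),
            class = "consumption_survey")
}

#' @export
print.consumption_survey <- function(x, ...) {
  cat(sprintf("Consumption survey: %d persons x %d days, %d consumption records\n",
              nrow(x$persons), x$n_days, nrow(x$records)))
  invisible(x)
}

#' Dose-metric specification
#'
#' Exposure and hazard can be expressed per unit mass (mg/kg BW/day) or as a
#' particle count (10^12 N/kg BW/day). The particle metric assumes
#' monodisperse spheres at the median particle diameter with the density of
#' amorphous silica.
#'
#' @param metric `"mass"` or `"particle_number"`.
#' @param diameter_nm median particle diameter in nm (default 100).
#' @param density_g_cm3 particle density in g/cm3 (default 2.2).
#' @return A `dose_metric_spec` list.
#' @export
dose_metric_spec <- function(metric = c("mass", "particle_number"),
                             diameter_nm = 100, density_g_cm3 = 2.2) {
  metric <- match.arg(metric)
  if (!(diameter_nm > 0) || !(density_g_cm3 > 0)) {
    stop("diameter and density must be positive", call. = FALSE)
  }
  structure(list(metric = metric, diameter_nm = diameter_nm,
                 density_g_cm3 = density_g_cm3),
            class = "dose_metric_spec")
}

#' Particle count per unit mass
#'
#' For monodisperse spheres of diameter d and density rho, the count per mg is
#' `1 / (rho * (pi/6) * d^3)` with d in cm and rho in g/cm3.
#'
#' @param spec a [dose_metric_spec()].
#' @return Particles per mg.
#' @examples
#' particles_per_mass(dose_metric_spec("particle_number")) # 8.68e11 per mg
#' @export
particles_per_mass <- function(spec) {
  stopifnot(inherits(spec, "dose_metric_spec"))
  d_cm <- spec$diameter_nm * 1e-7
  mass_g <- spec$density_g_cm3 * (pi / 6) * d_cm^3
  1 / (mass_g * 1000) # per mg
}

#' Link measured silica concentrations to consumed foods
#'
#' Each consumed food is linked to one or more basic (powder) products with a
#' composition fraction. The food's total-silica concentration is
#' `sum(fraction * summary(basic product measurements, mg/g)) * 1000` in ug
#' per g food; the default per-basic-product summary is the arithmetic mean
#' of its measured products.
#'
#' @param conc data frame with columns `basic_product`, `measured_product`,
#'   `total_silica_mg_per_g`.
#' @param links data frame with columns `food_code`, `basic_product`,
#'   `fraction` in (0, 1].
#' @param summary_fun per-basic-product summary statistic (default [mean()]).
#' @return Named numeric vector: ug total silica per g food, by food code.
#' @examples
#' tab <- load_table1_fixture()
#' head(link_concentrations(tab$concentrations, tab$links))
#' @export
link_concentrations <- function(conc, links, summary_fun = mean) {
  stopifnot(all(c("basic_product", "total_silica_mg_per_g") %in% names(conc)),
            all(c("food_code", "basic_product", "fraction") %in% names(links)))
  if (any(links$fraction <= 0 | links$fraction > 1)) {
    stop("link fractions must lie in (0, 1]", call. = FALSE)
  }
  unknown <- setdiff(links$basic_product, conc$basic_product)
  if (length(unknown) > 0) {
    stop("link refers to unknown basic product(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  basic_mean <- vapply(split(conc$total_silica_mg_per_g, conc$basic_product),
                       summary_fun, 0)
  contrib <- links$fraction * basic_mean[links$basic_product] * 1000
  out <- vapply(split(contrib, links$food_code), sum, 0)
  out
}

#' Person-day nanosilica exposure
#'
#' Individual-day exposure: for each person-day,
#' `IDEXP = sum_k amount_g / bw_kg * conc_k * F` in ug/kg BW/day, where
#' `conc_k` is the linked total-silica concentration of food k (ug/g) and F
#' is the nanofraction. Under the particle-number metric the result is
#' additionally multiplied by the particle count per ug and reported in
#' 10^12 N/kg BW/day. Person-days with no (linked) consumption get exposure
#' 0; foods absent from the concentration map contribute 0.
#'
#' @param survey a [consumption_survey()].
#' @param conc_map named vector from [link_concentrations()] (ug/g by food).
#' @param nanofraction scalar F in (0, 1].
#' @param dose_metric a [dose_metric_spec()] (default mass).
#' @return Data frame `person_id`, `day`, `idexp` covering every person-day.
#' @export
compute_person_day_exposures <- function(survey, conc_map, nanofraction = 0.5,
                                         dose_metric = dose_metric_spec()) {
  stopifnot(inherits(survey, "consumption_survey"),
            inherits(dose_metric, "dose_metric_spec"))
  if (!(nanofraction > 0 && nanofraction <= 1)) {
    stop("nanofraction must lie in (0, 1]", call. = FALSE)
  }
  grid <- expand.grid(person_id = survey$persons$person_id,
                      day = seq_len(survey$n_days),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$person_id, survey$persons$person_id), grid$day), ]
  rownames(grid) <- NULL
  grid$idexp <- 0
  rec <- survey$records
  if (nrow(rec) > 0) {
    bw <- stats::setNames(survey$persons$bw_kg, survey$persons$person_id)
    if (any(is.na(bw[as.character(rec$person_id)]))) {
      stop("missing body weight for a consuming person", call. = FALSE)
    }
    conc <- conc_map[as.character(rec$food_code)]
    conc[is.na(conc)] <- 0
    dose <- rec$amount_g / bw[as.character(rec$person_id)] * conc * nanofraction
    key <- paste(rec$person_id, rec$day, sep = "\r")
    per_day <- vapply(split(dose, key), sum, 0)
    gkey <- paste(grid$person_id, grid$day, sep = "\r")
    hit <- match(gkey, names(per_day))
    grid$idexp[!is.na(hit)] <- per_day[hit[!is.na(hit)]]
  }
  if (dose_metric$metric == "particle_number") {
    # per ug = per mg / 1000; reported in units of 10^12 particles
    grid$idexp <- grid$idexp * (particles_per_mass(dose_metric) / 1000 / 1e12)
  }
  grid
}

#' Exceedance curve of a usual-intake distribution
#'
#' `1 - ECDF` evaluated at the sorted unique intake values, using strict
#' exceedance: the curve value at x is the fraction of individuals with
#' intake strictly greater than x.
#'
#' @param values numeric vector of usual intakes (or a `usual_intake_distribution`).
#' @return Data frame with columns `x` and `exceedance`, non-increasing.
#' @export
exceedance_curve <- function(values) {
  if (inherits(values, "usual_intake_distribution")) values <- values$iexp
  if (length(values) == 0) stop("empty distribution", call. = FALSE)
  xs <- sort(unique(values))
  n <- length(values)
  # strict exceedance at each unique value
  exceed <- 1 - cumsum(tabulate(match(sort(values), xs), length(xs))) / n
  data.frame(x = xs, exceedance = exceed)
}

#' Fraction of the population exceeding a value
#'
#' @param values numeric intake values.
#' @param x threshold.
#' @return Fraction with value strictly greater than `x`.
#' @export
fraction_exceeding <- function(values, x) {
  if (inherits(values, "usual_intake_distribution")) values <- values$iexp
  mean(values > x)
}

#' Bootstrap resample a survey at the person level
#'
#' Draws n persons with replacement; each resampled person keeps all their
#' recall days and records and receives a fresh unique id. This is the
#' consumption-data uncertainty resampler of the outer Monte Carlo loop.
#' Uses the current RNG state.
#'
#' @param survey a [consumption_survey()].
#' @return A new `consumption_survey` with the same number of persons.
#' @export
bootstrap_survey <- function(survey) {
  stopifnot(inherits(survey, "consumption_survey"))
  n <- nrow(survey$persons)
  idx <- sample.int(n, n, replace = TRUE)
  new_persons <- survey$persons[idx, , drop = FALSE]
  old_ids <- new_persons$person_id
  new_persons$person_id <- seq_len(n)
  rownames(new_persons) <- NULL
  rec_by_person <- split(survey$records, survey$records$person_id)
  picked <- lapply(seq_len(n), function(i) {
    r <- rec_by_person[[as.character(old_ids[i])]]
    if (is.null(r) || nrow(r) == 0) return(NULL)
    r$person_id <- i
    r
  })
  new_records <- do.call(rbind, c(picked, list(survey$records[0, , drop = FALSE])))
  rownames(new_records) <- NULL
  consumption_survey(new_persons, new_records, n_days = survey$n_days)
}

#' Bootstrap resample a concentration table within basic products
#'
#' Within each basic product, its measured-product rows are resampled with
#' replacement to the same count. This is the concentration-data uncertainty
#' resampler. Uses the current RNG state.
#'
#' @param conc concentration data frame (`basic_product`, `measured_product`,
#'   `total_silica_mg_per_g`, ...).
#' @return A resampled data frame with the same per-basic-product row counts.
#' @export
bootstrap_concentrations <- function(conc) {
  stopifnot(nrow(conc) > 0)
  parts <- lapply(split(conc, conc$basic_product), function(rows) {
    rows[sample.int(nrow(rows), nrow(rows), replace = TRUE), , drop = FALSE]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
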