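# CSV schemas of the pipeline tables
ipra_schemas <- list(
  survey = c("person_id", "bw_kg", "day", "food_code", "amount_g"),
  concentration = c("basic_product", "measured_product", "total_silica_mg_per_g"),
  links = c("food_code", "basic_product", "fraction"),
  dose_response = c("group", "dose_mg_per_kg_bw_day", "rat_id",
                    "positive_slides", "total_slides")
)

check_schema <- function(df, schema, path) {
  missing <- setdiff(ipra_schemas[[schema]], names(df))
  if (length(missing) > 0) {
    stop("file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read and write pipeline tables
#'
#' Plain UTF-8 CSV with mandatory headers and decimal points. The survey is
#' flattened to one row per consumption record, carrying the person's body
#' weight on each row; persons without records survive the round trip via a
#' sentinel row with an empty food code. Numeric fields are written with 12
#' significant digits.
#'
#' @param path file path.
#' @param survey a [consumption_survey()].
#' @name ipra_io
#' @return Readers return the corresponding object; writers return the path
#'   invisibly.
#' @export
read_survey_csv <- function(path) {
  df <- check_schema(utils::read.csv(path, stringsAsFactors = FALSE),
                     "survey", path)
  persons <- unique(df[c("person_id", "bw_kg")])
  rownames(persons) <- NULL
  rec <- df[!is.na(df$food_code) & df$food_code != "",
            c("person_id", "day", "food_code", "amount_g")]
  rownames(rec) <- NULL
  consumption_survey(persons, rec, n_days = max(df$day))
}

#' @rdname ipra_io
#' @export
write_survey_csv <- function(survey, path) {
  stopifnot(inherits(survey, "consumption_survey"))
  df <- merge(survey$records, survey$persons, by = "person_id", sort = FALSE)
  lonely <- setdiff(survey$persons$person_id, survey$records$person_id)
  if (length(lonely) > 0) {
    extra <- data.frame(person_id = lonely, day = survey$n_days,
                        food_code = "", amount_g = NA_real_,
                        bw_kg = survey$persons$bw_kg[
                          match(lonely, survey$persons$person_id)])
    df <- rbind(df, extra)
  }
  df <- df[order(df$person_id, df$day), ipra_schemas$survey]
  write_numeric_csv(df, path)
}

#' @rdname ipra_io
#' @export
read_concentration_csv <- function(path) {
  check_schema(utils::read.csv(path, stringsAsFactors = FALSE),
               "concentration", path)
}

#' @rdname ipra_io
#' @export
read_links_csv <- function(path) {
  check_schema(utils::read.csv(path, stringsAsFactors = FALSE), "links", path)
}

#' @rdname ipra_io
#' @export
read_dose_response_csv <- function(path) {
  df <- check_schema(utils::read.csv(path, stringsAsFactors = FALSE),
                     "dose_response", path)
  dose_response_data(df$dose_mg_per_kg_bw_day, df$positive_slides,
                     df$total_slides)
}

#' @rdname ipra_io
#' @param data a [dose_response_data()].
#' @export
write_dose_response_csv <- function(data, path) {
  stopifnot(inherits(data, "dose_response_data"))
  df <- data.frame(group = match(data$dose, sort(unique(data$dose))),
                   dose_mg_per_kg_bw_day = data$dose,
                   rat_id = stats::ave(data$dose, data$dose,
                                       FUN = seq_along),
                   positive_slides = data$positive,
                   total_slides = data$total)
  write_numeric_csv(df, path)
}

# numeric columns at 12 significant digits, lossless for the pipeline
write_numeric_csv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Missing blocks fall back to the package defaults (the constants of the
#' published assessment: body weights 70 / 0.25 kg, EF_chronic nominal 1.475
#' with lognormal mean 1.80 and sd 1.52, EF_inter p99 = 10, intraspecies
#' sensitivity bounds 2-10, nanofraction p50 = 0.5 and p95 = 0.8, particle
#' diameter 100 nm, density 2.2 g/cm3, 500 outer iterations).
#'
#' @param path YAML file path (optional; `NULL` gives pure defaults).
#' @return List with `extrapolation` ([extrapolation_model()]), `config`
#'   ([ipra_config()]), and `paths` (any file paths given in the YAML).
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  ex <- raw$extrapolation %||% list()
  extrap <- extrapolation_model(
    bw_human = ex$bw_human %||% 70, bw_animal = ex$bw_animal %||% 0.25,
    chronic_nominal = ex$chronic_nominal %||% 1.475,
    chronic_mean = ex$chronic_mean %||% 1.80,
    chronic_sd = ex$chronic_sd %||% 1.52,
    inter_p99 = ex$inter_p99 %||% 10,
    intra_lower = ex$intra_lower %||% 2, intra_upper = ex$intra_upper %||% 10)
  mc <- raw$monte_carlo %||% list()
  dm <- raw$dose_metric %||% list()
  nf <- raw$nanofraction %||% list()
  config <- ipra_config(
    outer = mc$outer %||% 500, inner = mc$inner %||% 1e5,
    master_seed = mc$seed %||% 1L,
    dose_metric = dose_metric_spec(dm$metric %||% "mass",
                                   dm$diameter_nm %||% 100,
                                   dm$density_g_cm3 %||% 2.2),
    nanofraction_model = fit_nanofraction(nf$p50 %||% 0.5, nf$p95 %||% 0.8),
    nominal_nanofraction = nf$nominal %||% 0.5)
  list(extrapolation = extrap, config = config, paths = raw$paths %||% list())
}

#' Write an IMoE result to JSON
#'
#' Serializes the per-iteration percentile table, the nominal run, the bar
#' summaries and the seed/config echo, so a run is reproducible from the
#' file alone.
#'
#' @param result an `imoe_result`.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_imoe_json <- function(result, path) {
  stopifnot(inherits(result, "imoe_result"))
  bars <- lapply(result$config$percentile_pairs, function(pp) {
    unclass(imoe_percentile_bounds(result, pp))
  })
  cfg <- result$config
  out <- list(
    config = list(outer = cfg$outer, inner = cfg$inner,
                  master_seed = cfg$master_seed,
                  dose_metric = unclass(cfg$dose_metric),
                  toggles = as.list(cfg$toggles),
                  nominal_nanofraction = cfg$nominal_nanofraction),
    nominal = as.list(result$nominal),
    skipped = result$skipped,
    bars = bars,
    iterations = result$iterations
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
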