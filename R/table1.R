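# recorded md5 checksums of the packaged concentration/link fixtures
TABLE1_MD5 <- c(
  table1_concentrations.csv = "7c8e962798edc93d8e0b75e861347e1b",
  table1_links.csv = "6fae57b5cdada91d7f60f37b4635473b"
)

#' Load the packaged measured-product concentration table
#'
#' Returns the 25 measured food products with their total-silica contents
#' (mg/g), grouped into 13 basic (powder) products, together with the table
#' linking consumed food types to basic products with composition fractions.
#' Nanosilica values reported below the 0.1 mg/g quantification bound are
#' stored as left-censored at 0.1 (`censored_flag = 1`); they are preserved
#' for completeness but not used by the pipeline, which models the nano
#' fraction of total silica with an uncertainty distribution instead.
#'
#' @param check integrity-check the fixture files against their recorded
#'   checksums (default TRUE).
#' @return List with `concentrations` (25 rows) and `links` data frames.
#' @examples
#' tab <- load_table1_fixture()
#' length(unique(tab$concentrations$basic_product)) # 13
#' @export
load_table1_fixture <- function(check = TRUE) {
  paths <- vapply(names(TABLE1_MD5), function(f) {
    p <- system.file("extdata", f, package = "ipra")
    if (p == "") stop("fixture file missing: ", f, call. = FALSE)
    p
  }, "")
  if (check) {
    got <- unname(tools::md5sum(paths))
    if (!identical(got, unname(TABLE1_MD5))) {
      stop("fixture integrity check failed (checksum mismatch)", call. = FALSE)
    }
  }
  conc <- utils::read.csv(paths[1], stringsAsFactors = FALSE)
  links <- utils::read.csv(paths[2], stringsAsFactors = FALSE)
  list(concentrations = conc, links = links)
}
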