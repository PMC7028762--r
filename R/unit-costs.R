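#' Unit-cost tables
#'
#' A unit-cost table maps each service item to its price in EUR per natural
#' unit (day, visit, unit). The shipped default preset covers the twelve
#' major health- and social-care items used by the costing examples
#' (psychiatric inpatient day 386, somatic inpatient day 576, day-care day
#' 168, psychiatrist visit 45, GP visit 20, sheltered workplace day 48,
#' occupational therapy unit 38, physical therapy unit 16, day-structuring
#' unit 33, contact/counseling-center visit 29, home-nursing visit 22,
#' police contact 62) together with the reporting category each item is
#' aggregated under. Prices are configuration data, not derived quantities.
#'
#' Besides tabled items, utilization records may carry a direct EUR amount
#' under one of the category labels \code{"medication"},
#' \code{"complementary"} or \code{"other_contacts"} for spend without a
#' per-unit price (e.g. medication).
#'
#' @param path Path to a CSV with columns \code{item}, \code{unit_label},
#'   \code{unit_cost_eur}, \code{category} (and optionally \code{source}).
#'   \code{NULL} loads the shipped default preset.
#' @return A data.frame of class \code{"unit_cost_table"}.
#' @examples
#' uc <- unit_cost_table()
#' uc[uc$item == "psychiatric_inpatient_day", "unit_cost_eur"]
#' @export
unit_cost_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "unit_costs_default.csv",
                        package = "prepostCEA", mustWork = TRUE)
  if (!file.exists(path)) stop_("unit-cost table not found: %s", path)
  uc <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  check_columns(uc, c("item", "unit_label", "unit_cost_eur", "category"),
                "unit cost table")
  if (anyDuplicated(uc$item))
    stop_("unit-cost table has duplicate item labels: %s",
          paste(unique(uc$item[duplicated(uc$item)]), collapse = ", "))
  if (any(!is.finite(uc$unit_cost_eur) | uc$unit_cost_eur < 0))
    stop_("unit costs must be finite and >= 0")
  class(uc) <- c("unit_cost_table", "data.frame")
  uc
}

#' @export
print.unit_cost_table <- function(x, ...) {
  cat("Unit-cost table:", nrow(x), "items (EUR per natural unit)\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
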