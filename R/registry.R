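# Drug registry: identities, clinical Cmax and titration designs.

# The ten compounds of the screen with their preliminary concentration
# (clinical Cmax, micromolar) and the top dose of the secondary six-point
# fourfold titration. Values are the screen's published design constants.
.table2 <- data.frame(
  name = c(
    "Cisplatin", "Paclitaxel", "Fluorouracil", "SN-38", "Fedratinib",
    "Gemcitabine", "Epirubicin hydrochloride", "Doxorubicin hydrochloride",
    "Palbociclib", "Docetaxel"
  ),
  cmax_uM = c(13.67, 5.10, 7.5, 0.15, 3.44, 101.04, 0.16, 6.90, 0.22, 2.98),
  secondary_start_uM = c(50, 50, 50, 5, 50, 750, 5, 50, 5, 50),
  dilution_factor = 4,
  n_points = 6L,
  stringsAsFactors = FALSE
)

#' Build a validated drug registry
#'
#' A registry is a data frame with one row per drug carrying its clinical
#' maximum plasma concentration (`cmax_uM`, the preliminary screening dose)
#' and the secondary-titration design: top dose `secondary_start_uM`,
#' `dilution_factor` and `n_points`. All concentrations are micromolar.
#'
#' @param name character vector of unique drug names.
#' @param cmax_uM positive numeric, maximum plasma concentration (uM).
#' @param secondary_start_uM positive numeric, top dose of the titration (uM).
#' @param dilution_factor serial dilution ratio, > 1 (default 4).
#' @param n_points number of titration points, >= 2 (default 6).
#' @return A `drug_registry` data frame.
#' @export
#' @examples
#' drug_registry("drugA", cmax_uM = 1, secondary_start_uM = 10)
drug_registry <- function(name, cmax_uM, secondary_start_uM,
                          dilution_factor = 4, n_points = 6L) {
  reg <- data.frame(
    name = as.character(name),
    cmax_uM = as.numeric(cmax_uM),
    secondary_start_uM = as.numeric(secondary_start_uM),
    dilution_factor = as.numeric(dilution_factor),
    n_points = as.integer(n_points),
    stringsAsFactors = FALSE
  )
  validate_registry(reg)
}

validate_registry <- function(reg) {
  if (anyDuplicated(reg$name)) {
    stop("duplicate drug name in registry: ",
         paste(unique(reg$name[duplicated(reg$name)]), collapse = ", "))
  }
  if (any(!is.finite(reg$cmax_uM)) || any(reg$cmax_uM <= 0)) {
    stop("cmax_uM must be positive and finite for every drug")
  }
  if (any(!is.finite(reg$secondary_start_uM)) || any(reg$secondary_start_uM <= 0)) {
    stop("secondary_start_uM must be positive and finite for every drug")
  }
  if (any(reg$dilution_factor <= 1)) stop("dilution_factor must be > 1")
  if (any(reg$n_points < 1L)) stop("n_points must be >= 1")
  class(reg) <- c("drug_registry", "data.frame")
  reg
}

#' Load a drug registry
#'
#' Either the builtin ten-drug panel (`"table2"`) used throughout the screen,
#' or a CSV file with columns `name, cmax_uM, secondary_start_uM,
#' dilution_factor, n_points` (the last two optional; defaults 4 and 6).
#'
#' @param source `"table2"` or a path to a registry CSV.
#' @return A `drug_registry` data frame.
#' @export
#' @examples
#' reg <- load_registry("table2")
#' reg[reg$name == "Cisplatin", "cmax_uM"]  # 13.67
load_registry <- function(source = "table2") {
  if (identical(source, "table2")) {
    return(validate_registry(.table2))
  }
  if (!file.exists(source)) {
    stop("registry source not found: ", source,
         " (use \"table2\" for the builtin panel)")
  }
  raw <- utils::read.csv(source, stringsAsFactors = FALSE)
  needed <- c("name", "cmax_uM", "secondary_start_uM")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("registry file lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(raw$dilution_factor)) raw$dilution_factor <- 4
  if (is.null(raw$n_points)) raw$n_points <- 6L
  drug_registry(raw$name, raw$cmax_uM, raw$secondary_start_uM,
                raw$dilution_factor, raw$n_points)
}

#' Look up one drug in a registry
#'
#' @param registry a `drug_registry`.
#' @param drug drug name.
#' @return The single matching registry row.
#' @export
registry_drug <- function(registry, drug) {
  hit <- registry[registry$name == drug, , drop = FALSE]
  if (nrow(hit) != 1L) stop("drug not in registry: ", drug)
  hit
}

#' Secondary-screen dilution series for one drug
#'
#' Descending geometric series of `n_points` concentrations starting at the
#' drug's secondary top dose, each step divided by the dilution factor
#' (default fourfold).
#'
#' @param spec one registry row (see [registry_drug()]).
#' @return Numeric vector of concentrations in uM, strictly decreasing.
#' @export
#' @examples
#' dilution_series(registry_drug(load_registry("table2"), "Cisplatin"))
dilution_series <- function(spec) {
  stopifnot(nrow(spec) == 1L)
  spec$secondary_start_uM / spec$dilution_factor^(seq_len(spec$n_points) - 1)
}

#' Drugs of the TP regimen
#'
#' Paclitaxel (taxol) and cisplatin, the perioperative combination whose
#' organoid response defines the AUCsum score; they are always carried into
#' the secondary screen.
#'
#' @return Character vector of the two registry drug names.
#' @export
tp_drugs <- function() c("Paclitaxel", "Cisplatin")
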