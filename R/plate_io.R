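# Well-level plate data: the screen_dataset container and its CSV dialect.

#' Well label used for negative-control (vehicle) wells
#' @export
NC_TAG <- "NC"

.well_columns <- c("organoid_id", "drug", "concentration_uM",
                   "timepoint", "replicate", "signal")

#' Assemble a screen dataset from well measurements
#'
#' A screen dataset bundles a long-format well table (one ATP luminescence
#' read per row) with the drug registry it was run against and the screening
#' stage. Preliminary screens are endpoint-only reads at each drug's Cmax;
#' secondary screens carry paired start (`T0`) and end (`TEND`) reads so that
#' growth-rate inhibition can be computed.
#'
#' @param wells data frame with columns `organoid_id`, `drug` (registry name
#'   or `"NC"`), `concentration_uM` (0 for NC wells), `timepoint` (`"T0"` or
#'   `"TEND"`), `replicate` (positive integer), `signal` (luminescence, >= 0).
#' @param stage `"PRELIMINARY"` or `"SECONDARY"`.
#' @param registry a `drug_registry`; every non-NC drug in `wells` must
#'   appear in it.
#' @return A `screen_dataset` (list with elements `stage`, `wells`,
#'   `registry`).
#' @export
screen_dataset <- function(wells, stage = c("PRELIMINARY", "SECONDARY"),
                           registry = load_registry("table2")) {
  stage <- match.arg(stage)
  missing <- setdiff(.well_columns, names(wells))
  if (length(missing)) {
    stop("well table lacks column(s): ", paste(missing, collapse = ", "))
  }
  wells <- as.data.frame(wells)[, .well_columns]
  wells$organoid_id <- as.character(wells$organoid_id)
  wells$drug <- as.character(wells$drug)
  wells$timepoint <- as.character(wells$timepoint)
  bad_tp <- setdiff(unique(wells$timepoint), c("T0", "TEND"))
  if (length(bad_tp)) {
    stop("unknown timepoint tag(s): ", paste(bad_tp, collapse = ", "))
  }
  if (any(!is.finite(wells$signal)) || any(wells$signal < 0)) {
    stop("signal must be finite and >= 0 in every well")
  }
  if (any(wells$concentration_uM < 0)) {
    stop("concentration_uM must be >= 0")
  }
  if (any(wells$drug == NC_TAG & wells$concentration_uM != 0)) {
    stop("NC wells must have concentration 0")
  }
  unknown <- setdiff(unique(wells$drug), c(NC_TAG, registry$name))
  if (length(unknown)) {
    stop("drug(s) absent from registry: ", paste(unknown, collapse = ", "))
  }
  if (stage == "PRELIMINARY") {
    treated <- wells[wells$drug != NC_TAG, ]
    n_conc <- tapply(treated$concentration_uM, treated$drug,
                     function(x) length(unique(x)))
    if (any(n_conc != 1L)) {
      stop("preliminary screens use a single concentration per drug; ",
           "offending drug(s): ",
           paste(names(n_conc)[n_conc != 1L], collapse = ", "))
    }
  } else {
    nc <- wells[wells$drug == NC_TAG, ]
    for (org in unique(wells$organoid_id)) {
      tps <- unique(nc$timepoint[nc$organoid_id == org])
      if (!all(c("T0", "TEND") %in% tps)) {
        stop("secondary dataset needs both T0 and TEND NC wells for ", org)
      }
    }
  }
  structure(list(stage = stage, wells = wells, registry = registry),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf("<screen_dataset> stage=%s  %d wells  %d organoid(s)  %d drug(s)\n",
              x$stage, nrow(x$wells), length(unique(x$wells$organoid_id)),
              length(setdiff(unique(x$wells$drug), NC_TAG))))
  invisible(x)
}

#' Read a screen dataset from CSV
#'
#' The dialect is comma-separated UTF-8 with a mandatory header and "."
#' decimal separator; columns as documented in [screen_dataset()].
#'
#' @param path CSV file path.
#' @param stage `"PRELIMINARY"` or `"SECONDARY"`.
#' @param registry drug registry the wells were run against.
#' @return A `screen_dataset`.
#' @export
read_screen_csv <- function(path, stage,
                            registry = load_registry("table2")) {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.well_columns, names(raw))
  if (length(missing)) {
    stop("file ", path, " lacks column(s): ", paste(missing, collapse = ", "))
  }
  screen_dataset(raw, stage = stage, registry = registry)
}

#' Write a screen dataset to CSV
#'
#' Inverse of [read_screen_csv()]: `read_screen_csv(write_screen_csv(x))`
#' reproduces the well records exactly (modulo float formatting).
#'
#' @param dataset a `screen_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "screen_dataset"))
  utils::write.csv(dataset$wells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
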