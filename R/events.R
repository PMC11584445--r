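#' Construct an AE event table
#'
#' An ordered table of acoustic-emission events for one specimen: the
#' tensile strain at which each signal was detected, its energy, and the
#' sensor channel that recorded it. Events are sorted by strain (the model
#' is indexed by strain, not clock time); exact strain ties keep both
#' events, ordered by energy descending.
#'
#' @param strain event strains, >= 0.
#' @param energy signal energies, > 0 (any consistent unit).
#' @param channel sensor channel ids (character); recycled if length 1.
#' @param specimen_id opaque specimen label.
#' @return A data frame of class `"ae_events"` with columns
#'   `strain`, `energy`, `channel` and attribute `specimen_id`.
#' @export
ae_events <- function(strain, energy, channel = "central",
                      specimen_id = NA_character_) {
  strain <- as.numeric(strain)
  energy <- as.numeric(energy)
  n <- length(strain)
  if (length(energy) != n)
    stop("'strain' and 'energy' must have equal length", call. = FALSE)
  channel <- rep_len(as.character(channel), n)
  if (n && (any(!is.finite(strain)) || any(strain < 0)))
    stop("event strains must be finite and >= 0", call. = FALSE)
  if (n && (any(!is.finite(energy)) || any(energy <= 0)))
    stop("event energies must be finite and > 0", call. = FALSE)
  # stable sort: strain ascending, ties broken by energy descending
  ord <- order(strain, -energy)
  out <- data.frame(strain = strain[ord], energy = energy[ord],
                    channel = channel[ord], stringsAsFactors = FALSE)
  structure(out, specimen_id = as.character(specimen_id),
            class = c("ae_events", "data.frame"))
}

#' @export
print.ae_events <- function(x, ...) {
  id <- attr(x, "specimen_id")
  cat(sprintf("AE event table%s: %d events",
              if (is.na(id)) "" else paste0(" [", id, "]"), nrow(x)))
  if (nrow(x))
    cat(sprintf(", strain %.4g .. %.4g, channels: %s",
                min(x$strain), max(x$strain),
                paste(unique(x$channel), collapse = ", ")))
  cat("\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' Read an AE event table from delimited text
#'
#' Canonical dialect is CSV with a one-line header and columns
#' `strain`, `energy`, `channel` (extra columns are carried through
#' untouched as opaque metadata). Rows are sorted ascending by strain on
#' read.
#'
#' @param path file path.
#' @param sep field delimiter (default `","`).
#' @param specimen_id label for the sequence; defaults to the file name
#'   without extension.
#' @return An [ae_events()] table.
#' @export
read_ae_events <- function(path, sep = ",", specimen_id = NULL) {
  if (is.null(specimen_id))
    specimen_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         colClasses = NA)
  need <- c("strain", "energy", "channel")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("event table ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("strain", "energy")) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad))
        stop("non-numeric value in column '", col, "' of ", path,
             " at data row ", bad[1L], ": '", v[bad[1L]], "'", call. = FALSE)
      raw[[col]] <- num
    }
  }
  ev <- ae_events(raw$strain, raw$energy, as.character(raw$channel),
                  specimen_id = specimen_id)
  extra <- setdiff(names(raw), need)
  if (length(extra)) {
    ord <- order(raw$strain, -raw$energy)
    for (col in extra) ev[[col]] <- raw[[col]][ord]
  }
  ev
}

#' Write an AE event table to CSV
#'
#' @param events an [ae_events()] table (a `"coxplosive_sim"` realization is
#'   accepted: its strains are written with empty energies on the central
#'   channel).
#' @param path destination file.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_ae_events <- function(events, path, sep = ",") {
  if (inherits(events, "coxplosive_sim"))
    events <- data.frame(strain = events$cum_strains, energy = NA_real_,
                         channel = "central", stringsAsFactors = FALSE)
  utils::write.csv(as.data.frame(events), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Remove friction artifacts from an AE event table
#'
#' During three-point bending the rib ends slide against the supports,
#' producing low-energy signals picked up by the guard sensors at the ends.
#' These are not microfailures and are excluded before any model fitting:
#' an event is kept only if its channel is not a guard channel *and* its
#' energy is at least `e_min`. Friction signals are energetically
#' well-separated from genuine microfailure events, so a single energy
#' threshold suffices; by default the same threshold doubles as the Pareto
#' lower cut-off (see [fit_pareto()]).
#'
#' @param events an [ae_events()] table.
#' @param guard_channels character vector of guard sensor ids (may be
#'   empty).
#' @param e_min energy threshold, >= 0; events strictly below it are
#'   dropped.
#' @return The filtered [ae_events()] table (possibly empty), order
#'   preserved.
#' @export
filter_friction_events <- function(events, guard_channels = character(),
                                   e_min = 0) {
  stopifnot(inherits(events, "ae_events"), length(e_min) == 1L, e_min >= 0)
  keep <- !(events$channel %in% guard_channels) & events$energy >= e_min
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, specimen_id = attr(events, "specimen_id"),
            class = c("ae_events", "data.frame"))
}

#' Number of AE events and maximum strain of a sequence
#'
#' Convenience observables: `n_ae()` is the event count (after whatever
#' filtering has been applied), `eps_max()` the strain of the last event,
#' interpreted as the strain at macroscopic fracture.
#'
#' @param events an [ae_events()] table.
#' @return A scalar.
#' @export
n_ae <- function(events) {
  stopifnot(inherits(events, "ae_events"))
  nrow(events)
}

#' @rdname n_ae
#' @export
eps_max <- function(events) {
  stopifnot(inherits(events, "ae_events"))
  if (!nrow(events)) return(NA_real_)
  max(events$strain)
}

#' Read or write a specimen metadata table
#'
#' Metadata CSV with columns `specimen_id`, `age` (years), `bmi`
#' (kg/m^2).
#'
#' @param path file path.
#' @return `read_specimen_meta()`: a data frame with the three columns.
#' @export
read_specimen_meta <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "age", "bmi")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols))
    stop("metadata table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (any(!is.finite(meta$age)) || any(meta$age <= 0))
    stop("ages must be finite and > 0", call. = FALSE)
  if (any(!is.finite(meta$bmi)) || any(meta$bmi <= 0))
    stop("BMI values must be finite and > 0", call. = FALSE)
  meta$specimen_id <- as.character(meta$specimen_id)
  meta
}

#' @rdname read_specimen_meta
#' @param meta data frame with columns `specimen_id`, `age`, `bmi`.
#' @export
write_specimen_meta <- function(meta, path) {
  stopifnot(all(c("specimen_id", "age", "bmi") %in% names(meta)))
  utils::write.csv(meta[c("specimen_id", "age", "bmi")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read per-specimen result records
#'
#' A specimen record collects metadata, fitted model parameters and the
#' observables used by the cohort stage: `specimen_id`, `age`, `bmi`,
#' `alpha`, `lambda`, `beta`, `nu`, `e_m`, `n_ae`, `eps_max`, `mu_inf`,
#' `phi_min`, `converged`. Missing fitted values round-trip as `NA`.
#' Floats are written with 17 significant digits so that read-after-write
#' reproduces them bit-exactly.
#'
#' @param records a data frame (one row per specimen) or a single record as
#'   a named list.
#' @param path destination CSV.
#' @param append append to an existing file instead of overwriting.
#' @return `read_specimen_records()`: data frame of records.
#' @export
write_specimen_records <- function(records, path, append = FALSE) {
  if (!is.data.frame(records)) records <- as.data.frame(records)
  cols <- specimen_record_columns()
  for (col in setdiff(cols, names(records))) records[[col]] <- NA
  records <- records[cols]
  num <- vapply(records, is.numeric, logical(1L))
  out <- records
  out[num] <- lapply(records[num], function(v)
    ifelse(is.na(v), "", formatC(v, digits = 17, format = "g")))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = !append, quote = FALSE, append = append)
  invisible(path)
}

#' @rdname write_specimen_records
#' @export
read_specimen_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  rec$specimen_id <- as.character(rec$specimen_id)
  if ("converged" %in% names(rec)) rec$converged <- as.logical(rec$converged)
  rec
}

specimen_record_columns <- function() {
  c("specimen_id", "age", "bmi", "alpha", "lambda", "beta", "nu", "e_m",
    "n_ae", "eps_max", "mu_inf", "phi_min", "converged")
}
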