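#' Build a skip-s stimulation/measurement pattern
#'
#' One frame per electrode \code{e}: current is driven between electrodes
#' \code{e} and \code{e + skip + 1} (mod n), i.e. with \code{skip}
#' electrodes in between -- the study hardware used "skipping 4" on a 32
#' electrode belt. Voltages are measured on every pair of the same spacing
#' that does not touch a drive electrode. Conventions for "skip" differ
#' between vendors; here skip counts the electrodes physically between the
#' pair members, so skip 0 is the classical adjacent pattern.
#'
#' @param nElectrodes electrode count (> skip + 1)
#' @param skip electrodes skipped between pair members (study value 4)
#' @param current injected current in mA; the study used 1-4 mA per subject
#'   (a warning is issued outside that range)
#' @return a \code{\link{StimulationPattern}}
#' @examples
#' pat <- makeSkipPattern(32, skip = 4, current = 2)
#' length(pat@frames)
#' @export
makeSkipPattern <- function(nElectrodes, skip = 4L, current = 2) {
  nElectrodes <- as.integer(nElectrodes)
  skip <- as.integer(skip)
  if (skip < 0L || skip >= nElectrodes - 1L)
    stop("invalid pattern: need 0 <= skip < nElectrodes - 1", call. = FALSE)
  if (current < 1 || current > 4)
    warning("injection current ", current, " mA is outside the study's 1-4 mA range")
  sep <- skip + 1L
  frames <- lapply(seq_len(nElectrodes), function(e) {
    drive <- c(e, (e - 1L + sep) %% nElectrodes + 1L)
    m <- seq_len(nElectrodes)
    mp <- cbind(m, (m - 1L + sep) %% nElectrodes + 1L)
    touches <- mp[, 1] %in% drive | mp[, 2] %in% drive
    list(drive = drive, current = current,
         measPairs = mp[!touches, , drop = FALSE])
  })
  new("StimulationPattern", nElectrodes = nElectrodes, skip = skip,
      frames = frames)
}

#' Total number of measurements in a pattern
#' @param pattern a \code{\link{StimulationPattern}}
#' @return integer, summed over frames
#' @export
nMeasurements <- function(pattern) {
  sum(vapply(pattern@frames, function(f) nrow(f$measPairs), integer(1)))
}

# (frame, row) index table for the stacked voltage vector
measurementIndex <- function(pattern) {
  do.call(rbind, lapply(seq_along(pattern@frames), function(i) {
    f <- pattern@frames[[i]]
    if (!nrow(f$measPairs)) return(NULL)
    data.frame(frame = i, drive_pos = f$drive[1], drive_neg = f$drive[2],
               meas_pos = f$measPairs[, 1], meas_neg = f$measPairs[, 2],
               current_mA = f$current)
  }))
}

setMethod("nElectrodes", "StimulationPattern", function(x) x@nElectrodes)

setMethod("show", "StimulationPattern", function(object) {
  cat(sprintf("StimulationPattern: %d electrodes, skip %d, %d frames, %d measurements\n",
              object@nElectrodes, object@skip, length(object@frames),
              nMeasurements(object)))
})

setMethod("voltages", "MeasurementSet", function(x) x@voltages)

setMethod("show", "MeasurementSet", function(object) {
  nm <- object@noiseModel
  cat(sprintf("MeasurementSet: %d voltages (%d frames), %g kHz, noise: %s\n",
              length(object@voltages), length(object@pattern@frames),
              object@frequencyKHz,
              if (identical(nm$type, "none")) "none"
              else if (identical(nm$type, "additive"))
                sprintf("additive sd %.3g V (seed %d)", nm$sd, object@seed)
              else sprintf("multiplicative %.3g (seed %d)", nm$fraction,
                           object@seed)))
})

#' Write / read a measurement set as CSV with JSON sidecar
#'
#' CSV columns: \code{frame, drive_pos, drive_neg, meas_pos, meas_neg,
#' current_mA, voltage_V} (one row per frame x measurement pair, voltages at
#' 17 significant digits). The sidecar \code{<path>.json} stores frequency,
#' noise model, seed, electrode count, skip and mesh id, so the pair
#' round-trips exactly.
#'
#' @param data a \code{\link{MeasurementSet}}
#' @param path CSV file path (sidecar written at \code{<path>.json})
#' @return \code{readMeasurements} returns a \code{MeasurementSet};
#'   \code{writeMeasurements} returns \code{path} invisibly.
#' @export
writeMeasurements <- function(data, path) {
  idx <- measurementIndex(data@pattern)
  idx$voltage_V <- fmtG(data@voltages)
  utils::write.csv(idx, path, row.names = FALSE, quote = FALSE)
  side <- list(frequency_khz = data@frequencyKHz,
               noise_model = data@noiseModel,
               seed = if (is.na(data@seed)) NULL else data@seed,
               n_electrodes = data@pattern@nElectrodes,
               skip = data@pattern@skip,
               mesh_id = data@meshId)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeMeasurements
#' @export
readMeasurements <- function(path) {
  df <- utils::read.csv(path, colClasses = c(rep("integer", 5),
                                             "numeric", "numeric"))
  need <- c("frame", "drive_pos", "drive_neg", "meas_pos", "meas_neg",
            "current_mA", "voltage_V")
  if (!identical(names(df), need))
    stop("malformed measurement CSV: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyNA(df)) stop("malformed measurement CSV: missing values", call. = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pattern <- makeSkipPattern(side$n_electrodes, side$skip,
                             current = df$current_mA[1])
  idx <- measurementIndex(pattern)
  if (nrow(idx) != nrow(df) ||
      !all(idx$frame == df$frame & idx$meas_pos == df$meas_pos &
             idx$meas_neg == df$meas_neg))
    stop("measurement CSV rows do not match the declared skip pattern",
         call. = FALSE)
  noise <- as.list(side$noise_model)
  new("MeasurementSet", pattern = pattern, voltages = df$voltage_V,
      frequencyKHz = side$frequency_khz, noiseModel = noise,
      seed = if (is.null(side$seed)) NA_integer_ else as.integer(side$seed),
      meshId = side$mesh_id %||% "")
}
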