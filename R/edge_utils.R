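# Field-deployment glue: streaming detection over a recording, the
# serial payload codec used between the edge device and the uplink
# radio, and battery-budget arithmetic.

#' Species code table
#'
#' Small-integer codes 0-7 in descending order of survey abundance, the
#' order used throughout the package.
#'
#' @return Named integer vector mapping species name to code.
#' @export
bat_species_codes <- function() {
  species <- names(bat_call_templates())
  stats::setNames(seq_along(species) - 1L, species)
}

#' Construct a detection event
#'
#' @param species_code Small integer code (see [bat_species_codes()]).
#' @param species_name Scientific name.
#' @param latitude,longitude Coordinates in decimal degrees.
#' @param timestamp `POSIXct` time or an ISO 8601 string.
#' @return An object of class `detection_event`.
#' @export
detection_event <- function(species_code, species_name, latitude, longitude,
                            timestamp = Sys.time()) {
  if (latitude < -90 || latitude > 90) stop_invalid("latitude out of range [-90, 90]")
  if (longitude < -180 || longitude > 180) stop_invalid("longitude out of range [-180, 180]")
  if (inherits(timestamp, "POSIXt")) timestamp <- format_iso8601(timestamp)
  structure(list(species_code = as.integer(species_code),
                 species_name = as.character(species_name),
                 latitude = as.numeric(latitude),
                 longitude = as.numeric(longitude),
                 timestamp = timestamp),
            class = "detection_event")
}

format_iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' @export
print.detection_event <- function(x, ...) {
  cat(sprintf("<detection> %s (code %d) at (%g, %g), %s\n",
              x$species_name, x$species_code, x$latitude, x$longitude, x$timestamp))
  invisible(x)
}

#' Run the full detection pipeline over a recording
#'
#' Relabels a native-rate recording to the pipeline rate, cuts it into
#' fixed-length segments, featurizes each and classifies it; a detection
#' event is emitted for every segment whose top class probability exceeds
#' the confidence threshold. With `threshold = 0` every segment emits,
#' mirroring an always-on field unit. Events are timestamped from the
#' segment offsets on the relabelled (time-expanded) time axis.
#'
#' @param waveform Numeric samples at `fs_native`.
#' @param fs_native Native sample rate in Hz.
#' @param model Trained classifier (`echo_model`).
#' @param config A [feature_config()].
#' @param threshold Confidence threshold in `[0, 1]`.
#' @param latitude,longitude Deployment coordinates.
#' @param start_time `POSIXct` timestamp of the recording start.
#' @return List of `detection_event`s (possibly empty).
#' @export
run_detection_pipeline <- function(waveform, fs_native, model,
                                   config = feature_config(), threshold = 0.5,
                                   latitude = 0, longitude = 0,
                                   start_time = Sys.time()) {
  rl <- relabel_rate(waveform, fs_native, config$fs_target)
  segments <- segment_audio(rl$waveform, rl$fs, config$segment_s)
  if (length(segments) == 0L) return(list())
  codes <- bat_species_codes()
  events <- list()
  for (k in seq_along(segments)) {
    img <- featurize_segment(segments[[k]], config)
    if (dim(img)[2] != model$spec$input_shape[2]) {
      img <- crop_image_width(img, model$spec$input_shape[2])
    }
    probs <- predict(model, img)
    top <- which.max(probs[1L, ])
    if (probs[1L, top] > threshold) {
      name <- colnames(probs)[top]
      code <- if (!is.null(name) && name %in% names(codes)) codes[[name]] else top - 1L
      events[[length(events) + 1L]] <- detection_event(
        code, if (is.null(name)) as.character(top - 1L) else name,
        latitude, longitude,
        timestamp = start_time + (k - 1L) * config$segment_s)
    }
  }
  events
}

#' Encode a detection as the serial payload string
#'
#' The wire format between the edge device and the radio is a bare
#' comma-separated `code,lat,lon` string with decimal points and no
#' spaces; the timestamp is attached server-side at decode time.
#'
#' @param event A [detection_event()].
#' @return Payload string, e.g. `"3,25.3,55.5"`.
#' @export
encode_detection <- function(event) {
  stopifnot(inherits(event, "detection_event"))
  # as.character always uses a decimal point, independent of locale
  paste(as.character(event$species_code),
        as.character(event$latitude),
        as.character(event$longitude), sep = ",")
}

#' Decode a serial payload into a detection event
#'
#' Parses `"int,float,float"`, attaches a timestamp from the supplied
#' clock and resolves the species code against the code table.
#'
#' @param payload Payload string.
#' @param species_table Named code vector as from [bat_species_codes()].
#' @param clock Function returning the current `POSIXct` time.
#' @return A [detection_event()].
#' @export
decode_detection <- function(payload, species_table = bat_species_codes(),
                             clock = Sys.time) {
  parts <- strsplit(payload, ",", fixed = TRUE)[[1]]
  if (length(parts) != 3L) stop_invalid("payload must have 3 comma-separated fields, got %d", length(parts))
  if (!grepl("^-?[0-9]+$", parts[1])) {
    stop_invalid("field 1 ('%s') is not an integer species code", parts[1])
  }
  for (i in 2:3) {
    if (!grepl("^-?[0-9]+(\\.[0-9]+)?$", parts[i])) {
      stop_invalid("field %d ('%s') is not a decimal number", i, parts[i])
    }
  }
  code <- as.integer(parts[1])
  hit <- match(code, species_table)
  if (is.na(hit)) stop_invalid("unknown species code %d", code)
  detection_event(code, names(species_table)[hit],
                  as.numeric(parts[2]), as.numeric(parts[3]),
                  timestamp = format_iso8601(clock()))
}

#' Power budget of a battery-operated field unit
#'
#' @param current_mA Average current draw in milliamps.
#' @param voltage_V Supply voltage in volts.
#' @param capacity_Ah Battery capacity in amp-hours.
#' @param derating Fraction of the nominal runtime kept as a conservative
#'   estimate of real-world usage.
#' @return An object of class `power_budget`.
#' @export
power_budget <- function(current_mA, voltage_V, capacity_Ah, derating = 0.5) {
  assert_scalar_positive(current_mA, "current_mA")
  assert_scalar_positive(voltage_V, "voltage_V")
  assert_scalar_positive(capacity_Ah, "capacity_Ah")
  if (derating <= 0 || derating > 1) stop_invalid("derating must be in (0, 1]")
  structure(list(current_mA = current_mA, voltage_V = voltage_V,
                 capacity_Ah = capacity_Ah, derating = derating),
            class = "power_budget")
}

#' Battery life in whole hours
#'
#' Energy is `capacity_Ah * voltage_V` watt-hours and draw is
#' `voltage_V * current_mA / 1000` watts; the nominal runtime is floored
#' to whole hours and the derated figure applies the conservative factor.
#' A 528 mA draw at 5 V on a 50 Ah bank gives 250 Wh / 2.64 W: 94 h
#' nominal, 47 h derated at 50%.
#'
#' @param budget A [power_budget()].
#' @return List with `full_hours` and `derated_hours` (integers).
#' @examples
#' battery_life_hours(power_budget(528, 5, 50, 0.5))
#' @export
battery_life_hours <- function(budget) {
  stopifnot(inherits(budget, "power_budget"))
  energy_wh <- budget$capacity_Ah * budget$voltage_V
  power_w <- budget$voltage_V * budget$current_mA / 1000
  full <- floor(energy_wh / power_w)
  list(full_hours = as.integer(full),
       derated_hours = as.integer(floor(full * budget$derating)))
}
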