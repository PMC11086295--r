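test_that("battery arithmetic reproduces the worked field example", {
  hours <- battery_life_hours(power_budget(528, 5, 50, 0.5))
  expect_equal(hours$full_hours, 94L)    # floor(250 Wh / 2.64 W)
  expect_equal(hours$derated_hours, 47L)
  expect_equal(battery_life_hours(power_budget(1000, 5, 1, 1))$full_hours, 1L)
})

test_that("battery life scales homothetically with capacity", {
  h1 <- battery_life_hours(power_budget(200, 5, 10, 1))$full_hours
  h2 <- battery_life_hours(power_budget(200, 5, 20, 1))$full_hours
  expect_equal(h2, 2L * h1)
  expect_error(power_budget(0, 5, 10), "current_mA")
})

test_that("payloads encode as bare comma-separated code,lat,lon", {
  ev <- detection_event(3L, "P_kuhli", 25.30, 55.50,
                        timestamp = as.POSIXct("2024-05-01 12:00:00", tz = "UTC"))
  expect_equal(encode_detection(ev), "3,25.3,55.5")
  expect_false(grepl(" ", encode_detection(ev)))
})

test_that("payloads decode, resolve species and attach ISO 8601 timestamps", {
  clock <- function() as.POSIXct("2024-05-01 21:30:05", tz = "UTC")
  ev <- decode_detection("2,24.1,-55.0", clock = clock)
  expect_equal(ev$species_code, 2L)
  expect_equal(ev$species_name, "P_kuhli")
  expect_equal(ev$longitude, -55.0)
  expect_equal(ev$timestamp, "2024-05-01T21:30:05Z")
  expect_match(ev$timestamp, "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}Z$")
  expect_error(decode_detection("x,1,2"), "field 1")
  expect_error(decode_detection("1,2"), "3 comma-separated")
  expect_error(decode_detection("99,1,2"), "99")
})

test_that("encode then decode is the identity on the payload fields", {
  for (ev in list(detection_event(0L, "R_muscatellum", 0, 0),
                  detection_event(7L, "A_tridens", -12.25, 130.5))) {
    back <- decode_detection(encode_detection(ev))
    expect_equal(back$species_code, ev$species_code)
    expect_equal(back$latitude, ev$latitude)
    expect_equal(back$longitude, ev$longitude)
  }
})

test_that("coordinates and species codes are validated", {
  expect_error(detection_event(1L, "x", 95, 0), "latitude")
  expect_error(detection_event(1L, "x", 0, 200), "longitude")
})

test_that("the detection pipeline emits one event per confident segment", {
  model <- nn_init(build_classifier_spec(n_classes = 8L), seed = 2L)
  model$levels <- names(bat_species_codes())
  # nine pipeline-seconds of audio at the native rate
  n <- 9L * 44100L
  wave <- sin(2 * pi * 40e3 * (0:(n - 1L)) / 384000)
  t0 <- as.POSIXct("2024-05-01 20:00:00", tz = "UTC")
  all_events <- run_detection_pipeline(wave, 384000, model, threshold = 0,
                                       latitude = 25.3, longitude = 55.5,
                                       start_time = t0)
  expect_length(all_events, 3L)  # floor(9 / 3) segments, threshold 0 emits all
  expect_equal(all_events[[1]]$timestamp, "2024-05-01T20:00:00Z")
  expect_equal(all_events[[3]]$timestamp, "2024-05-01T20:00:06Z")
  expect_true(all(vapply(all_events, function(e) e$latitude, numeric(1)) == 25.3))
  # an untrained network is near-uniform: a 0.99 threshold silences it
  none <- run_detection_pipeline(wave, 384000, model, threshold = 0.99)
  expect_length(none, 0L)
  # audio shorter than one segment produces no events
  expect_length(run_detection_pipeline(numeric(1000), 384000, model), 0L)
})
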