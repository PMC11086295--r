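# Shared fixtures: small templates and cached image stacks so the slower
# pipeline pieces run once per suite.

fast_templates <- function() {
  list(
    call_template("low",  "FM_sweep", 30e3, 24e3, 0.004, 0.040),
    call_template("mid",  "FM_sweep", 55e3, 38e3, 0.004, 0.045),
    call_template("high", "FM_sweep", 90e3, 60e3, 0.003, 0.050),
    call_template("cf",   "CF",       120e3, 120e3, 0.005, 0.055)
  )
}

# one cached tiny image stack (4 classes x 6 segments) for model-level tests
tiny_image_stack <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(fast_templates(), rep(6L, 4), seed = 101L, snr_db = 25)
      cache <<- dataset_to_images(ds)
    }
    cache
  }
})

# reference per-class totals of the emulated survey (train/val/test below)
survey_class_totals <- c(
  R_muscatellum = 1666L, T_perforatus = 403L, P_kuhli = 299L,
  R_nasutus = 269L, E_bottae = 123L, R_aegyptius = 121L,
  M_emarginatus = 112L, A_tridens = 26L
)

survey_split_table <- matrix(
  c(1199L, 300L, 167L,
    290L,  73L,  40L,
    215L,  54L,  30L,
    194L,  48L,  27L,
    89L,   22L,  12L,
    87L,   22L,  12L,
    81L,   20L,  11L,
    18L,   5L,   3L),
  ncol = 3, byrow = TRUE,
  dimnames = list(names(survey_class_totals), c("train", "val", "test"))
)
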