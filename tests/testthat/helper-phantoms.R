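# Shared phantom configurations for tests.
#
# "small": a 40 x 56 x 56 grid at 2 mm -- runs in well under a second,
# used wherever geometry rather than classification accuracy is at stake.
# "easy": the easy-contrast regime (tumor 60 HU vs liver 100 HU, noise
# sd 8) on a 64 x 96 x 96 grid at 1.5 mm with 8-14 mm lesions, used for
# the end-to-end segmentation checks. At this desk scale the matching
# physical texture neighborhood is window = 7 (10.5 mm).

small_config <- function(seed, n_tumors = 4, tumor_radius_mm = c(5, 9),
                         noise_sd = 5, ...) {
  phantom_config(dim = c(40L, 56L, 56L), spacing = c(2, 2, 2),
                 liver_semiaxes_mm = c(30, 44, 44),
                 n_tumors = n_tumors, tumor_radius_mm = tumor_radius_mm,
                 noise_sd = noise_sd, seed = seed, ...)
}

easy_config <- function(seed, ...) {
  phantom_config(dim = c(64L, 96L, 96L), spacing = c(1.5, 1.5, 1.5),
                 liver_semiaxes_mm = c(40, 60, 60),
                 n_tumors = 5L, tumor_radius_mm = c(8, 14),
                 noise_sd = 8, seed = seed, ...)
}

desk_window <- 7L

# A classifier trained once on an easy-contrast phantom and reused by the
# segmentation tests (training phantom seed is disjoint from all test
# phantom seeds).
trained_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- make_phantom(easy_config(990))
      cache <<- train_phantom_classifier(tr, n_per_class = 3000L,
                                         window = desk_window, seed = 1L)
    }
    cache
  }
})
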