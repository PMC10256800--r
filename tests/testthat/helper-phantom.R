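# Shared small fixtures, built once per test run.

small_spec <- function(seed = 7L) {
  phantom_spec(shape = c(48, 48, 48), spacing = c(4, 4, 4), seed = seed)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_phantom <- function() cached("phantom", function() {
  make_lung_phantom(small_spec())
})

small_dose <- function() cached("dose", function() {
  make_dose(small_phantom())
})

# tiny volume helper for unit tests
toy_volume <- function(data = array(0, c(4, 4, 4)), spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  image_volume(data, spacing, origin)
}

full_mask <- function(vol, label = "lung") {
  roi_mask(array(TRUE, dim(vol$data)), vol, label = label)
}
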