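# Programmatic fixtures. Everything is built in code at test time; nothing is
# stored on disk.

# Solid-color labeled image with optional boxes.
solid_image <- function(H, W, value = 100L, class_id = 0L, boxes = list(),
                        id = "fix_1") {
  px <- array(as.integer(value), c(H, W, 3))
  structure(list(pixels = px, class_id = as.integer(class_id), boxes = boxes,
                 image_id = id),
            class = "labeled_image")
}

constant_window <- function(values = c(temperature = 25, humidity = 60,
                                       light = 500, co2 = 400), hours = 24) {
  readings <- matrix(rep(values, hours), 4, hours,
                     dimnames = list(names(values), NULL))
  structure(list(readings = readings, channel_names = names(values),
                 window_hours = as.integer(hours)),
            class = "sensor_window")
}

# One shared small dataset per test session (cheap to build, reused widely).
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(6, confusability = 0.5, seed = 97)
    }
    cache
  }
})
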