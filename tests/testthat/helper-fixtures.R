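# Shared, lazily computed fixtures. Everything is generated in-session
# from seeds; no binary fixtures are shipped.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, compute) {
  if (is.null(.fixtures[[name]])) assign(name, compute(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# the default synthetic fixture (generator defaults)
default_fixture <- function() {
  fixture("default_slide", function() generate_slide(synth_config()))
}

# a small fixture for fast module tests
small_fixture <- function() {
  fixture("small_slide", function() generate_slide(synth_config(size = 512L,
                                                                seed = 5L)))
}

# a toy slide: constant-intensity channels
toy_slide <- function(nr = 64, nc = nr, value = 100L, pixel_size = 1,
                      channels = c("DAPI", "FITC")) {
  ch <- stats::setNames(
    lapply(channels, function(z) matrix(as.integer(value), nr, nc)),
    channels)
  slide(ch, pixel_size = pixel_size)
}

# a hand-built ObjectLayer from an explicit label matrix (features computed)
toy_layer <- function(labels, pixel_size = 1, x = NULL) {
  if (is.null(x))
    x <- toy_slide(nrow(labels), ncol(labels), pixel_size = pixel_size)
  layer <- slidequant:::object_layer(labels, scale = 1, x)
  compute_features(layer, x)
}

# draw a filled disk of a value onto a matrix (test-side renderer)
draw_disk <- function(m, row, col, radius, value) {
  rr <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  cc <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  m[(rr - row)^2 + (cc - col)^2 <= radius^2] <- value
  m
}
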