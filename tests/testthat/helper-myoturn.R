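# shared fixtures, built in code at test time

geom_default <- filament_geometry()

render_quiet <- render_config(noise_sd = 0)

# all-green (pre-chase) filament site table
sites_green <- function(geom = geom_default) {
  tibble::tibble(x = geom$x, label = "green")
}

# filament with red labels on a selection of sites
sites_with_red <- function(sel, geom = geom_default) {
  s <- sites_green(geom)
  s$label[sel] <- "red"
  s
}

# synthetic normalized waveform built directly on the standard grid,
# bypassing rendering; green is a broad central hump unless overridden
make_waveform <- function(red_fun, green_fun = NULL, grid_n = 201,
                          green_scale = 1, red_scale = 1,
                          id = 1L, myotube = 1L, time_min = 15) {
  x <- seq(-1, 1, length.out = grid_n)
  g <- if (is.null(green_fun)) pmax(1 - (x / 0.85)^2, 0) else green_fun(x)
  r <- red_fun(x)
  g <- g / max(g)
  r <- if (max(r) > 0) r / max(r) else r
  w <- tibble::new_tibble(list(x_norm = x, green = g, red = r),
                          class = "sarcomere_waveform")
  attr(w, "green_scale") <- green_scale
  attr(w, "red_scale") <- red_scale
  attr(w, "empty_channels") <- if (red_scale <= 0) "red" else character(0)
  attr(w, "sarcomere_id") <- id
  attr(w, "myotube") <- myotube
  attr(w, "time_min") <- time_min
  w
}

gauss <- function(mu, sd = 0.12, h = 1) {
  function(x) h * exp(-(x - mu)^2 / (2 * sd^2))
}

# mirror a waveform about x = 0 (grid is symmetric)
mirror_waveform <- function(w) {
  m <- w
  m$green <- rev(w$green)
  m$red <- rev(w$red)
  m
}

expect_category <- function(w, expected, rules = classification_rules()) {
  expect_identical(as.character(classify_pattern(w, rules)$category),
                   expected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
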