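# Fixtures built in code; no data files.

# one office exactly at every Scheme-1 limit
record_at_limits <- function(scheme = scheme_hk(1)) {
  tibble::as_tibble(as.list(scheme$limits))
}

# one office comfortably below both schemes' limits
record_clean <- function() {
  tibble::tibble(co2 = 500, co = 1, rsp = 20, no2 = 30, o3 = 20, hcho = 15,
                 tvoc = 150, radon = 40, abc = 200)
}

# n random records spanning below/above the limits (for label properties)
random_records <- function(n, seed = 1) {
  lim <- scheme_hk(1)$limits
  iaqscreen:::with_seed(seed, {
    out <- purrr::map(lim, function(l) stats::runif(n, 0, 1.4 * l))
    tibble::as_tibble(out)
  })
}

# linearly separable toy classification set: label is a threshold on x1
separable_set <- function(n = 20, seed = 4) {
  iaqscreen:::with_seed(seed, {
    x <- tibble::tibble(x1 = stats::runif(n), x2 = stats::runif(n))
    y <- factor(ifelse(x$x1 > 0.5, "satisfactory", "unsatisfactory"),
                levels = c("satisfactory", "unsatisfactory"))
    list(x = x, y = y)
  })
}

# small labelled synthetic survey shared across tests
small_survey <- function(n = 300, seed = 7) {
  generate_offices(n_offices = n, seed = seed)
}
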