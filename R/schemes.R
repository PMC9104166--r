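#' Pollutant identifiers used throughout the package
#'
#' The nine pollutants measured in the Hong Kong office IAQ certification
#' protocol, in canonical column order: carbon dioxide (`co2`, ppm), carbon
#' monoxide (`co`, ppm), respirable suspended particulates (`rsp`, ug/m3),
#' nitrogen dioxide (`no2`, ug/m3), ozone (`o3`, ug/m3), formaldehyde
#' (`hcho`, ug/m3), total volatile organic compounds (`tvoc`, ug/m3), radon
#' (`radon`, Bq/m3) and airborne bacteria count (`abc`, CFU/m3).
#'
#' @format Character vector of length 9.
#' @export
iaq_pollutants <- c("co2", "co", "rsp", "no2", "o3", "hcho", "tvoc",
                    "radon", "abc")

#' The three surrogate indicators
#'
#' CO2, RSP and TVOC: the easily measured pollutants used as surrogates for
#' the full nine-parameter assessment. CO2 tracks occupant load and
#' ventilation, RSP tracks filtration performance, TVOC tracks building and
#' activity emissions.
#'
#' @format Character vector of length 3.
#' @export
iaq_surrogates <- c("co2", "rsp", "tvoc")

#' Construct an IAQ assessment scheme
#'
#' A scheme is a named, complete set of 8-h exposure limits, one per
#' pollutant, against which an office is assessed. An office is satisfactory
#' under a scheme iff every pollutant is at or below its limit.
#'
#' @param limits Named numeric vector or list with one positive limit for
#'   each of the nine [iaq_pollutants], in the units documented there.
#' @param name Label for the scheme.
#' @return An object of class `iaq_scheme`: a list with elements `name` and
#'   `limits` (named numeric, canonical pollutant order).
#' @examples
#' new_scheme(c(co2 = 1000, co = 8.7, rsp = 180, no2 = 150, o3 = 120,
#'              hcho = 100, tvoc = 600, radon = 200, abc = 1000), "custom")
#' @export
new_scheme <- function(limits, name = "scheme") {
  limits <- unlist(limits)
  missing <- setdiff(iaq_pollutants, names(limits))
  if (length(missing) > 0L) {
    stop("invalid scheme: missing limits for ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(limits), iaq_pollutants)
  if (length(extra) > 0L) {
    stop("invalid scheme: unknown pollutants ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  limits <- limits[iaq_pollutants]
  if (!all(is.finite(limits)) || any(limits <= 0)) {
    stop("invalid scheme: all limits must be finite and > 0", call. = FALSE)
  }
  structure(list(name = as.character(name), limits = limits),
            class = "iaq_scheme")
}

#' Built-in Hong Kong exposure-limit schemes
#'
#' The two columns of the Hong Kong IAQ Certification Scheme "satisfactory"
#' class: Scheme 1 is the pre-2019 objective; Scheme 2 is the 2019 update,
#' which tightens carbon monoxide (8.7 to 6.1 ppm), respirable particulates
#' (180 to 100 ug/m3) and radon (200 to 167 Bq/m3) and leaves the other six
#' limits unchanged. Every Scheme-2 limit is at most its Scheme-1
#' counterpart, so satisfaction under Scheme 2 implies satisfaction under
#' Scheme 1.
#'
#' @param version 1 (old objective) or 2 (updated objective).
#' @return An `iaq_scheme`.
#' @examples
#' scheme_hk(1)$limits
#' scheme_hk(2)$limits[c("co", "rsp", "radon")]
#' @export
scheme_hk <- function(version = 1) {
  version <- as.character(version)
  switch(version,
    "1" = new_scheme(
      c(co2 = 1000, co = 8.7, rsp = 180, no2 = 150, o3 = 120,
        hcho = 100, tvoc = 600, radon = 200, abc = 1000),
      name = "scheme1"),
    "2" = new_scheme(
      c(co2 = 1000, co = 6.1, rsp = 100, no2 = 150, o3 = 120,
        hcho = 100, tvoc = 600, radon = 167, abc = 1000),
      name = "scheme2"),
    stop("unknown scheme version: ", version, call. = FALSE)
  )
}

#' @export
print.iaq_scheme <- function(x, ...) {
  cat("<iaq_scheme> ", x$name, "\n", sep = "")
  print(x$limits)
  invisible(x)
}

#' @export
format.iaq_scheme <- function(x, ...) x$name

#' Read or write a scheme file
#'
#' Schemes are stored as flat YAML: a `name` key plus one `pollutant: limit`
#' entry per pollutant. Files reproducing the two built-in Hong Kong schemes
#' ship with the package under `extdata/`.
#'
#' @param path File path.
#' @return `read_scheme()` returns an `iaq_scheme`; `write_scheme()` returns
#'   `path` invisibly.
#' @examples
#' read_scheme(system.file("extdata", "scheme_1.yaml", package = "iaqscreen"))
#' @export
read_scheme <- function(path) {
  raw <- yaml::read_yaml(path)
  name <- raw$name %||% tools::file_path_sans_ext(basename(path))
  raw$name <- NULL
  new_scheme(unlist(raw), name = name)
}

#' @rdname read_scheme
#' @param scheme An `iaq_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "iaq_scheme"))
  yaml::write_yaml(c(list(name = scheme$name), as.list(scheme$limits)),
                   path, precision = 15)
  invisible(path)
}

resolve_scheme <- function(scheme) {
  if (inherits(scheme, "iaq_scheme")) return(scheme)
  if (is.character(scheme) && length(scheme) == 1L) {
    if (scheme %in% c("1", "2", "scheme1", "scheme2")) {
      return(scheme_hk(gsub("scheme", "", scheme)))
    }
    if (file.exists(scheme)) return(read_scheme(scheme))
  }
  if (is.numeric(scheme) && length(scheme) == 1L) return(scheme_hk(scheme))
  stop("cannot interpret `scheme`: supply an iaq_scheme, 1, 2, or a file path",
       call. = FALSE)
}
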