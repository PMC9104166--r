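#' Fractional dose of a pollutant
#'
#' The measured 8-h exposure level divided by the reference exposure limit,
#' the dimensionless building block of the IAQ index: 1 means the pollutant
#' sits exactly at its limit.
#'
#' @param level Measured concentration(s), same units as the limit; finite,
#'   non-negative.
#' @param limit Reference exposure limit; must be positive.
#' @return Numeric vector `level / limit`.
#' @examples
#' fractional_dose(90, 180)   # 0.5
#' @export
fractional_dose <- function(level, limit) {
  if (any(!is.finite(limit)) || any(limit <= 0)) {
    stop("invalid scheme: exposure limit must be finite and > 0",
         call. = FALSE)
  }
  if (any(!is.finite(level)) || any(level < 0)) {
    stop("exposure level must be finite and >= 0", call. = FALSE)
  }
  level / limit
}

#' Surrogate IAQ index
#'
#' The arithmetic mean of the fractional doses of the three surrogate
#' pollutants (CO2, RSP, TVOC) against a reference scheme's limits:
#' theta = (CO2/limit + RSP/limit + TVOC/limit) / 3. By convention the
#' reference limits are always Scheme 1 (CO2 1000 ppm, RSP 180 ug/m3,
#' TVOC 600 ug/m3), whichever scheme is used for labelling, so that index
#' values remain comparable across schemes; pass `reference` to override.
#'
#' Because the index is linear in the levels, the index of a mean triple
#' equals the mean of the per-office indices.
#'
#' @param data Data frame with numeric columns `co2`, `rsp` and `tvoc`
#'   (extra columns are kept).
#' @param reference Scheme supplying the three surrogate limits; defaults to
#'   [scheme_hk()] Scheme 1.
#' @param keep_doses Keep the per-surrogate fractional-dose columns
#'   (`dose_co2`, `dose_rsp`, `dose_tvoc`)?
#' @return The input as a tibble with a `theta` column appended (and dose
#'   columns if requested).
#' @examples
#' library(tibble)
#' iaq_index(tibble(co2 = 658, rsp = 30, tvoc = 358))$theta  # ~0.474
#' @export
iaq_index <- function(data, reference = scheme_hk(1), keep_doses = FALSE) {
  reference <- resolve_scheme(reference)
  need <- setdiff(iaq_surrogates, names(data))
  if (length(need) > 0L) {
    stop("`data` lacks surrogate column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lim <- reference$limits[iaq_surrogates]
  if (anyNA(lim)) {
    stop("invalid scheme: reference lacks a surrogate limit", call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  doses <- purrr::map2(iaq_surrogates, lim,
                       function(p, l) fractional_dose(out[[p]], l))
  names(doses) <- paste0("dose_", iaq_surrogates)
  out$theta <- (doses[[1]] + doses[[2]] + doses[[3]]) / 3
  if (keep_doses) {
    for (nm in names(doses)) out[[nm]] <- doses[[nm]]
  }
  out
}

#' Assess offices against an exposure-limit scheme
#'
#' Labels each record satisfactory when all nine pollutant levels are at or
#' below the scheme's limits, unsatisfactory when one or more exceed. A level
#' exactly at the limit passes. Missing values are an error: screening never
#' imputes a pollutant silently.
#'
#' @param data Data frame with the nine [iaq_pollutants] columns.
#' @param scheme An `iaq_scheme`, or 1/2 for the built-in Hong Kong schemes.
#' @param column Name of the label column to append.
#' @return The input as a tibble with a factor column (levels
#'   `satisfactory`, `unsatisfactory`) appended.
#' @examples
#' offices <- generate_offices(n_offices = 5, seed = 1)
#' assess_iaq(offices, scheme_hk(2))
#' @export
assess_iaq <- function(data, scheme = scheme_hk(1), column = "label") {
  scheme <- resolve_scheme(scheme)
  need <- setdiff(iaq_pollutants, names(data))
  if (length(need) > 0L) {
    stop("incomplete record: missing pollutant column(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(as.data.frame(data)[iaq_pollutants])
  if (anyNA(mat) || any(!is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1, ]
    stop("incomplete record: row ", bad[["row"]], ", pollutant ",
         iaq_pollutants[bad[["col"]]], " is missing or non-finite",
         call. = FALSE)
  }
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1, ]
    stop("negative level: row ", bad[["row"]], ", pollutant ",
         iaq_pollutants[bad[["col"]]], call. = FALSE)
  }
  ok <- mat <= rep(scheme$limits[iaq_pollutants], each = nrow(mat))
  out <- tibble::as_tibble(data)
  out[[column]] <- factor(ifelse(rowSums(ok) == length(iaq_pollutants),
                                 "satisfactory", "unsatisfactory"),
                          levels = c("satisfactory", "unsatisfactory"))
  out
}
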