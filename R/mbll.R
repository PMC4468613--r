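#' Default extinction coefficients for HbO and HbR
#'
#' Absorption per unit concentration per unit pathlength at the two working
#' wavelengths of a continuous-wave instrument (760 and 830 nm). The printed
#' literature values carry no explicit units; all downstream quantities are
#' therefore relative concentration changes in arbitrary units, which is all
#' the model fit requires.
#'
#' @return Tibble with columns `wavelength`, `eps_hbo`, `eps_hbr`.
#' @export
extinction_defaults <- function() {
  tibble::tibble(
    wavelength = c(760, 830),
    eps_hbo = c(1.486, 2.231),
    eps_hbr = c(3.843, 1.791)
  )
}

ext_lookup <- function(extinction, wavelengths) {
  i <- match(wavelengths, extinction$wavelength)
  if (anyNA(i)) abort("extinction table does not cover both wavelengths")
  e <- list(
    hbo1 = extinction$eps_hbo[i[1]], hbr1 = extinction$eps_hbr[i[1]],
    hbo2 = extinction$eps_hbo[i[2]], hbr2 = extinction$eps_hbr[i[2]]
  )
  if (any(unlist(e) <= 0)) abort("extinction coefficients must be positive")
  e
}

#' Convert dual-wavelength optical-density changes to hemoglobin changes
#'
#' Solves the modified Beer-Lambert law per channel and sample. With
#' pathlength-normalized optical densities
#' `od_j = deltaOD(lambda_j) / DPF(lambda_j)` the two-wavelength system gives
#' \deqn{\Delta HbO = \frac{\varepsilon_{HbR}^{\lambda_1} od_2 -
#'   \varepsilon_{HbR}^{\lambda_2} od_1}{l\,(\varepsilon_{HbR}^{\lambda_1}
#'   \varepsilon_{HbO}^{\lambda_2} - \varepsilon_{HbR}^{\lambda_2}
#'   \varepsilon_{HbO}^{\lambda_1})}}
#' and symmetrically for `deltaHbR` (numerators swapped with the HbO
#' coefficients, shared determinant denominator). Outputs are relative
#' concentration changes in arbitrary units.
#'
#' @param data Data frame of optical-density changes, one column per
#'   channel-wavelength pair named `<channel>_<wavelength>` (e.g.
#'   `CH01_760`, `CH01_830`); an optional `time` column is carried through.
#' @param wavelengths The two wavelengths in nm, in the order
#'   `(lambda1, lambda2)`.
#' @param dpf Differential pathlength factors, one per wavelength (same
#'   order); dimensionless. Defaults 7.25 at 760 nm and 6.38 at 830 nm.
#' @param separation Source-detector separation in cm; a scalar, or a named
#'   vector with one entry per channel.
#' @param extinction Extinction coefficient table, as
#'   [extinction_defaults()].
#'
#' @return Tibble with columns `<channel>_HbO` and `<channel>_HbR` (plus
#'   `time` if present in the input), same number of rows as `data`.
#' @examples
#' od <- tibble::tibble(CH01_760 = c(0, 0.01), CH01_830 = c(0, 0.02))
#' od_to_hb(od)
#' @export
od_to_hb <- function(data, wavelengths = c(760, 830),
                     dpf = c(7.25, 6.38), separation = 3,
                     extinction = extinction_defaults()) {
  stopifnot(length(wavelengths) == 2, length(dpf) == 2)
  if (any(dpf <= 0)) abort("DPF values must be positive")
  e <- ext_lookup(extinction, wavelengths)
  det <- e$hbr1 * e$hbo2 - e$hbr2 * e$hbo1
  if (abs(det) < 1e-12) {
    abort("degenerate wavelength pair: extinction determinant is zero")
  }

  time_col <- if ("time" %in% names(data)) data["time"] else NULL
  od_cols <- setdiff(names(data), "time")
  m <- regmatches(od_cols, regexec("^(.*)_([0-9]+)$", od_cols))
  if (any(lengths(m) != 3)) {
    abort("optical-density columns must be named <channel>_<wavelength>")
  }
  chan <- vapply(m, `[`, "", 2)
  wl <- as.numeric(vapply(m, `[`, "", 3))
  channels <- unique(chan)

  sep_for <- function(ch) {
    if (length(separation) == 1 && is.null(names(separation))) {
      return(as.numeric(separation))
    }
    s <- separation[[ch]]
    if (is.null(s) || is.na(s)) abort(paste0("no separation given for channel ", ch))
    s
  }

  out <- purrr::map(channels, function(ch) {
    i1 <- which(chan == ch & wl == wavelengths[1])
    i2 <- which(chan == ch & wl == wavelengths[2])
    if (length(i1) != 1 || length(i2) != 1) {
      abort(paste0("channel ", ch, " must appear at exactly the two wavelengths"))
    }
    od1 <- as.numeric(data[[od_cols[i1]]]) / dpf[1]
    od2 <- as.numeric(data[[od_cols[i2]]]) / dpf[2]
    if (length(od1) != length(od2)) abort("mismatched series lengths")
    l <- sep_for(ch)
    if (l <= 0) abort("separation must be positive")
    den <- l * det
    tibble::tibble(
      "{ch}_HbO" := (e$hbr1 * od2 - e$hbr2 * od1) / den,
      "{ch}_HbR" := (e$hbo2 * od1 - e$hbo1 * od2) / den
    )
  })
  res <- dplyr::bind_cols(out)
  if (!is.null(time_col)) res <- dplyr::bind_cols(tibble::as_tibble(time_col), res)
  res
}

#' Forward Beer-Lambert map from hemoglobin changes to optical densities
#'
#' The inverse of [od_to_hb()]: predicts the pathlength-scaled
#' optical-density change at each wavelength from concentration changes,
#' `deltaOD(lambda_j) = l * DPF(lambda_j) * (eps_HbO deltaHbO + eps_HbR
#' deltaHbR)`. Used mainly to validate the round-trip and to build synthetic
#' optical-density inputs.
#'
#' @param data Data frame with columns `<channel>_HbO`, `<channel>_HbR`
#'   (optional `time` carried through).
#' @inheritParams od_to_hb
#' @return Tibble of `<channel>_<wavelength>` optical-density columns.
#' @export
hb_to_od <- function(data, wavelengths = c(760, 830),
                     dpf = c(7.25, 6.38), separation = 3,
                     extinction = extinction_defaults()) {
  e <- ext_lookup(extinction, wavelengths)
  time_col <- if ("time" %in% names(data)) data["time"] else NULL
  hbo_cols <- grep("_HbO$", names(data), value = TRUE)
  channels <- sub("_HbO$", "", hbo_cols)
  out <- purrr::map(channels, function(ch) {
    hbo <- data[[paste0(ch, "_HbO")]]
    hbr <- data[[paste0(ch, "_HbR")]]
    if (is.null(hbr)) abort(paste0("missing HbR column for channel ", ch))
    l <- if (length(separation) == 1 && is.null(names(separation))) {
      separation
    } else {
      separation[[ch]]
    }
    tibble::tibble(
      "{ch}_{wavelengths[1]}" := l * dpf[1] * (e$hbo1 * hbo + e$hbr1 * hbr),
      "{ch}_{wavelengths[2]}" := l * dpf[2] * (e$hbo2 * hbo + e$hbr2 * hbr)
    )
  })
  res <- dplyr::bind_cols(out)
  if (!is.null(time_col)) res <- dplyr::bind_cols(tibble::as_tibble(time_col), res)
  res
}
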