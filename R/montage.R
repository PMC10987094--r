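# Electrode montage on the unit sphere, plus the candidate pools used for
# data-driven electrode selection.

# Approximate 10-20 / 10-10 positions as (theta, phi) in degrees following
# the spherical convention used by scalp-spline software: theta is the
# angle from the vertex (Cz = 0), phi the azimuth measured counterclockwise
# from the right ear (positive toward the nasion on the right hemisphere).
MONTAGE_32 <- data.frame(
  label = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
            "FC5", "FC1", "FC2", "FC6",
            "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
            "CP5", "CP1", "CP2", "CP6",
            "P7", "P3", "Pz", "P4", "P8",
            "PO7", "PO3", "POz", "PO4", "PO8",
            "O1", "Oz", "O2"),
  theta = c(92, 92, 92, 60, 46, 60, 92,
            72, 32, 32, 72,
            69, 46, 23, 0, 23, 46, 69,
            72, 32, 32, 72,
            92, 60, 46, 60, 92,
            92, 69, 69, 69, 92,
            92, 92, 92),
  phi = c(108, 72, 144, 129, 90, 51, 36,
          158, 148, 32, 22,
          180, 180, 180, 0, 0, 0, 0,
          -158, -148, -32, -22,
          -144, -129, -90, -51, -36,
          -126, -112, -90, -68, -54,
          -108, -90, -72),
  stringsAsFactors = FALSE
)

#' Default electrode montage
#'
#' A 35-channel scalp montage (a 10-10 subset with dense occipito-parietal
#' and central coverage) plus the two VEOG channels above and below the
#' left eye. Scalp positions lie on the unit sphere; VEOG channels carry no
#' scalp position and are excluded from re-referencing, spline
#' interpolation, CSD, and scalp artifact thresholds.
#'
#' @param n_scalp Number of scalp channels (truncates the default list;
#'   kept configurable so the selection and CSD logic can be exercised on
#'   smaller montages).
#' @return A data frame with class `montage`: `label`, `x`, `y`, `z`
#'   (unit-sphere coordinates, `NA` for VEOG), `is_scalp`.
#' @export
default_montage <- function(n_scalp = nrow(MONTAGE_32)) {
  m <- MONTAGE_32[seq_len(n_scalp), , drop = FALSE]
  th <- m$theta * pi / 180
  ph <- m$phi * pi / 180
  scalp <- data.frame(label = m$label,
                      x = sin(th) * cos(ph),
                      y = sin(th) * sin(ph),
                      z = cos(th),
                      is_scalp = TRUE,
                      stringsAsFactors = FALSE)
  veog <- data.frame(label = c("VEOGupper", "VEOGlower"),
                     x = NA_real_, y = NA_real_, z = NA_real_,
                     is_scalp = FALSE, stringsAsFactors = FALSE)
  out <- rbind(scalp, veog)
  rownames(out) <- NULL
  class(out) <- c("montage", "data.frame")
  out
}

#' Candidate electrode pools
#'
#' The occipital pool feeds SSVEP electrode selection; the left/right
#' central pools feed mu-beta electrode selection; three occipito-parietal
#' midline electrodes are fixed for the alpha analysis.
#'
#' @param montage A [default_montage()].
#' @return A list of character vectors: `occipital`, `central_left`,
#'   `central_right`, `alpha_midline`.
#' @export
electrode_pools <- function(montage = default_montage()) {
  have <- function(x) x[x %in% montage$label]
  list(
    occipital = have(c("PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2")),
    central_left = have(c("C5", "C3", "C1", "FC5", "FC1", "CP5", "CP1")),
    central_right = have(c("C6", "C4", "C2", "FC6", "FC2", "CP6", "CP2")),
    alpha_midline = have(c("Pz", "POz", "Oz"))
  )
}
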