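#' Define a fluorophore with Gaussian excitation/emission profiles
#'
#' Native cellular fluorophores (NAD(P)H, flavins, collagen, tryptophan, ...)
#' are modelled with separable Gaussian excitation and emission spectra. This
#' deliberately omits vibronic structure: the minimal model is sufficient to
#' produce channel-correlated, group-separable signals for testing the
#' downstream pipeline.
#'
#' @param name Fluorophore name (e.g. `"NADH-like"`).
#' @param excitation_center_nm,excitation_width_nm Gaussian excitation center
#'   and SD (nm).
#' @param emission_center_nm,emission_width_nm Gaussian emission center and SD
#'   (nm).
#' @param brightness Nonnegative scalar scaling the response.
#' @return An object of class `fluorophore`.
#' @export
fluorophore <- function(name, excitation_center_nm, excitation_width_nm,
                        emission_center_nm, emission_width_nm,
                        brightness = 1) {
  stopifnot(excitation_width_nm > 0, emission_width_nm > 0, brightness >= 0)
  structure(
    list(name = name,
         excitation_center_nm = excitation_center_nm,
         excitation_width_nm = excitation_width_nm,
         emission_center_nm = emission_center_nm,
         emission_width_nm = emission_width_nm,
         brightness = brightness),
    class = "fluorophore"
  )
}

#' Default two-fluorophore panel
#'
#' NADH-like and FAD-like species, the dominant metabolic autofluorophores.
#' Centers follow the textbook free-NADH (ex ~350 / em ~460 nm) and FAD
#' (ex ~450 / em ~530 nm) spectra.
#'
#' @return Named list of [fluorophore()] objects.
#' @export
default_fluorophores <- function() {
  list(
    "NADH-like" = fluorophore("NADH-like", 350, 25, 460, 35, brightness = 1),
    "FAD-like"  = fluorophore("FAD-like", 450, 25, 530, 30, brightness = 1)
  )
}

#' Expected response of a fluorophore in one spectral channel
#'
#' The response is separable: a Gaussian excitation efficiency evaluated at the
#' channel's excitation center, times the fraction of the Gaussian emission
#' profile falling inside the channel's emission window, times the
#' fluorophore's brightness. Deterministic and nonnegative; additive over a
#' partition of the emission axis.
#'
#' @param f A [fluorophore()].
#' @param channel One row of a `channel_table` (or any list with the channel
#'   fields).
#' @return Nonnegative scalar response per unit abundance.
#' @export
channel_response <- function(f, channel) {
  exc_eff <- exp(-(channel$excitation_center_nm - f$excitation_center_nm)^2 /
                   (2 * f$excitation_width_nm^2))
  em_mass <- stats::pnorm(channel$emission_high_nm, f$emission_center_nm,
                          f$emission_width_nm) -
    stats::pnorm(channel$emission_low_nm, f$emission_center_nm,
                 f$emission_width_nm)
  f$brightness * exc_eff * em_mass
}

#' Response of a fluorophore across all channels of a table
#'
#' @param f A [fluorophore()].
#' @param channels A `channel_table`.
#' @return Named numeric vector (one entry per channel, named by channel_id).
#' @export
channel_response_vector <- function(f, channels) {
  r <- vapply(seq_len(nrow(channels)),
              function(i) channel_response(f, channels[i, ]),
              numeric(1))
  names(r) <- channels$channel_id
  r
}

#' Mixed-spectrum of a fluorophore panel at given abundances
#'
#' @param fluors Named list of fluorophores.
#' @param abundances Named numeric vector (same names as `fluors`).
#' @param channels A `channel_table`.
#' @return Named numeric vector: sum over fluorophores of
#'   abundance x channel response.
#' @export
mixed_spectrum <- function(fluors, abundances, channels) {
  stopifnot(all(names(fluors) %in% names(abundances)))
  resp <- vapply(names(fluors),
                 function(nm) abundances[[nm]] * channel_response_vector(fluors[[nm]], channels),
                 numeric(nrow(channels)))
  if (is.null(dim(resp))) resp <- matrix(resp, nrow = nrow(channels))
  out <- rowSums(resp)
  names(out) <- channels$channel_id
  out
}
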