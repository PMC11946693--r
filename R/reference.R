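# Reference analysis configuration for the dilute aqueous 1,3-propanediol
# systems the direct method was developed on.

#' Reference MD system configuration for dilute aqueous 1,3-propanediol
#'
#' The analysis configuration for the six reference solution systems (1 mol
#' percent 1,3-propanediol in water at 298.15 K and 1 atm) that the direct
#' labeling method targets: box composition, number of target diol
#' molecules, the initial diol conformation each system was built from, the
#' post-equilibration trajectory length, and the resulting number of
#' molecule-frame configurations at the 1 ps recording stride. Given
#' equivalent trajectories (OPLS-AA diol in TIP4P-Ew water, NPT, coordinates
#' recorded every 1 ps), running [label_trajectory()] with this
#' configuration and the package's default binning reproduces the published
#' solution-composition and lifetime tables; the numbers themselves require
#' the nanosecond MD runs and are not computable from this package alone.
#'
#' @return data frame with columns \code{system}, \code{n_total}
#'   (molecules in the box), \code{n_diol} (target molecules),
#'   \code{initial_conformation}, \code{t_ns} (analyzed trajectory length),
#'   \code{stride_ps}, and \code{n_conf} (= \code{n_diol} x \code{t_ns} x
#'   1000 / \code{stride_ps}).
#' @export
md_reference_systems <- function() {
  data.frame(
    system = c("800_cryst", "800_H-b_1", "800_H-b_2", "800_tTTt",
               "2700_cryst", "6400_cryst"),
    n_total = c(800, 800, 800, 800, 2700, 6400),
    n_diol = c(8, 8, 8, 8, 27, 64),
    initial_conformation = c("gGGg′ (crystal)", "tGG′g", "gGG′g",
                             "tTTt", "gGGg′ (crystal)", "gGGg′ (crystal)"),
    t_ns = c(5, 5, 5, 15, 5, 2),
    stride_ps = 1,
    n_conf = c(40000, 40000, 40000, 120000, 135000, 128000),
    stringsAsFactors = FALSE
  )
}
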