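# Published deformation-monitoring measurements of the Palaeolithic wooden
# point from the Ljubljanica River, used as worked-example input for the
# change-table computations. Values are the digitally measured 3-D model
# dimensions (µm) and volumes (µm³) per scan year; the 2008 row is the
# manual in-situ estimate and carries no volume.

#' Published wooden-point measurements by scan year
#'
#' Length, width, thickness (µm) and volume (µm³) of the repeatedly scanned
#' Palaeolithic wooden point: the 2008 manual estimate and the six
#' digitally measured 3-D models (2009 before conservation, 2013–2019 after
#' the resin-irrigation phase). Feeding these to [change_table()] with base
#' 2009 or 2013 reproduces the published percent-change baselines.
#'
#' @param include_manual include the 2008 manual estimate (default FALSE:
#'   only the digitally measured models).
#' @return list of [morph_report()] objects, labelled by year.
#' @examples
#' reps <- palaeo_point_reports()
#' head(change_table(reps, base = "2009"))
#' @export
palaeo_point_reports <- function(include_manual = FALSE) {
  rows <- list(
    list("2008", 160000, 51000, 25000, NA_real_),
    list("2009", 155606, 50014, 25579, 70653.6),
    list("2013", 160958, 52274, 28810, 80404.1),
    list("2015", 152709, 50594, 23856, 66382.8),
    list("2017", 151768, 50348, 23585, 65238.9),
    list("2018", 150435, 48359, 22689, 63871.9),
    list("2019", 149171, 50705, 23793, 63289.4)
  )
  if (!include_manual) rows <- rows[-1]
  lapply(rows, function(r)
    morph_report(length = r[[2]], width = r[[3]], thickness = r[[4]],
                 volume = r[[5]], label = r[[1]]))
}
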