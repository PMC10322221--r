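## Zonal analysis: annular zones C1-C4 around the optic disc, measured in
## papillary-diameter (PD) units from the disc border, and per-zone
## aggregation of diameter and tortuosity samples.

#' Zone specification
#'
#' Default annuli: C1 = 0.5-1.0 PD, C2 = 1.0-1.5 PD, C3 = 1.5-2.0 PD,
#' C4 = 2.0-2.5 PD from the optic disc border. Intervals are half-open
#' `[inner, outer)`.
#'
#' @param names zone names.
#' @param inner,outer inner and outer distances in PD units.
#' @return data.frame with columns `name`, `inner`, `outer`.
#' @export
zone_spec <- function(names = c("C1", "C2", "C3", "C4"),
                      inner = c(0.5, 1.0, 1.5, 2.0),
                      outer = c(1.0, 1.5, 2.0, 2.5)) {
  stopifnot(length(names) == length(inner), length(inner) == length(outer),
            all(inner < outer), !is.unsorted(inner),
            all(outer[-length(outer)] <= inner[-1L]))
  data.frame(name = names, inner = inner, outer = outer)
}

#' Zone of a point
#'
#' The distance from the disc border in PD units is
#' `(||point - center|| - PD/2) / PD`; the point belongs to the zone whose
#' half-open interval `[inner, outer)` contains that distance.
#'
#' @param x,y point coordinates in pixels (vectorized).
#' @param disc calibrated `optic_disc`.
#' @param spec [zone_spec()].
#' @return character vector of zone names, `NA` for points outside all
#'   zones (including the disc interior and border, distance below the
#'   innermost zone).
#' @export
zone_of <- function(x, y, disc, spec = zone_spec()) {
  d <- .border_dist_pd(x, y, disc)
  out <- rep(NA_character_, length(d))
  for (i in seq_len(nrow(spec)))
    out[d >= spec$inner[i] & d < spec$outer[i]] <- spec$name[i]
  out
}

#' Aggregate metrics per annular zone
#'
#' Assigns each diameter cross-section and curvature sample to the zone of
#' its centerline measurement point and computes per-zone means: average
#' diameter (all / artery / vein), AVR from the per-zone artery and vein
#' means, and tortuosity. Empty zones report `NA` with zero counts.
#'
#' @param sections data.frame from [sample_diameters()].
#' @param curvatures data.frame from [sample_curvatures()].
#' @param disc calibrated `optic_disc`.
#' @param spec [zone_spec()].
#' @return data.frame, one row per zone: `zone`, `n_diameter`,
#'   `diameter_um`, `diameter_artery_um`, `diameter_vein_um`, `avr`,
#'   `n_curvature`, `tortuosity`.
#' @export
aggregate_zones <- function(sections, curvatures, disc, spec = zone_spec()) {
  zs <- if (nrow(sections)) zone_of(sections$x, sections$y, disc, spec)
  else character()
  zc <- if (!is.null(curvatures) && nrow(curvatures))
    zone_of(curvatures$x, curvatures$y, disc, spec) else character()
  one <- function(zname) {
    sec <- sections[!is.na(zs) & zs == zname, , drop = FALSE]
    cur <- curvatures[!is.na(zc) & zc == zname, , drop = FALSE]
    d_all <- average_diameter(sec, "all")
    d_art <- average_diameter(sec, "artery")
    d_ven <- average_diameter(sec, "vein")
    data.frame(zone = zname,
               n_diameter = nrow(sec),
               diameter_um = d_all,
               diameter_artery_um = d_art,
               diameter_vein_um = d_ven,
               avr = if (is.na(d_art) || is.na(d_ven) || d_ven <= 0)
                 NA_real_ else d_art / d_ven,
               n_curvature = nrow(cur),
               tortuosity = if (nrow(cur)) mean(cur$curvature) else NA_real_)
  }
  do.call(rbind, lapply(spec$name, one))
}
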