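# Planar polyline geometry. All coordinates are projected metres; there is
# deliberately no geodesy anywhere in the engine.

polyline_length <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) < 2L) return(0)
  sum(sqrt(rowSums(diff(mat)^2)))
}

# Nearest point on a polyline to p = c(x, y), segment-clamped.
# Returns list(point, dist, tangent) where tangent is the unit direction of
# the segment holding the nearest point.
nearest_on_polyline <- function(mat, p) {
  best <- list(point = NULL, dist = Inf, tangent = NULL)
  for (i in seq_len(nrow(mat) - 1L)) {
    a <- mat[i, ]; b <- mat[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- sum((p - a) * ab) / len2
    t <- min(1, max(0, t))
    q <- a + t * ab
    d <- sqrt(sum((p - q)^2))
    if (d < best$dist) best <- list(point = q, dist = d, tangent = ab / sqrt(len2))
  }
  if (!is.finite(best$dist)) stop("degenerate zero-length geometry")
  best
}

resolve_geometry <- function(link) {
  if (is.matrix(link)) return(link)
  if (is.list(link) && !is.null(link$geometry)) {
    g <- link$geometry
    if (is.list(g)) {
      if (length(g) != 1L) stop("expected a single link")
      g <- g[[1L]]
    }
    return(g)
  }
  stop("cannot interpret link geometry")
}

#' Perpendicular distance from a point to a road link
#'
#' Euclidean distance from a point to the nearest point on the link
#' polyline. Distances are clamped to the segments: points beyond a link's
#' end measure to the endpoint, not to the infinite line.
#'
#' @param link a one-row `road_links` subset or a coordinate matrix.
#' @param point numeric length-2 vector `c(x, y)` in the same projected CRS.
#' @return Distance in metres.
#' @export
#' @examples
#' seg <- rbind(c(0, 0), c(1000, 0))
#' perpendicular_distance(seg, c(500, 300))   # 300
#' perpendicular_distance(seg, c(1500, 300))  # to the endpoint: 583.095...
perpendicular_distance <- function(link, point) {
  mat <- resolve_geometry(link)
  if (polyline_length(mat) <= 0) stop("degenerate zero-length geometry")
  nearest_on_polyline(mat, as.numeric(point))$dist
}

# Unit vector of a compass bearing (degrees clockwise from north),
# in (x = east, y = north) map coordinates.
compass_unit <- function(deg) {
  r <- deg * pi / 180
  c(sin(r), cos(r))
}

# Downwind transport unit vector for a from-direction wdir.
transport_unit <- function(wdir_from) compass_unit(wdir_from + 180)

#' Effective source-receptor distance along the hourly transport direction
#'
#' The perpendicular road distance divided by the cosine of the angle
#' between the downwind transport direction and the road normal pointing
#' toward the receptor: the distance pollutant actually travels from the
#' road to the receptor that hour. When the receptor is effectively upwind
#' (cosine at or below `cos_cap`) `NA` is returned; otherwise the result is
#' bounded by `d_perp / cos_cap`.
#'
#' @param link a one-row `road_links` subset or coordinate matrix.
#' @param receptor numeric `c(x, y)`, or a one-row `receptors` subset.
#' @param wind_from_deg wind from-direction, degrees clockwise from north
#'   in `[0, 360)`; transport is toward `wind_from_deg + 180`.
#' @param cos_cap upwind cutoff cosine (default 0.1, i.e. effective
#'   distances are capped at 10 times the perpendicular distance).
#' @return Effective distance in metres, or `NA_real_` when upwind.
#' @export
#' @examples
#' seg <- rbind(c(0, 0), c(1000, 0))
#' effective_distance(seg, c(500, -100), wind_from_deg = 0)   # 100
#' effective_distance(seg, c(500, -100), wind_from_deg = 180) # upwind: NA
effective_distance <- function(link, receptor, wind_from_deg,
                               cos_cap = dispersion_constants()$cos_cap) {
  stopifnot(wind_from_deg >= 0, wind_from_deg < 360)
  mat <- resolve_geometry(link)
  if (inherits(receptor, "data.frame")) receptor <- c(receptor$x[1], receptor$y[1])
  p <- as.numeric(receptor)
  near <- nearest_on_polyline(mat, p)
  if (near$dist == 0) return(0)
  n_hat <- (p - near$point) / near$dist
  cos_theta <- sum(transport_unit(wind_from_deg) * n_hat)
  if (cos_theta <= cos_cap) return(NA_real_)
  near$dist / cos_theta
}
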