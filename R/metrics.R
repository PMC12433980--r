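# Activation-map construction and map-comparison statistics.

#' Build an activation map from a simulation trace
#'
#' First ascending -10 mV crossing per node within the beat window, in ms
#' relative to the window start. Nodes with no ascending crossing in the
#' window are flagged unactivated (`NA`); a map with zero activated nodes is
#' returned as a distinguished empty map (all `NA`), not an error.
#'
#' @param trace A [SimulationTrace-class].
#' @param window `c(t0, t1)` (ms, absolute; half-open `[t0, t1)`).
#' @param medium `"tissue"` or `"network"`.
#' @param nNodes Number of nodes of the medium; inferred from the trace's
#'   model when omitted.
#' @return An [ActivationMap-class].
#' @export
activationMap <- function(trace, window, medium = c("tissue", "network"),
                          nNodes = NULL) {
  medium <- match.arg(medium)
  ids <- NULL
  if (is.null(nNodes)) {
    fm <- trace@finalModel
    nNodes <- if (medium == "tissue") length(fm@state$vT) else length(fm@state$vN)
    if (medium == "network" && length(fm@netIndex) == nNodes)
      ids <- as.integer(fm@netIndex)
  }
  if (is.null(ids)) ids <- seq_len(nNodes)
  ev <- trace@events
  ev <- ev[ev$medium == medium & ev$dir == 1L &
             ev$time >= window[1] & ev$time < window[2], , drop = FALSE]
  at <- rep(NA_real_, nNodes)
  if (nrow(ev)) {
    ev <- ev[order(ev$time), ]
    first <- !duplicated(ev$node)
    at[ev$node[first]] <- ev$time[first] - window[1]
  }
  new("ActivationMap", medium = medium, at = at, ids = ids, t0 = window[1])
}

#' Total activation time of a map
#'
#' The range (latest minus earliest activation) over activated nodes.
#'
#' @param map An [ActivationMap-class].
#' @return Total AT in ms (`NA` for an empty map).
#' @export
totalAT <- function(map) {
  a <- map@at[!is.na(map@at)]
  if (!length(a)) return(NA_real_)
  max(a) - min(a)
}

#' @describeIn compareMaps Map-comparison statistics.
setMethod("compareMaps", signature("ActivationMap", "ActivationMap"),
          function(a, b) {
  if (a@medium != b@medium) stop("maps compare only within one medium")
  common <- intersect(a@ids, b@ids)
  if (!length(common)) stop("maps cover disjoint node sets")
  ia <- match(common, a@ids); ib <- match(common, b@ids)
  shared <- which(!is.na(a@at[ia]) & !is.na(b@at[ib]))
  if (!length(shared)) stop("maps share no activated nodes")
  da <- a@at[ia][shared]; db <- b@at[ib][shared]
  d <- db - da
  ccv <- if (sd(da) == 0 || sd(db) == 0) {
    if (all(d == d[1])) 1 else NA_real_
  } else cor(da, db)
  tA <- totalAT(a); tB <- totalAT(b)
  new("MapComparison",
      rd = 100 * sum(abs(d)) / sum(abs(da)),
      rmsdMean = mean(abs(d)), rmsdSd = if (length(d) > 1) sd(abs(d)) else 0,
      cc = ccv,
      pctAbsDeltaTotalAT = 100 * abs(tB - tA) / tA,
      absDiff = abs(d), nShared = length(shared),
      nOnlyA = sum(!is.na(a@at[ia]) & is.na(b@at[ib])),
      nOnlyB = sum(is.na(a@at[ia]) & !is.na(b@at[ib])))
})

#' @describeIn absDifferenceMap Per-node absolute difference field.
setMethod("absDifferenceMap", signature("ActivationMap", "ActivationMap"),
          function(a, b) {
  if (a@medium != b@medium) stop("maps compare only within one medium")
  common <- intersect(a@ids, b@ids)
  if (!length(common)) stop("maps cover disjoint node sets")
  setNames(abs(b@at[match(common, b@ids)] - a@at[match(common, a@ids)]),
           common)
})

#' Write an activation map as CSV
#'
#' Columns `node_id, x, y, z, at_ms, activated`.
#'
#' @param map An [ActivationMap-class] over a tissue domain.
#' @param domain The [TissueDomain-class] providing coordinates.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeActivationMapCSV <- function(map, domain, file) {
  co <- tissueCoords(domain)
  write.csv(data.frame(node_id = co$node, x = co$x, y = co$y, z = 0,
                       at_ms = map@at, activated = !is.na(map@at)),
            file, row.names = FALSE)
  invisible(file)
}

#' Export a per-node scalar field as legacy VTK structured points
#'
#' @param domain A [TissueDomain-class].
#' @param values Numeric vector (length nx*ny); `NA` written as -1.
#' @param file Output path.
#' @param name Field name in the VTK file.
#' @return `file`, invisibly.
#' @export
writeFieldVTK <- function(domain, values, file, name = "field") {
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 2.0", "purkinet field", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", domain@nx, domain@ny),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g 1", domain@spacing, domain@spacing),
               sprintf("POINT_DATA %d", domain@nx * domain@ny),
               sprintf("SCALARS %s float 1", name),
               "LOOKUP_TABLE default"), con)
  v <- values; v[is.na(v)] <- -1
  writeLines(sprintf("%.6g", v), con)
  invisible(file)
}
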