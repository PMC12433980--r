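# Rule-based Purkinje network generation, the reconnection-pruning
# algorithm, PMJ placement, and network I/O.
#
# Networks are grown by recursive branching from a His root over the sheet,
# followed by a cross-bridging pass that links nearby internal nodes of
# distinct distal branches (the "reunification" cables whose removal is the
# manipulated variable of the whole package).

.normalize <- function(d) d / sqrt(sum(d^2))

.rot <- function(d, a) c(cos(a) * d[1] - sin(a) * d[2],
                         sin(a) * d[1] + cos(a) * d[2])

.domainSize <- function(domain) {
  c(w = (domain@nx - 1L) * domain@spacing,
    h = (domain@ny - 1L) * domain@spacing)
}

#' Convert a Purkinje network to an igraph object
#'
#' Directed graph with vertex names equal to node ids; used for all
#' traversal bookkeeping (reachability, cycle counting, path enumeration).
#'
#' @param net A [PurkinjeNetwork-class].
#' @return An igraph graph.
#' @export
asIgraph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = as.character(net@edges$from),
               to = as.character(net@edges$to)),
    directed = TRUE,
    vertices = data.frame(name = as.character(net@nodes$id),
                          role = net@nodes$role))
}

.rootId <- function(net) net@nodes$id[net@nodes$role == "his_root"]

.reachableIds <- function(net) {
  g <- asIgraph(net)
  r <- igraph::subcomponent(g, as.character(.rootId(net)), mode = "out")
  as.integer(names(r))
}

#' Generate a rule-based Purkinje network
#'
#' Grows a His bundle, two proximal fascicles, and recursively bifurcating
#' distal branches over the tissue sheet, then (for `reconnectionRate > 0`)
#' adds cross-bridge cables between nearby internal nodes of distinct,
#' non-ancestral branches. Bridge targets become reunification nodes (two
#' parent cables converging onto one child); bridges never carry PMJ
#' terminals. The result is deterministic in `(seed, parameters)`.
#'
#' @param domain A [TissueDomain-class] defining the growth region.
#' @param fascicleSpec Named list of branching parameters; unset entries take
#'   the defaults: `nGenerations` (5), `segmentLength` (0.8 mm),
#'   `hisLength` (6 mm), `fascicleLength` (10 mm), `branchLength` (9 mm),
#'   `lengthDecay` (0.8), `branchAngle` (0.55 rad), `fascicleAngle`
#'   (0.9 rad), `jitterSd` (0.1 rad per segment), `bridgeMaxDist` (6 mm),
#'   `bridgeMinDist` (1.5 mm), `bridgeCvScale` (1), `bridgeDepthTol`
#'   (5 mm; bridges join nodes of similar conduction depth from the root,
#'   which keeps anterograde activation nearly unchanged while opening
#'   retrograde shortcuts).
#' @param reconnectionRate Fraction in [0, 1]; the number of attempted
#'   cross-bridges is `round(rate * number of distal cables)`.
#' @param seed Integer RNG seed.
#' @return A [PurkinjeNetwork-class]; `topologyMode` is `"mesh"` when at
#'   least one bridge was added and `"tree"` otherwise.
#' @export
generateNetwork <- function(domain, fascicleSpec = list(),
                            reconnectionRate = 0.3, seed = 1L) {
  stopifnot(reconnectionRate >= 0, reconnectionRate <= 1)
  fs <- utils::modifyList(list(
    nGenerations = 8L, segmentLength = 0.8, hisLength = 6,
    fascicleLength = 10, branchLength = 9, lengthDecay = 0.8,
    branchAngle = 0.55, fascicleAngle = 0.9, jitterSd = 0.1,
    bridgeMaxDist = 6, bridgeMinDist = 1.5, bridgeCvScale = 1,
    bridgeDepthTol = 5), fascicleSpec)
  sz <- .domainSize(domain)
  if (min(sz) < fs$hisLength + fs$fascicleLength)
    stop(sprintf(
      "growth region too small (%.3g x %.3g mm) to host the requested branch generations",
      sz["w"], sz["h"]))

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(seed)

  env <- new.env()
  env$x <- numeric(); env$y <- numeric(); env$role <- character()
  env$eFrom <- integer(); env$eTo <- integer(); env$eCable <- integer()
  env$cId <- integer(); env$cProx <- logical(); env$cKind <- character()
  env$cGen <- integer()
  margin <- 0.5

  addNode <- function(x, y, role) {
    env$x <- c(env$x, x); env$y <- c(env$y, y); env$role <- c(env$role, role)
    length(env$x)
  }
  addCable <- function(proximal, kind, gen) {
    id <- length(env$cId) + 1L
    env$cId <- c(env$cId, id); env$cProx <- c(env$cProx, proximal)
    env$cKind <- c(env$cKind, kind); env$cGen <- c(env$cGen, gen)
    id
  }
  # grow one cable from a start node along dir; returns end node id
  grow <- function(start, dir, len, gen, proximal) {
    cab <- addCable(proximal, "branch", gen)
    nSeg <- max(2L, ceiling(len / fs$segmentLength))
    segLen <- len / nSeg
    pos <- c(env$x[start], env$y[start])
    cur <- start
    for (i in seq_len(nSeg)) {
      dir <- .normalize(.rot(dir, rnorm(1, 0, fs$jitterSd)))
      nxt <- pos + dir * segLen
      if (nxt[1] < margin || nxt[1] > sz["w"] - margin) dir[1] <- -dir[1]
      if (nxt[2] < margin || nxt[2] > sz["h"] - margin) dir[2] <- -dir[2]
      nxt <- pos + dir * segLen
      nd <- addNode(nxt[1], nxt[2], "internal")
      env$eFrom <- c(env$eFrom, cur); env$eTo <- c(env$eTo, nd)
      env$eCable <- c(env$eCable, cab)
      cur <- nd; pos <- nxt
    }
    list(end = cur, dir = dir)
  }

  # His bundle: from the basal edge straight toward the apex
  root <- addNode(sz["w"] / 2, sz["h"] - margin, "his_root")
  his <- grow(root, c(0, -1), fs$hisLength, 0L, TRUE)
  env$role[his$end] <- "branch_point"
  # two proximal fascicles
  queue <- list()
  for (s in c(-1, 1)) {
    f <- grow(his$end, .normalize(.rot(c(0, -1), s * fs$fascicleAngle)),
              fs$fascicleLength, 1L, TRUE)
    env$role[f$end] <- "branch_point"
    queue[[length(queue) + 1L]] <- list(node = f$end, dir = f$dir, gen = 2L)
  }
  # distal generations
  while (length(queue)) {
    item <- queue[[1]]; queue <- queue[-1]
    len <- fs$branchLength * fs$lengthDecay^(item$gen - 2L)
    for (s in c(-1, 1)) {
      b <- grow(item$node, .normalize(.rot(item$dir, s * fs$branchAngle)),
                len, item$gen, FALSE)
      if (item$gen < fs$nGenerations) {
        env$role[b$end] <- "branch_point"
        queue[[length(queue) + 1L]] <-
          list(node = b$end, dir = b$dir, gen = item$gen + 1L)
      } else {
        env$role[b$end] <- "pmj_terminal"
      }
    }
  }

  nodes <- data.frame(id = seq_along(env$x), x = env$x, y = env$y, z = 0,
                      role = env$role, stringsAsFactors = FALSE)
  edges <- data.frame(from = env$eFrom, to = env$eTo, cable = env$eCable)
  cables <- data.frame(id = env$cId, proximal = env$cProx, cvScale = 1,
                       kind = env$cKind, gen = env$cGen,
                       stringsAsFactors = FALSE)

  # ---- cross-bridging (reunification) pass ----
  nBridges <- 0L
  if (reconnectionRate > 0) {
    distalCables <- cables$id[!cables$proximal & cables$kind == "branch"]
    want <- max(1L, round(reconnectionRate * length(distalCables)))
    cand <- nodes$id[nodes$role == "internal" &
                       edges$cable[match(nodes$id, edges$to)] %in% distalCables]
    if (length(cand) > 600L) cand <- sort(sample(cand, 600L))
    mkGraph <- function() igraph::graph_from_data_frame(
      data.frame(from = as.character(edges$from), to = as.character(edges$to)),
      directed = TRUE, vertices = data.frame(name = as.character(nodes$id)))
    g <- mkGraph()
    # candidate pairs within the distance band, on different cables, at
    # similar conduction depth from the root (reconnections join distal
    # fibers whose anterograde arrival times are already close)
    cd <- as.matrix(stats::dist(cbind(nodes$x[cand], nodes$y[cand])))
    depth <- as.numeric(igraph::distances(g, as.character(root),
                                          as.character(cand),
                                          mode = "out")) * fs$segmentLength
    dd <- abs(outer(depth, depth, "-"))
    pairs <- which(upper.tri(cd) & cd >= fs$bridgeMinDist &
                     cd <= fs$bridgeMaxDist & dd <= fs$bridgeDepthTol,
                   arr.ind = TRUE)
    if (nrow(pairs)) {
      ord <- sample.int(nrow(pairs))
      cableOf <- edges$cable[match(cand, edges$to)]
      used <- integer()
      for (k in ord) {
        if (nBridges >= want) break
        a <- cand[pairs[k, 1]]; b <- cand[pairs[k, 2]]
        if (cableOf[pairs[k, 1]] == cableOf[pairs[k, 2]]) next
        if (a %in% used || b %in% used) next
        dAB <- igraph::distances(g, as.character(a), as.character(b), mode = "out")
        dBA <- igraph::distances(g, as.character(b), as.character(a), mode = "out")
        if (is.finite(dAB) || is.finite(dBA)) next  # ancestor-related: skip
        # straight polyline a -> b; b becomes a reunification node
        cab <- addCable(FALSE, "bridge", NA_integer_)
        cables <- rbind(cables, data.frame(id = cab, proximal = FALSE,
                                           cvScale = fs$bridgeCvScale,
                                           kind = "bridge",
                                           gen = NA_integer_))
        ia <- match(a, nodes$id); ib <- match(b, nodes$id)
        pA <- c(nodes$x[ia], nodes$y[ia]); pB <- c(nodes$x[ib], nodes$y[ib])
        nSeg <- max(1L, round(sqrt(sum((pB - pA)^2)) / fs$segmentLength))
        prev <- a
        newEdges <- NULL
        for (i in seq_len(nSeg)) {
          if (i < nSeg) {
            p <- pA + (pB - pA) * i / nSeg
            nd <- max(nodes$id) + 1L
            nodes <- rbind(nodes, data.frame(id = nd, x = p[1], y = p[2],
                                             z = 0, role = "internal"))
          } else nd <- b
          newEdges <- rbind(newEdges, data.frame(from = prev, to = nd, cable = cab))
          prev <- nd
        }
        edges <- rbind(edges, newEdges)
        nodes$role[ia] <- "branch_point"
        nodes$role[ib] <- "reunification"
        used <- c(used, a, b)
        nBridges <- nBridges + 1L
        g <- mkGraph()
      }
    }
  }

  # segment lengths from coordinates
  edges$length <- sqrt((nodes$x[edges$to] - nodes$x[edges$from])^2 +
                         (nodes$y[edges$to] - nodes$y[edges$from])^2)
  net <- new("PurkinjeNetwork", nodes = nodes, edges = edges,
             cables = cables[, c("id", "proximal", "cvScale", "kind", "gen")],
             topologyMode = if (nBridges > 0L) "mesh" else "tree")
  validObject(net)
  net
}

#' @describeIn pruneReconnections Prune a network's reunification cables.
setMethod("pruneReconnections", "PurkinjeNetwork", function(net) {
  if (net@topologyMode == "tree") return(net)
  nodes <- net@nodes; edges <- net@edges
  rootId <- .rootId(net)
  pmjIds <- nodes$id[nodes$role == "pmj_terminal"]
  proximalCables <- net@cables$id[net@cables$proximal]

  repeat {
    indeg <- table(edges$to)
    reun <- as.integer(names(indeg)[indeg > 1L])
    if (!length(reun)) break
    r <- min(reun)
    inc <- which(edges$to == r)
    keep <- inc[order(edges$cable[inc], edges$from[inc])][1]
    drop <- setdiff(inc, keep)
    # guard: never remove a proximal (fascicle) cable edge
    drop <- drop[!(edges$cable[drop] %in% proximalCables)]
    if (!length(drop))
      stop(sprintf("reunification node %d cannot be resolved without removing a fascicle cable", r))
    # remove one excess parent per pass (multi-parent nodes resolve over
    # successive passes): walk the removed parent cable backward from r
    # through its degree-2 interior nodes, stopping where the cable
    # originated (the first node whose remaining attachments belong to
    # other cables, i.e. a bifurcation, or the root); the walk never
    # leaves the removed cable
    e <- drop[order(-edges$cable[drop], -edges$from[drop])][1]
    cid <- edges$cable[e]
    cur <- edges$from[e]
    toDrop <- e
    repeat {
      rem <- setdiff(which(edges$from == cur | edges$to == cur), toDrop)
      role <- nodes$role[match(cur, nodes$id)]
      if (length(rem) != 1L || edges$cable[rem] != cid ||
          role %in% c("his_root", "pmj_terminal")) break
      cur <- setdiff(c(edges$from[rem], edges$to[rem]), cur)
      toDrop <- c(toDrop, rem)
    }
    edges <- edges[-toDrop, , drop = FALSE]
  }
  # delete nodes left without any attachment (interiors of removed cables)
  attached <- nodes$id %in% c(edges$from, edges$to) | nodes$role == "his_root"
  nodes <- nodes[attached, , drop = FALSE]

  # recompute roles for former reunification/bifurcation nodes
  indeg <- table(edges$to); outdeg <- table(edges$from)
  for (i in seq_len(nrow(nodes))) {
    id <- nodes$id[i]
    if (nodes$role[i] %in% c("his_root", "pmj_terminal")) next
    tot <- sum(indeg[as.character(id)], outdeg[as.character(id)], na.rm = TRUE)
    nodes$role[i] <- if (tot >= 3L) "branch_point" else "internal"
  }

  cables <- net@cables[net@cables$id %in% unique(edges$cable), , drop = FALSE]
  out <- new("PurkinjeNetwork", nodes = nodes, edges = edges, cables = cables,
             topologyMode = "tree")
  reach <- .reachableIds(out)
  if (!all(pmjIds %in% out@nodes$id) || !all(pmjIds %in% reach))
    stop("pruning would leave a PMJ terminal unconnected to a parent branch; input mesh is malformed")
  validObject(out)
  out
})

#' @describeIn networkStats Topology summary.
setMethod("networkStats", "PurkinjeNetwork", function(net) {
  g <- asIgraph(net)
  indeg <- igraph::degree(g, mode = "in")
  comp <- igraph::components(igraph::as_undirected(g))$no
  cycles <- nrow(net@edges) - nrow(net@nodes) + comp
  term <- net@nodes$id[net@nodes$role == "pmj_terminal"]
  mult <- setNames(rep(NA_real_, length(term)), as.character(term))
  if (igraph::is_dag(g)) {
    topo <- as.integer(names(igraph::topo_sort(g)))
    np <- setNames(rep(0, nrow(net@nodes)), as.character(net@nodes$id))
    np[as.character(.rootId(net))] <- 1
    for (v in topo) {
      out <- net@edges$to[net@edges$from == v]
      if (length(out))
        np[as.character(out)] <- np[as.character(out)] + np[as.character(v)]
    }
    mult <- np[as.character(term)]
  }
  list(nNodes = nrow(net@nodes), nEdges = nrow(net@edges),
       nCables = nrow(net@cables),
       nTerminals = length(term),
       nReunification = sum(indeg > 1L),
       cycleCount = as.integer(cycles),
       pathMultiplicity = mult,
       allReachable = length(.reachableIds(net)) == nrow(net@nodes))
})

#' Place Purkinje-muscular junctions at fixed density
#'
#' Selects `round(density * area)` terminals (capped by the number of
#' root-reachable `pmj_terminal` nodes, with a warning when the cap binds)
#' and assigns each a myocardial footprint: all tissue nodes within `radius`
#' of the terminal (at least the nearest node). In this 2D setting the
#' volumetric reference density (15 PMJs per cm^3) is interpreted per cm^2.
#'
#' @param net A [PurkinjeNetwork-class].
#' @param domain A [TissueDomain-class].
#' @param density PMJs per cm^2.
#' @param resistance Junctional resistance (Ohm); default 1e5 (100 kOhm).
#' @param seed Integer RNG seed for terminal selection.
#' @param radius Footprint radius (mm).
#' @return A [PMJSet-class].
#' @export
placePMJs <- function(net, domain, density = 15, resistance = 1e5,
                      seed = 1L, radius = 0.8) {
  stopifnot(density > 0, resistance > 0)
  sz <- .domainSize(domain)
  areaCm2 <- prod(sz) / 100
  if (areaCm2 <= 0) stop("zero-measure domain")
  reach <- .reachableIds(net)
  term <- intersect(net@nodes$id[net@nodes$role == "pmj_terminal"], reach)
  if (length(term) < 1L) stop("network has no reachable pmj_terminal nodes")
  count <- round(density * areaCm2)
  if (count < 1L) stop("requested PMJ count is zero for this domain size")
  if (count > length(term)) {
    warning(sprintf("requested %d PMJs but only %d terminals available; capping",
                    count, length(term)))
    count <- length(term)
  }
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(seed)
  chosen <- sort(sample(term, count))
  gx <- rep(seq_len(domain@nx) - 1L, times = domain@ny) * domain@spacing
  gy <- rep(seq_len(domain@ny) - 1L, each = domain@nx) * domain@spacing
  foot <- lapply(chosen, function(id) {
    i <- match(id, net@nodes$id)
    d2 <- (gx - net@nodes$x[i])^2 + (gy - net@nodes$y[i])^2
    f <- which(d2 <= radius^2)
    if (!length(f)) f <- which.min(d2)
    as.integer(f)
  })
  new("PMJSet", terminal = as.integer(chosen),
      resistance = rep(resistance, count), footprint = foot)
}

# ---------------------------------------------------------------------------
# Network text format:
#   purkinet-network 1 <topologyMode>
#   node <id> <x> <y> <z> <role>
#   cable <id> <proximal 0/1> <kind> <cvScale> <node id list ...>
#   pmj <terminal id> <resistance> <footprint tissue ids ...>
# ---------------------------------------------------------------------------

#' Write a Purkinje network (and optionally its PMJs) as plain text
#'
#' @param net A [PurkinjeNetwork-class].
#' @param file Output path.
#' @param pmjs Optional [PMJSet-class].
#' @return `file`, invisibly.
#' @export
writePurkinjeNetwork <- function(net, file, pmjs = NULL) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines(sprintf("purkinet-network 1 %s", net@topologyMode), con)
  nd <- net@nodes
  writeLines(sprintf("node %d %.10g %.10g %.10g %s", nd$id, nd$x, nd$y, nd$z, nd$role), con)
  for (ci in seq_len(nrow(net@cables))) {
    cid <- net@cables$id[ci]
    e <- net@edges[net@edges$cable == cid, , drop = FALSE]
    seqIds <- c(e$from[1], e$to)
    writeLines(sprintf("cable %d %d %s %.10g %s", cid,
                       as.integer(net@cables$proximal[ci]), net@cables$kind[ci],
                       net@cables$cvScale[ci], paste(seqIds, collapse = " ")), con)
  }
  if (!is.null(pmjs))
    for (k in seq_along(pmjs@terminal))
      writeLines(sprintf("pmj %d %.10g %s", pmjs@terminal[k], pmjs@resistance[k],
                         paste(pmjs@footprint[[k]], collapse = " ")), con)
  invisible(file)
}

#' Read a Purkinje network from the package text format
#'
#' @param file Path written by [writePurkinjeNetwork()].
#' @return List with `network` ([PurkinjeNetwork-class]) and `pmjs`
#'   ([PMJSet-class] or `NULL`).
#' @export
readPurkinjeNetwork <- function(file) {
  lines <- readLines(file)
  hdr <- strsplit(lines[1], " +")[[1]]
  if (hdr[1] != "purkinet-network") stop("not a purkinet network file")
  mode <- hdr[3]
  toks <- strsplit(lines[-1], " +")
  kinds <- vapply(toks, `[[`, "", 1)
  ndT <- toks[kinds == "node"]
  nodes <- data.frame(
    id = vapply(ndT, function(t) as.integer(t[2]), 1L),
    x = vapply(ndT, function(t) as.numeric(t[3]), 1),
    y = vapply(ndT, function(t) as.numeric(t[4]), 1),
    z = vapply(ndT, function(t) as.numeric(t[5]), 1),
    role = vapply(ndT, `[[`, "", 6), stringsAsFactors = FALSE)
  cbT <- toks[kinds == "cable"]
  edges <- NULL
  cables <- data.frame(id = integer(), proximal = logical(),
                       cvScale = numeric(), kind = character(),
                       gen = integer(), stringsAsFactors = FALSE)
  for (t in cbT) {
    cid <- as.integer(t[2])
    seqIds <- as.integer(t[-(1:5)])
    cables <- rbind(cables, data.frame(id = cid, proximal = as.logical(as.integer(t[3])),
                                       cvScale = as.numeric(t[5]), kind = t[4],
                                       gen = NA_integer_))
    edges <- rbind(edges, data.frame(from = head(seqIds, -1), to = seqIds[-1],
                                     cable = cid))
  }
  edges$length <- sqrt(
    (nodes$x[match(edges$to, nodes$id)] - nodes$x[match(edges$from, nodes$id)])^2 +
    (nodes$y[match(edges$to, nodes$id)] - nodes$y[match(edges$from, nodes$id)])^2 +
    (nodes$z[match(edges$to, nodes$id)] - nodes$z[match(edges$from, nodes$id)])^2)
  net <- new("PurkinjeNetwork", nodes = nodes, edges = edges, cables = cables,
             topologyMode = mode)
  validObject(net)
  pmT <- toks[kinds == "pmj"]
  pmjs <- NULL
  if (length(pmT))
    pmjs <- new("PMJSet",
                terminal = vapply(pmT, function(t) as.integer(t[2]), 1L),
                resistance = vapply(pmT, function(t) as.numeric(t[3]), 1),
                footprint = lapply(pmT, function(t) as.integer(t[-(1:3)])))
  list(network = net, pmjs = pmjs)
}

#' Export a network as legacy VTK polydata (polylines)
#'
#' @param net A [PurkinjeNetwork-class].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeNetworkVTK <- function(net, file) {
  con <- file(file, "w"); on.exit(close(con))
  nd <- net@nodes
  writeLines(c("# vtk DataFile Version 2.0", "purkinet network", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", nrow(nd))), con)
  writeLines(sprintf("%.6g %.6g %.6g", nd$x, nd$y, nd$z), con)
  idx <- match(net@edges$from, nd$id) - 1L
  idy <- match(net@edges$to, nd$id) - 1L
  writeLines(sprintf("LINES %d %d", length(idx), 3L * length(idx)), con)
  writeLines(sprintf("2 %d %d", idx, idy), con)
  invisible(file)
}
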