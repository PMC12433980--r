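# Network generation, pruning (with the worked toy example and a seeded
# property sweep against an igraph oracle), topology statistics, PMJ
# placement, and the text-format round trip.

# the worked mesh: root -> A; A -> B, A -> C; B -> D, C -> D; D -> P.
# D is a reunification node (two parent cables); pruning must remove only
# the C -> D edge (the larger-id parent cable back to its bifurcation),
# leaving 5 of the 6 edges.
toyMesh <- function() {
  nodes <- data.frame(
    id = 1:6,
    x = c(0, 0, -1, 1, 0, 0), y = c(3, 2, 1, 1, 0, -1), z = 0,
    role = c("his_root", "branch_point", "internal", "internal",
             "reunification", "pmj_terminal"))
  edges <- data.frame(
    from = c(1L, 2L, 2L, 3L, 4L, 5L),
    to = c(2L, 3L, 4L, 5L, 5L, 6L),
    cable = c(1L, 2L, 3L, 4L, 5L, 6L),
    length = 1)
  cables <- data.frame(id = 1:6, proximal = c(TRUE, rep(FALSE, 5)),
                       cvScale = 1,
                       kind = c("his", "branch", "branch", "branch",
                                "bridge", "branch"))
  new("PurkinjeNetwork", nodes = nodes, edges = edges, cables = cables,
      topologyMode = "mesh")
}

test_that("worked example: pruning keeps 5 of 6 edges", {
  tr <- pruneReconnections(toyMesh())
  expect_equal(tr@topologyMode, "tree")
  expect_equal(nrow(tr@edges), 5L)
  # the removed edge is the larger-cable-id parent of the reunification node
  gone <- setdiff(paste(toyMesh()@edges$from, toyMesh()@edges$to),
                  paste(tr@edges$from, tr@edges$to))
  expect_equal(gone, "4 5")
  # the dangling tail node of the other cable survives
  expect_true(4L %in% tr@nodes$id)
  # the PMJ terminal survives and no node keeps two parents
  expect_true(6L %in% tr@nodes$id)
  expect_true(all(table(tr@edges$to) <= 1L))
  # idempotent
  expect_identical(pruneReconnections(tr), tr)
})

test_that("networkStats on the worked mesh", {
  s <- networkStats(toyMesh())
  expect_equal(s$nReunification, 1L)
  expect_equal(s$cycleCount, 1L)  # E - V + C = 6 - 6 + 1
  expect_equal(unname(s$pathMultiplicity), 2)  # root->A->B->D->P, root->A->C->D->P
  expect_true(s$allReachable)
})

test_that("pruned networks satisfy tree invariants across seeds", {
  d <- tissueDomain(30, 30, spacing = 0.5)
  for (seed in 1:12) {
    net <- generateNetwork(d, fascicleSpec = list(nGenerations = 6L),
                           reconnectionRate = 0.4, seed = seed)
    tr <- pruneReconnections(net)
    # tree in-degree, same PMJ-candidate set, reachability (igraph oracle)
    expect_true(all(table(tr@edges$to) <= 1L))
    expect_setequal(tr@nodes$id[tr@nodes$role == "pmj_terminal"],
                    net@nodes$id[net@nodes$role == "pmj_terminal"])
    g <- asIgraph(tr)
    reach <- igraph::subcomponent(g, as.character(tr@nodes$id[tr@nodes$role == "his_root"]),
                                  mode = "out")
    expect_equal(length(reach), nrow(tr@nodes))
    expect_identical(pruneReconnections(tr), tr)
  }
})

test_that("generation is deterministic in the seed", {
  d <- tissueDomain(30, 30, spacing = 0.5)
  a <- generateNetwork(d, fascicleSpec = list(nGenerations = 6L), seed = 7L)
  b <- generateNetwork(d, fascicleSpec = list(nGenerations = 6L), seed = 7L)
  cc <- generateNetwork(d, fascicleSpec = list(nGenerations = 6L), seed = 8L)
  expect_identical(a, b)
  expect_false(identical(a, cc))
})

test_that("generation does not disturb the caller's RNG stream", {
  d <- tissueDomain(30, 30, spacing = 0.5)
  set.seed(99); x1 <- runif(1)
  set.seed(99)
  invisible(generateNetwork(d, fascicleSpec = list(nGenerations = 5L), seed = 3L))
  expect_identical(runif(1), x1)
})

test_that("zero reconnection rate yields a tree outright", {
  d <- tissueDomain(30, 30, spacing = 0.5)
  net <- generateNetwork(d, fascicleSpec = list(nGenerations = 5L),
                         reconnectionRate = 0, seed = 1L)
  expect_equal(net@topologyMode, "tree")
  expect_true(all(table(net@edges$to) <= 1L))
})

test_that("domain too small for the fascicle scaffold errors", {
  expect_error(generateNetwork(tissueDomain(8, 8, spacing = 0.5), seed = 1L),
               "too small")
})

test_that("PMJ placement density, determinism and errors", {
  d <- tissueDomain(40, 40)
  net <- generateNetwork(d, seed = 5L)
  pm <- placePMJs(net, d, density = 10, seed = 2L)
  expect_equal(length(pm@terminal), 160L)  # 10 per cm^2 on 16 cm^2
  expect_identical(placePMJs(net, d, density = 10, seed = 2L), pm)
  expect_true(all(vapply(pm@footprint, length, 1L) > 0))
  expect_true(all(net@nodes$role[match(pm@terminal, net@nodes$id)] == "pmj_terminal"))
  expect_error(placePMJs(net, d, density = -1), "density")
  noTerm <- toyMesh()
  noTerm@nodes$role[6] <- "internal"
  expect_error(placePMJs(noTerm, d), "pmj_terminal")
})

test_that("network text format round-trips", {
  net <- toyMesh()
  f <- tempfile(fileext = ".txt")
  writePurkinjeNetwork(net, f)
  back <- readPurkinjeNetwork(f)$network
  expect_equal(back@topologyMode, net@topologyMode)
  expect_equal(back@nodes$id, net@nodes$id)
  expect_equal(back@nodes$role, net@nodes$role)
  expect_equal(back@edges$from, net@edges$from)
  expect_equal(back@edges$to, net@edges$to)
  expect_equal(back@edges$cable, net@edges$cable)
  expect_equal(back@nodes$x, net@nodes$x, tolerance = 1e-9)
  unlink(f)
})

test_that("validity catches malformed networks", {
  bad <- toyMesh()
  bad@nodes$role[1] <- "internal"  # no his_root
  expect_error(validObject(bad), "his_root")
  bad2 <- toyMesh()
  bad2@topologyMode <- "tree"      # mesh structure declared as tree
  expect_error(validObject(bad2), "in-degree")
})
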