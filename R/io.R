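# Run configuration (YAML), the composite experiment driver, run manifests
# (JSON) and shared CSV writers.

.configSchema <- list(
  fixture   = "list or character; fixtureSpec fields or a spec name",
  cases     = "character subset of mesh, tree, none",
  protocols = "character subset of his, s1, s1s2, line",
  output_dir = "character",
  seed      = "integer",
  solver    = "optional list (dt)",
  log_level = "optional character: quiet, info"
)

#' Read and validate a run configuration
#'
#' YAML for human-authored configs. Schema violations are enumerated in one
#' error, never silently defaulted: required fields are `fixture`,
#' `protocols`, `output_dir` and `seed`; `cases` defaults to all three.
#'
#' @param file YAML path.
#' @return Validated config list.
#' @export
readRunConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param config Config list (as from [readRunConfig()]).
#' @export
validateRunConfig <- function(config) {
  bad <- character()
  for (f in c("fixture", "protocols", "output_dir", "seed"))
    if (is.null(config[[f]])) bad <- c(bad, sprintf("missing required field: %s", f))
  if (!is.null(config$protocols) &&
      !all(config$protocols %in% c("his", "s1", "s1s2", "line")))
    bad <- c(bad, sprintf("unknown protocol: %s",
                          paste(setdiff(config$protocols,
                                        c("his", "s1", "s1s2", "line")),
                                collapse = ", ")))
  if (is.null(config$cases)) config$cases <- c("mesh", "tree", "none")
  if (!all(config$cases %in% c("mesh", "tree", "none")))
    bad <- c(bad, sprintf("unknown case: %s",
                          paste(setdiff(config$cases, c("mesh", "tree", "none")),
                                collapse = ", ")))
  unknown <- setdiff(names(config), names(.configSchema))
  if (length(unknown))
    bad <- c(bad, sprintf("unknown field: %s", paste(unknown, collapse = ", ")))
  if (!is.null(config$seed) &&
      (length(config$seed) != 1 || is.na(suppressWarnings(as.integer(config$seed)))))
    bad <- c(bad, "seed must be a single integer")
  if (length(bad)) stop(paste(bad, collapse = "; "))
  config$seed <- as.integer(config$seed)
  config
}

#' Hash of the canonical serialized configuration
#'
#' MD5 of the canonical (sorted-key, unboxed) JSON form; identifies the run.
#'
#' @param config Config list.
#' @return Hash string.
#' @export
configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[order(names(config))], tmp,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.specFromConfig <- function(config) {
  fx <- config$fixture
  if (is.character(fx)) fx <- list(name = fx)
  fx$seed <- fx$seed %||% config$seed
  do.call(fixtureSpec, fx)
}

#' Write an event stream as CSV
#'
#' Columns `medium, node, time_ms, direction` (1 ascending, -1 descending).
#'
#' @param events Event data frame (a [SimulationTrace-class]'s `events`).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeEventsCSV <- function(events, file) {
  write.csv(data.frame(medium = events$medium, node = events$node,
                       time_ms = events$time, direction = events$dir),
            file, row.names = FALSE)
  invisible(file)
}

.logInfo <- function(config, fmt, ...) {
  if (!identical(config$log_level, "quiet"))
    message(sprintf("[purkinet] %s", sprintf(fmt, ...)))
}

#' Run the composite experiment
#'
#' Orchestrates the study sequence — His pacing (anterograde), apical S1
#' pacing (retrograde), the S1S2 vulnerable-window scan, and rapid line
#' pacing — for each requested model case (mesh / tree / no-network) from
#' one fixture spec, and writes a deterministic result bundle: activation
#' maps (CSV + VTK), event streams, a Table-1-style mesh-vs-tree map
#' comparison JSON, a Table-2-style initiation/maintenance JSON, and a
#' manifest recording config hash, seed, dt and package version.
#'
#' @param config Validated config list ([readRunConfig()]).
#' @return Invisibly, the result bundle list (also written to
#'   `config$output_dir`).
#' @export
runExperiment <- function(config) {
  config <- validateRunConfig(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- .specFromConfig(config)
  dt <- config$solver$dt %||% 0.05
  .logInfo(config, "building fixture '%s' (seed %d)", spec@name, spec@seed)
  models <- list()
  if (any(c("mesh", "tree") %in% config$cases)) {
    fs <- buildFixtureSet(spec, dt = dt)
    models <- fs[intersect(c("mesh", "tree"), config$cases)]
    if ("none" %in% config$cases) models$none <- fs$none
  } else if ("none" %in% config$cases) {
    models$none <- buildFixture(spec, "none", dt = dt)
  }

  res <- list()
  for (case in names(models)) {
    m <- models[[case]]
    r <- list()
    outp <- function(f) file.path(config$output_dir, sprintf("%s_%s", case, f))
    if ("his" %in% config$protocols && !is.null(m@network)) {
      .logInfo(config, "%s: His pacing", case)
      r$his <- runHisPacing(m)
      writeActivationMapCSV(r$his$map, m@domain, outp("anterograde_map.csv"))
      writeFieldVTK(m@domain, r$his$map@at, outp("anterograde_map.vtk"),
                    name = "at_ms")
      writeEventsCSV(r$his$trace@events, outp("his_events.csv"))
    }
    if ("s1" %in% config$protocols) {
      .logInfo(config, "%s: S1 pacing", case)
      r$s1 <- runS1Pacing(m)
      writeActivationMapCSV(r$s1$map, m@domain, outp("retrograde_map.csv"))
      writeFieldVTK(m@domain, r$s1$map@at, outp("retrograde_map.vtk"),
                    name = "at_ms")
      writeEventsCSV(r$s1$trace@events, outp("s1_events.csv"))
    }
    if ("s1s2" %in% config$protocols) {
      .logInfo(config, "%s: S1S2 scan", case)
      r$s1s2 <- runS1S2Scan(m, threshold = r$s1$threshold)
      write.csv(r$s1s2$classifications, outp("s1s2_classifications.csv"),
                row.names = FALSE)
    }
    if ("line" %in% config$protocols) {
      .logInfo(config, "%s: line pacing", case)
      r$line <- runLinePacing(m)
      writeEventsCSV(r$line$trace@events, outp("line_events.csv"))
    }
    res[[case]] <- r
  }

  bundle <- list(cases = names(models))
  # Table-1-style comparison: mesh vs tree activation maps, both directions
  if (all(c("mesh", "tree") %in% names(res))) {
    cmpJson <- list()
    for (dir in c("anterograde", "retrograde")) {
      key <- if (dir == "anterograde") "his" else "s1"
      if (is.null(res$mesh[[key]])) next
      for (med in c("map", "networkMap")) {
        a <- res$mesh[[key]][[med]]; b <- res$tree[[key]][[med]]
        if (is.null(a) || is.null(b)) next
        cc <- compareMaps(a, b)
        cmpJson[[dir]][[a@medium]] <- list(
          rd_pct = cc@rd, rmsd_mean_ms = cc@rmsdMean, rmsd_sd_ms = cc@rmsdSd,
          cc = cc@cc, pct_abs_delta_total_at = cc@pctAbsDeltaTotalAT,
          total_at_mesh_ms = totalAT(a), total_at_tree_ms = totalAT(b),
          n_shared = cc@nShared)
      }
    }
    if (length(cmpJson)) {
      jsonlite::write_json(cmpJson,
                           file.path(config$output_dir, "map_comparison.json"),
                           auto_unbox = TRUE, digits = NA)
      bundle$comparison <- cmpJson
    }
  }
  # Table-2-style initiation / maintenance summary
  arr <- list()
  for (case in names(res)) {
    e <- list()
    if (!is.null(res[[case]]$s1s2)) e$vulnerable_window <- res[[case]]$s1s2$window
    if (!is.null(res[[case]]$line)) {
      rep <- res[[case]]$line$report
      e$line_pacing <- list(induced = rep@induced, rotations = rep@rotations,
                            duration_s = rep@durationS,
                            terminated = rep@terminated)
    }
    if (length(e)) arr[[case]] <- e
  }
  if (length(arr)) {
    jsonlite::write_json(arr, file.path(config$output_dir, "arrhythmia.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    bundle$arrhythmia <- arr
  }

  manifest <- list(
    package = "purkinet",
    version = as.character(utils::packageVersion("purkinet")),
    config = config, config_hash = configHash(config),
    seed = spec@seed, dt = dt,
    created = "see config hash; timestamps omitted for determinism",
    outputs = sort(list.files(config$output_dir)))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  bundle$manifest <- manifest
  bundle$results <- res
  invisible(bundle)
}

#' Materialize fixture files on disk
#'
#' Writes the named fixture's network text files (mesh + tree), the domain
#' parameter CSV, a network VTK, and a manifest JSON with the spec and
#' content hashes — the `fixtures make <name>` CLI backend.
#'
#' @param spec A [FixtureSpec-class].
#' @param outputDir Output directory.
#' @return Invisibly, the manifest list.
#' @export
makeFixtureFiles <- function(spec, outputDir) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  fs <- buildFixtureSet(spec)
  pth <- function(f) file.path(outputDir, f)
  writePurkinjeNetwork(fs$mesh@network, pth("network_mesh.txt"),
                       pmjs = fs$mesh@pmjs)
  writePurkinjeNetwork(fs$tree@network, pth("network_tree.txt"),
                       pmjs = fs$tree@pmjs)
  writeNetworkVTK(fs$mesh@network, pth("network_mesh.vtk"))
  d <- fs$mesh@domain
  co <- tissueCoords(d)
  write.csv(data.frame(node_id = co$node, x = co$x, y = co$y,
                       tau_close = d@tauClose, apd_target_ms = d@apdTarget,
                       D = d@D),
            pth("domain.csv"), row.names = FALSE)
  specList <- list(name = spec@name, width = spec@width, height = spec@height,
                   spacing = spec@spacing, apd_range = spec@apdRange,
                   purkinje_apd_gap = spec@purkinjeApdGap,
                   pmj_density = spec@pmjDensity,
                   pmj_resistance = spec@pmjResistance,
                   reconnection_rate = spec@reconnectionRate,
                   seed = spec@seed)
  files <- c("network_mesh.txt", "network_tree.txt", "network_mesh.vtk",
             "domain.csv")
  manifest <- list(spec = specList,
                   hashes = as.list(unname(tools::md5sum(vapply(files, pth, "")))))
  names(manifest$hashes) <- files
  jsonlite::write_json(manifest, pth("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
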