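# Plain-text potentials format: first line "# fs=<Hz> units=mV", then one
# node per row, samples separated by whitespace.  Chosen so every
# intermediate artifact is diffable.

#' Read a potentials matrix
#'
#' @param path File with a `# fs=<Hz> units=mV` header line followed by
#'   one whitespace-delimited row per node.
#' @param role Role to assign to the field.
#' @return A [potential_field()].
#' @export
read_potentials <- function(path, role = "measured") {
  ln <- readLines(path)
  if (length(ln) == 0) stopf("%s: empty file", path)
  m <- regmatches(ln[1], regexec("^#\\s*fs=([0-9.eE+-]+)\\s+units=mV", ln[1]))[[1]]
  if (length(m) == 0)
    stopf("%s line 1: missing or invalid '# fs=<Hz> units=mV' header", path)
  fs <- as.numeric(m[2])
  body <- ln[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) stopf("%s: no data rows", path)
  rows <- lapply(body, function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]]))
  len <- vapply(rows, length, integer(1))
  if (length(unique(len)) != 1)
    stopf("%s row %d: ragged row (%d values, expected %d)",
          path, which(len != len[1])[1] + 1, len[which(len != len[1])[1]], len[1])
  potential_field(do.call(rbind, rows), fs, role)
}

#' Write a potentials matrix
#'
#' @param field A [potential_field()].
#' @param path Output path.
#' @param digits Significant digits (default 10; round-trips at printed
#'   precision).
#' @return `path`, invisibly.
#' @export
write_potentials <- function(field, path, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%s units=mV", format(field$fs, digits = 12)), con)
  writeLines(apply(field$values, 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " ")), con)
  invisible(path)
}

#' Write a per-node map with a JSON sidecar
#'
#' Two-column tab-separated text (node index, value) plus
#' `<path>.json` carrying the metadata.
#'
#' @param values Per-node values (numeric, character or factor).
#' @param path Output path.
#' @param meta Named list of metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_map <- function(values, path, meta = list()) {
  utils::write.table(
    data.frame(node = seq_along(values) - 1L, value = as.vector(values)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Run the full processing chain
#'
#' simulate (optional) -> baseline removal -> low-pass filtering -> beat
#' segmentation -> bipolar electrogram construction -> amplitude /
#' tissue / fragmentation maps.  Every intermediate artifact is written
#' to `out_dir` together with a manifest recording the parameters and
#' seed that produced each file.  Deterministic given the seed.
#'
#' @param config Named list: either `scenario` (a [scenario_config()] or
#'   arguments for one) to simulate inputs, or `mesh_file` +
#'   `potentials_file` to load them; optional stage parameters `Tw`
#'   (default 1 s), `knot_rule`, `fc` (100 Hz), `order` (9), `dspo`
#'   (default `"theta_V_alpha"`), `alpha`, `seed`, `beat` (which
#'   segmented beat to analyse, default 1).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the pipeline objects (`mesh`, `field`,
#'   `detrended`, `filtered`, `beats`, `window`, `begms`, `vpp`,
#'   `tissue`, `frag`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  manifest <- list(seed = seed, stages = list())
  note <- function(stage, file, params) {
    manifest$stages[[stage]] <<- list(file = file, params = params)
  }

  if (!is.null(config$scenario)) {
    sc <- if (inherits(config$scenario, "scenario_config")) config$scenario
          else do.call(scenario_config, config$scenario)
    scen <- generate_scenario(sc)
    mesh <- scen$mesh
    field <- scen$measured
    write_mesh_off(mesh, file.path(out_dir, "mesh.off"))
    write_potentials(field, file.path(out_dir, "measured.txt"))
    truth_file <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(
      list(activation_s = scen$truth$activation,
           label = as.character(scen$truth$label),
           config = unclass(sc)),
      truth_file, digits = NA, auto_unbox = TRUE, null = "null"
    )
    note("simulate", "measured.txt",
         list(seed = sc$seed, nodes = mesh$n_vertices, fs = sc$fs))
  } else {
    if (is.null(config$mesh_file) || is.null(config$potentials_file))
      stopf("config needs either 'scenario' or 'mesh_file' + 'potentials_file'")
    mesh <- read_mesh(config$mesh_file)
    field <- read_potentials(config$potentials_file)
  }

  Tw <- config$Tw %||% 1
  knot_rule <- config$knot_rule %||% "sample"
  bl <- remove_baseline(field, Tw, knot_rule)
  write_potentials(bl$detrended, file.path(out_dir, "detrended.txt"))
  note("baseline", "detrended.txt", list(Tw = Tw, knot_rule = knot_rule))

  fc <- config$fc %||% 100
  order <- config$order %||% 9
  lp <- lowpass_filter(bl$detrended, fc, order)
  write_potentials(lp$filtered, file.path(out_dir, "filtered.txt"))
  note("lowpass", "filtered.txt", list(fc = fc, order = order))

  beats <- segment_beats(lp$filtered)
  jsonlite::write_json(
    lapply(beats, function(w) list(t_in = w$t_in, t_end = w$t_end)),
    file.path(out_dir, "beats.json"), digits = NA, auto_unbox = TRUE
  )
  note("segment", "beats.json", list(threshold = 0.3, margin = 0.05))
  if (length(beats) == 0) stopf("segment: no beats found (flat field?)")
  beat_i <- config$beat %||% 1
  if (beat_i > length(beats))
    stopf("segment: beat %d requested but only %d found", beat_i, length(beats))
  window <- beats[[beat_i]]

  spec <- dspo_spec(config$dspo %||% "theta_V_alpha",
                    alpha = config$alpha, seed = seed)
  begms <- bipolar_field(lp$filtered, mesh, spec, window)
  bip_mat <- do.call(rbind, lapply(begms, function(b) b$signal))
  write_potentials(potential_field(bip_mat, field$fs, "clean"),
                   file.path(out_dir, "bipolar.txt"))
  jsonlite::write_json(
    list(dspo = spec$id, alpha = spec$alpha,
         reference = vapply(begms, function(b)
           if (identical(b$reference, "virtual-mean")) -1L
           else as.integer(b$reference) - 1L, integer(1))),
    file.path(out_dir, "bipolar_refs.json"), auto_unbox = TRUE, digits = NA
  )
  note("bipolar", "bipolar.txt",
       list(dspo = spec$id, alpha = spec$alpha,
            window = c(window$t_in, window$t_end)))

  vpp <- amplitude_map(begms)
  tissue <- classify_tissue(vpp, mode = "bipolar")
  frag <- fragmentation_map(begms)
  write_map(vpp$vpp, file.path(out_dir, "vpp.tsv"),
            meta = list(source = vpp$source, units = "mV",
                        window = c(window$t_in, window$t_end)))
  write_map(as.character(tissue$label), file.path(out_dir, "tissue.tsv"),
            meta = list(thresholds_mv = tissue$thresholds, mode = tissue$mode))
  write_map(frag$notches, file.path(out_dir, "notches.tsv"),
            meta = list(prominence_mv = frag$prominence,
                        margin_s = frag$margin,
                        min_notches = frag$min_notches))
  note("maps", "vpp.tsv",
       list(thresholds_mv = tissue$thresholds,
            prominence_mv = frag$prominence))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(mesh = mesh, field = field, detrended = bl$detrended,
                 filtered = lp$filtered, beats = beats, window = window,
                 begms = begms, vpp = vpp, tissue = tissue, frag = frag,
                 manifest = manifest))
}
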