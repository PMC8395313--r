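# End-to-end orchestration: profile a sequence panel, simulate a synthetic
# trajectory, analyze a trajectory into traces and a mode call. Every
# artifact embeds a config hash and the package version so runs are
# attributable and reproducible.

.pipeline_version <- function() {
  as.character(utils::packageVersion("helimode"))
}

#' Stable configuration hash
#'
#' @param config A list of configuration values.
#' @return Short hex hash string.
#' @export
config_hash <- function(config) {
  substr(rlang::hash(config), 1, 12)
}

#' Profile a panel of sequences
#'
#' Runs the amphipathicity profile over a FASTA file or a tidy peptide
#' table and optionally writes the result as TSV. With the bundled peptide
#' set this reproduces the standard sequence-property table for the five
#' anticancer peptides.
#'
#' @param input FASTA path or a data frame with `id`/`sequence` columns.
#' @param out_dir Output directory (`NULL` = no files written).
#' @inheritParams pep_profile
#' @return The profile tibble.
#' @export
pipeline_profile <- function(input, out_dir = NULL, scale = "fauchere_pliska",
                             window = 11L, delta = 100) {
  peptides <- if (is.character(input)) read_peptides(input) else input
  profile <- pep_profile(peptides, scale = scale, window = window,
                         delta = delta)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_profile_tsv(profile, file.path(out_dir, "profile.tsv"))
  }
  profile
}

#' Simulate a synthetic trajectory to disk
#'
#' Generates a mode-conditioned trajectory and writes the multi-model PDB
#' plus a ground-truth JSON (spec, config hash, package version).
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory.
#' @param basename File stem for the two artifacts.
#' @return Invisibly, list with `trajectory` (the tibble), `pdb`, `json`
#'   (paths).
#' @export
pipeline_simulate <- function(spec, out_dir, basename = "trajectory") {
  if (!inherits(spec, "synthetic_spec")) abort("`spec` must be a synthetic_spec.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  traj <- generate_mode_trajectory(spec)
  pdb <- file.path(out_dir, paste0(basename, ".pdb"))
  write_structures(traj, pdb)
  meta <- spec
  meta$peptide <- list(
    id = spec$peptide$id,
    sequence = paste(spec$peptide$residues, collapse = ""),
    c_terminal_amidated = spec$peptide$c_terminal_amidated
  )
  class(meta) <- NULL
  record <- list(
    tool = "helimode", version = .pipeline_version(),
    config_hash = config_hash(meta), spec = meta
  )
  json <- file.path(out_dir, paste0(basename, "_ground_truth.json"))
  jsonlite::write_json(record, json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(trajectory = traj, pdb = pdb, json = json))
}

#' Analyze a trajectory into traces and a binding-mode call
#'
#' Computes helicity, surface-distance, tilt, per-residue depth, signed
#' centre-of-mass height, and footprint traces, then classifies the binding
#' mode. Optionally writes each trace as a TSV (with a header naming the
#' metric, units, smoothing alpha and config hash) and the call as JSON.
#'
#' @param input Trajectory tibble or path to a multi-model PDB.
#' @param out_dir Output directory (`NULL` = nothing written).
#' @param alpha Exponential-smoothing weight for the helicity and distance
#'   traces (`NULL` = raw only).
#' @param thresholds A [mode_thresholds()] list.
#' @param timestep Frame spacing (ps) when reading from PDB.
#' @return An object of class `"traj_analysis"`: list with `traces` (named
#'   list of tibbles), `call` (a `binding_mode_call`), `config_hash`.
#' @export
pipeline_analyze <- function(input, out_dir = NULL, alpha = 0.05,
                             thresholds = mode_thresholds(),
                             timestep = 1000) {
  traj <- if (is.character(input)) read_structures(input, timestep = timestep)
          else input
  if (!any(traj$part == "lipidP")) {
    abort("Trajectory has no phosphorus atoms: no bilayer to analyze against.")
  }
  traces <- .all_traces(traj, alpha = alpha)
  call <- classify_binding_mode(
    traces$helicity, traces$distance, traces$tilt, traces$depth,
    com_height = traces$com_height, footprint = traces$footprint,
    thresholds = thresholds
  )
  cfg <- list(alpha = alpha, thresholds = thresholds,
              version = .pipeline_version())
  hash <- config_hash(cfg)
  out <- structure(
    list(traces = traces, call = call, config_hash = hash),
    class = "traj_analysis"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(traces)) {
      tr <- traces[[nm]]
      path <- file.path(out_dir, paste0(nm, "_trace.tsv"))
      header <- sprintf(
        "# metric=%s units=%s alpha=%s config=%s tool=helimode/%s",
        attr(tr, "metric") %||% nm, attr(tr, "units") %||% "",
        if (is.null(attr(tr, "alpha"))) "none" else attr(tr, "alpha"),
        hash, .pipeline_version()
      )
      writeLines(header, path)
      suppressWarnings(utils::write.table(
        tr, path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE
      ))
    }
    call_record <- list(
      tool = "helimode", version = .pipeline_version(), config_hash = hash,
      mode = call$mode, low_confidence = call$low_confidence,
      evidence = as.list(call$evidence),
      window_used = as.list(call$window_used),
      thresholds = thresholds
    )
    jsonlite::write_json(call_record, file.path(out_dir, "mode_call.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    summary_line <- sprintf(
      "mode=%s\tlow_confidence=%s\tbound_fraction=%.3f\tmean_helicity=%.3f\tmedian_tilt=%.1f\tconfig=%s",
      call$mode, call$low_confidence, call$evidence[["bound_fraction"]],
      call$evidence[["mean_helicity"]], call$evidence[["median_tilt"]], hash
    )
    writeLines(summary_line, file.path(out_dir, "mode_call.tsv"))
  }
  out
}

# single pass over frames computing every trace (labels reused for both
# helicity and tilt); equivalent to the individual *_trace() functions
.all_traces <- function(traj, alpha = 0.05) {
  frames <- traj_frames(traj)
  n <- length(frames)
  hel <- dist <- comh <- tiltv <- azv <- foot <- numeric(n)
  depths <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    labels <- tryCatch(
      assign_helix(fr),
      error = function(e) abort(sprintf("Frame %d: %s", i, conditionMessage(e)))
    )
    hel[i] <- helicity_fraction(labels)
    d <- peptide_surface_distance(fr)
    dist[i] <- as.numeric(d)
    comh[i] <- attr(d, "signed")
    ta <- .tilt_of_frame(fr, labels = labels)
    tiltv[i] <- ta[["tilt"]]; azv[i] <- ta[["azimuth"]]
    foot[i] <- surface_footprint(fr)
    dd <- residue_insertion_depths(fr)
    depths[[i]] <- dplyr::bind_cols(
      tibble(frame = i, time = attr(fr, "time") %||% NA_real_,
             .rows = nrow(dd)),
      dd
    )
  }
  list(
    helicity = .new_trace(frames, hel, "helicity", "fraction", alpha = alpha),
    distance = .new_trace(frames, dist, "surface_distance", "nm",
                          alpha = alpha),
    tilt = .new_trace(frames, tiltv, "tilt", "degrees",
                      extra = tibble(azimuth = azv)),
    depth = dplyr::bind_rows(depths),
    com_height = .new_trace(frames, comh, "com_height", "nm"),
    footprint = .new_trace(frames, foot, "footprint", "nm^2")
  )
}

#' @export
print.traj_analysis <- function(x, ...) {
  cat(sprintf("<traj_analysis> %d frames, config %s\n",
              nrow(x$traces$helicity), x$config_hash))
  print(x$call)
  invisible(x)
}

#' @rdname tidy.binding_mode_call
#' @param metric For `tidy.traj_analysis()`: which traces to stack.
#' @export
tidy.traj_analysis <- function(x, metric = c("helicity", "distance", "tilt"),
                               ...) {
  purrr::map_dfr(metric, function(nm) {
    tr <- x$traces[[nm]]
    tibble(metric = nm, frame = tr$frame, time = tr$time, value = tr$value)
  })
}

#' @rdname tidy.binding_mode_call
#' @export
glance.traj_analysis <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$call),
    tibble(config_hash = x$config_hash)
  )
}
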