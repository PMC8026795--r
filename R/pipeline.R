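#' Write a complete self-contained phantom test case to disk
#'
#' Emits everything the full pipeline consumes for one synthetic case:
#' geometry YAML, per-assembly CT volumes (NIfTI), simulated frontal and
#' lateral radiographs (float TIFF), per-segment meshes (ASCII STL), arrow
#' annotations and masks (JSON), measurement landmarks (JSON), 2D fiducial
#' projections (CSV) and a ground-truth file (JSON) with the true poses and
#' deformity angles.
#'
#' @param dir output directory (created if missing).
#' @param spec a [phantom_spec()].
#' @param g an [eos_geometry()].
#' @param poses per-bone true poses; default
#'   [phantom_weightbearing_poses()].
#' @param noise_sigma image noise passed to [simulate_eos_pair()].
#' @return invisibly, a named list of all written paths plus the built
#'   `truth` and simulation objects.
#' @export
write_phantom_case <- function(dir, spec = phantom_spec(),
                               g = phantom_geometry(), poses = NULL,
                               noise_sigma = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mesh_dir <- file.path(dir, "meshes")
  dir.create(mesh_dir, showWarnings = FALSE)
  truth <- build_phantom(spec)
  if (is.null(poses)) poses <- phantom_weightbearing_poses(truth)
  sim <- simulate_eos_pair(truth, poses$femur, poses$tibia, g, noise_sigma)

  paths <- list(
    geometry = file.path(dir, "geometry.yaml"),
    frontal = file.path(dir, "frontal.tif"),
    lateral = file.path(dir, "lateral.tif"),
    ct_femur = file.path(dir, "ct_femur.nii.gz"),
    ct_tibia = file.path(dir, "ct_tibia.nii.gz"),
    annotations = file.path(dir, "annotations.json"),
    landmarks = file.path(dir, "landmarks.json"),
    markers_frontal = file.path(dir, "markers_frontal.csv"),
    markers_lateral = file.path(dir, "markers_lateral.csv"),
    markers_ct = file.path(dir, "markers_ct.csv"),
    truth = file.path(dir, "truth.json"),
    meshes = mesh_dir
  )
  write_eos_geometry(g, paths$geometry)
  write_radiograph(sim$pair$frontal, paths$frontal)
  write_radiograph(sim$pair$lateral, paths$lateral)
  write_ct_volume(truth$segment_volumes$femur, paths$ct_femur)
  write_ct_volume(truth$segment_volumes$tibia, paths$ct_tibia)
  write_annotations(list(
    femur = list(arrow = sim$annotations$femur, masks = sim$masks$femur),
    tibia = list(arrow = sim$annotations$tibia, masks = sim$masks$tibia)
  ), paths$annotations)
  write_landmarks(truth$landmarks, paths$landmarks)
  utils::write.csv(sim$markers2d$frontal, paths$markers_frontal, row.names = FALSE)
  utils::write.csv(sim$markers2d$lateral, paths$markers_lateral, row.names = FALSE)
  write_markers_3d(truth$markers, paths$markers_ct)
  for (nm in names(truth$meshes)) {
    p <- file.path(mesh_dir, paste0(nm, ".stl"))
    write_stl(truth$meshes[[nm]], p)
    paths[[paste0("mesh_", nm)]] <- p
  }
  jsonlite::write_json(list(
    side = truth$side, ma = truth$ma, jlca = truth$jlca,
    pose_femur = unclass(poses$femur), pose_tibia = unclass(poses$tibia)
  ), paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(truth = truth, sim = sim, poses = poses)))
}

#' Pipeline configuration
#'
#' @param geometry,frontal,lateral,ct_femur,ct_tibia,annotations,landmarks
#'   input file paths; `mesh_dir` a directory of per-segment STL meshes
#'   (`femur.stl`, `tibia.stl`, `fibula.stl`, `patella.stl`, `talus.stl`).
#' @param side `"left"` or `"right"`.
#' @param out_dir output directory for the report and transforms.
#' @param ajc_threshold,cut_fraction measurement options (see
#'   [compute_ajc()], [compute_fct()]).
#' @param registration a [registration_config()].
#' @param seed integer seed recorded in the report.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(geometry, frontal, lateral, ct_femur, ct_tibia,
                            annotations, landmarks, mesh_dir,
                            side = c("left", "right"), out_dir = tempdir(),
                            ajc_threshold = 3, cut_fraction = 0.15,
                            registration = registration_config(),
                            seed = 1L) {
  side <- match.arg(side)
  structure(list(geometry = geometry, frontal = frontal, lateral = lateral,
                 ct_femur = ct_femur, ct_tibia = ct_tibia,
                 annotations = annotations, landmarks = landmarks,
                 mesh_dir = mesh_dir, side = side, out_dir = out_dir,
                 ajc_threshold = ajc_threshold, cut_fraction = cut_fraction,
                 registration = registration, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full registration-and-measurement pipeline
#'
#' Mirrors the end-to-end workflow: register femur and tibia to the
#' biplanar radiographs, transform the 3D surface models (and the
#' bone-attached landmarks) into the weight-bearing pose, measure MA and
#' JLCA in both the original non-weight-bearing state and the registered
#' weight-bearing state, and write a JSON report with both states and
#' their absolute differences.  Angles are reported to 0.1 degree in the
#' summary fields; full-precision values are kept in the machine fields.
#'
#' @param cfg a [pipeline_config()].
#' @return the report as a list (invisibly written to
#'   `<out_dir>/report.json` together with the per-bone transforms).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  for (f in c("geometry", "frontal", "lateral", "ct_femur", "ct_tibia",
              "annotations", "landmarks")) {
    if (!file.exists(cfg[[f]])) {
      stop(sprintf("pipeline stage 'inputs' failed: missing %s file: %s",
                   f, cfg[[f]]), call. = FALSE)
    }
  }
  g <- stage("geometry", read_eos_geometry(cfg$geometry))
  pair <- stage("images", radiograph_pair(read_radiograph(cfg$frontal),
                                          read_radiograph(cfg$lateral), g))
  ann <- stage("annotations", read_annotations(cfg$annotations))
  landmarks <- stage("landmarks", read_landmarks(cfg$landmarks))
  meshes <- stage("meshes", {
    out <- list()
    for (nm in c("femur", "tibia", "fibula", "patella", "talus")) {
      p <- file.path(cfg$mesh_dir, paste0(nm, ".stl"))
      if (file.exists(p)) out[[nm]] <- read_stl(p, nm)
    }
    out
  })
  vols <- stage("volumes", list(femur = read_ct_volume(cfg$ct_femur),
                                tibia = read_ct_volume(cfg$ct_tibia)))

  fits <- list()
  for (bone in c("femur", "tibia")) {
    fits[[bone]] <- stage(paste0("register_", bone), {
      register_bone(hu_to_attenuation(vols[[bone]]), pair,
                    ann[[bone]]$arrow, ann[[bone]]$masks, cfg$registration)
    })
  }

  measure_state <- function(mesh_set, lm) {
    measure_alignment(mesh_set, lm, cfg$side,
                      ajc_threshold = cfg$ajc_threshold,
                      cut_fraction = cfg$cut_fraction)
  }
  nwb <- stage("measure_nwb", measure_state(meshes, landmarks))

  tf <- lapply(fits, `[[`, "transform")
  wb_meshes <- stage("transform_meshes", {
    out <- meshes
    out$femur <- transform_mesh(meshes$femur, tf$femur)
    if (!is.null(meshes$patella)) {
      out$patella <- transform_mesh(meshes$patella, tf$femur)
    }
    for (nm in c("tibia", "fibula", "talus")) {
      if (!is.null(meshes[[nm]])) out[[nm]] <- transform_mesh(meshes[[nm]], tf$tibia)
    }
    out
  })
  wb_landmarks <- stage("transform_landmarks", {
    lm <- landmarks
    for (nm in c("femoral_head_points", "patella_points", "epicondyles")) {
      if (!is.null(lm[[nm]])) lm[[nm]] <- transform_points(tf$femur, lm[[nm]])
    }
    for (nm in c("eminences", "plateau_points")) {
      lm[[nm]] <- transform_points(tf$tibia, lm[[nm]])
    }
    lm
  })
  wb <- stage("measure_wb", measure_state(wb_meshes, wb_landmarks))

  report <- list(
    side = cfg$side,
    seed = cfg$seed,
    non_weight_bearing = list(ma = round(nwb$ma, 1), jlca = round(nwb$jlca, 1),
                              ma_exact = nwb$ma, jlca_exact = nwb$jlca),
    weight_bearing = list(ma = round(wb$ma, 1), jlca = round(wb$jlca, 1),
                          ma_exact = wb$ma, jlca_exact = wb$jlca),
    difference = list(ma = round(abs(wb$ma - nwb$ma), 1),
                      jlca = round(abs(wb$jlca - nwb$jlca), 1),
                      ma_exact = abs(wb$ma - nwb$ma),
                      jlca_exact = abs(wb$jlca - nwb$jlca)),
    registration = lapply(fits, function(f) {
      list(similarity = f$similarity, evaluations = f$evaluations,
           converged = f$converged, status = f$status)
    })
  )
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_transform(tf$femur, file.path(cfg$out_dir, "transform_femur.txt"))
  write_transform(tf$tibia, file.path(cfg$out_dir, "transform_tibia.txt"))
  report
}
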