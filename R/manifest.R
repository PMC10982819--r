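.manifestCols <- c("patient_id", "node_id", "patch_file", "mask_file",
                   "adc_file", "long_diam_mm", "short_diam_mm", "diam_ratio",
                   "mean_adc", "latent_met", "n_resected", "n_metastatic",
                   "y", "rho", "stage_true", "enroll_order", "cohort_tag")

#' Build the cohort manifest table
#'
#' One row per visible node with per-node features, per-patient pathology
#' labels and the cohort tag; the CSV form of this table is the interchange
#' format between the simulate / train / predict / evaluate steps.
#'
#' @param cohort an [LNCohort-class].
#' @param tag cohort tag (e.g. `"train"`, `"internal_test"`).
#' @param fileStub optional stub used to fill the per-node array file
#'   references.
#' @return data.frame with the manifest columns.
#' @export
cohortManifest <- function(cohort, tag = "train", fileStub = "nodes") {
  rows <- lapply(bags(cohort), function(b) {
    nid <- vapply(b@nodes, function(n) n@nodeId, character(1))
    data.frame(
      patient_id = b@patientId, node_id = nid,
      patch_file = file.path(fileStub, paste0(nid, "_patch.nii")),
      mask_file = file.path(fileStub, paste0(nid, "_mask.nii")),
      adc_file = file.path(fileStub, paste0(nid, "_adc.nii")),
      long_diam_mm = vapply(b@nodes, function(n) n@longDiamMm, numeric(1)),
      short_diam_mm = vapply(b@nodes, function(n) n@shortDiamMm, numeric(1)),
      diam_ratio = vapply(b@nodes, function(n) n@diamRatio, numeric(1)),
      mean_adc = vapply(b@nodes, function(n) n@meanAdc, numeric(1)),
      latent_met = vapply(b@nodes, function(n) n@latentMet, logical(1)),
      n_resected = b@nResected, n_metastatic = b@nMetastatic,
      y = b@y, rho = b@rho, stage_true = b@stageTrue,
      enroll_order = b@enrollOrder, cohort_tag = tag,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# fixed floating-point formatting so identical inputs give byte-identical CSVs
.writeCsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 10, format = "g")
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     quote = FALSE, eol = "\n")
  invisible(path)
}

#' Write a cohort to disk
#'
#' Writes `manifest.csv`, a `params.json` sidecar echoing the resolved
#' simulation parameters and seed, and per-node patch/mask/ADC arrays as
#' uncompressed NIfTI under `nodes/`. Outputs are byte-reproducible for
#' identical inputs.
#'
#' @param cohort an [LNCohort-class].
#' @param dir output directory (created if needed).
#' @param tag cohort tag recorded in the manifest.
#' @param writeArrays skip the NIfTI arrays when `FALSE` (manifest only).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir, tag = "train", writeArrays = TRUE) {
  dir.create(file.path(dir, "nodes"), recursive = TRUE, showWarnings = FALSE)
  mf <- cohortManifest(cohort, tag = tag)
  .writeCsv(mf, file.path(dir, "manifest.csv"))
  p <- cohort@params
  sidecar <- if (is(p, "CohortParams"))
    lapply(slotNames(p), function(s) slot(p, s)) else list()
  if (is(p, "CohortParams")) names(sidecar) <- slotNames(p)
  jsonlite::write_json(sidecar, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (writeArrays) {
    for (b in bags(cohort)) for (n in b@nodes) {
      RNifti::writeNifti(n@patch,
        file.path(dir, "nodes", paste0(n@nodeId, "_patch.nii")))
      RNifti::writeNifti(n@mask,
        file.path(dir, "nodes", paste0(n@nodeId, "_mask.nii")))
      if (!is.null(n@adcPatch))
        RNifti::writeNifti(n@adcPatch,
          file.path(dir, "nodes", paste0(n@nodeId, "_adc.nii")))
    }
  }
  invisible(dir)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir cohort directory.
#' @return an [LNCohort-class]; the params slot carries the JSON sidecar
#'   as a plain list.
#' @export
readCohort <- function(dir) {
  mf <- loadManifest(file.path(dir, "manifest.csv"))
  params <- if (file.exists(file.path(dir, "params.json")))
    jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  else NULL
  bagsOut <- lapply(split(mf, mf$patient_id), function(rows) {
    rows <- rows[order(rows$node_id), ]
    nodesOut <- lapply(seq_len(nrow(rows)), function(i) {
      rd <- function(f) {
        a <- RNifti::readNifti(file.path(dir, f))
        matrix(as.numeric(a), nrow(a), ncol(a))
      }
      adc <- if (file.exists(file.path(dir, rows$adc_file[i])))
        rd(rows$adc_file[i]) else NULL
      new("LymphNode", nodeId = rows$node_id[i],
          patch = rd(rows$patch_file[i]), mask = rd(rows$mask_file[i]),
          adcPatch = adc,
          longDiamMm = rows$long_diam_mm[i],
          shortDiamMm = rows$short_diam_mm[i],
          diamRatio = rows$diam_ratio[i], meanAdc = rows$mean_adc[i],
          latentMet = as.logical(rows$latent_met[i]))
    })
    new("PatientBag", patientId = rows$patient_id[1], nodes = nodesOut,
        nResected = as.integer(rows$n_resected[1]),
        nMetastatic = as.integer(rows$n_metastatic[1]),
        y = as.integer(rows$y[1]), rho = rows$rho[1],
        stageTrue = rows$stage_true[1],
        enrollOrder = as.integer(rows$enroll_order[1]))
  })
  ord <- order(vapply(bagsOut, function(b) b@enrollOrder, integer(1)))
  new("LNCohort", bags = bagsOut[ord], params = params)
}

#' Load a cohort manifest CSV
#'
#' @param path CSV path with the documented manifest header.
#' @return typed manifest data.frame.
#' @export
loadManifest <- function(path) {
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.manifestCols, names(mf))
  if (length(missing))
    stop("manifest schema error: missing columns ",
         paste(missing, collapse = ", "))
  mf
}

#' Validate a cohort manifest
#'
#' Checks every manifest invariant and returns all violations (with row
#' numbers) instead of stopping at the first: count consistency
#' (`0 <= n_metastatic <= n_resected`), label consistency
#' (`y == (n_metastatic > 0)`, `rho == n_metastatic / n_resected`,
#' stage/count agreement), constancy of patient-level fields across a
#' patient's rows, no patient in two cohort tags, and (optionally)
#' existence of the referenced array files.
#'
#' @param manifest manifest data.frame.
#' @param dir base directory for file-existence checks.
#' @param checkFiles whether to check referenced files.
#' @return data.frame of violations (`row`, `field`, `message`);
#'   zero rows when the manifest is valid.
#' @export
validateManifest <- function(manifest, dir = ".", checkFiles = FALSE) {
  v <- list()
  flag <- function(row, field, message)
    v[[length(v) + 1]] <<- data.frame(row = row, field = field,
                                      message = message,
                                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    if (r$n_metastatic < 0 || r$n_metastatic > r$n_resected)
      flag(i, "n_metastatic", "need 0 <= n_metastatic <= n_resected")
    if (abs(r$rho - r$n_metastatic / r$n_resected) > 1e-6)
      flag(i, "rho", "rho != n_metastatic / n_resected")
    if (r$y != as.integer(r$n_metastatic > 0))
      flag(i, "y", "y != (n_metastatic > 0)")
    if (r$n_metastatic >= 0 &&
        !identical(r$stage_true, countToStage(max(r$n_metastatic, 0))))
      flag(i, "stage_true", "stage_true inconsistent with n_metastatic")
  }
  patientCols <- c("n_resected", "n_metastatic", "y", "rho", "stage_true",
                   "enroll_order", "cohort_tag")
  for (pid in unique(manifest$patient_id)) {
    rows <- which(manifest$patient_id == pid)
    for (cc in patientCols)
      if (length(unique(manifest[[cc]][rows])) > 1)
        flag(rows[1], cc,
             paste0("patient-level field ", cc,
                    " varies across rows of patient ", pid))
    if (length(unique(manifest$cohort_tag[rows])) > 1)
      flag(rows[1], "cohort_tag",
           paste0("patient ", pid, " appears in two cohort tags"))
  }
  if (checkFiles) {
    for (cc in c("patch_file", "mask_file", "adc_file")) {
      miss <- which(!file.exists(file.path(dir, manifest[[cc]])))
      for (i in miss) flag(i, cc, "referenced file does not exist")
    }
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(row = integer(0), field = character(0),
                  message = character(0), stringsAsFactors = FALSE)
}

#' Chronological train/test split
#'
#' Splits patients by enrollment order: the first
#' \eqn{\lceil n \, r / (r + 1) \rceil} patients (ratio r:1) form the
#' training cohort and the remainder the test cohort. Patient-level by
#' construction (a patient is never split) and invariant to the row order
#' of the manifest.
#'
#' @param manifest manifest data.frame with an `enroll_order` column.
#' @param ratio train:test ratio (`4` means 4:1).
#' @return list with `train` and `test` patient-id vectors and `tags`, a
#'   named per-patient tag vector.
#' @export
chronologicalSplit <- function(manifest, ratio = 4) {
  if (!"enroll_order" %in% names(manifest) ||
      anyNA(manifest$enroll_order))
    stop("manifest lacks a sortable enrollment key (enroll_order)")
  pat <- unique(manifest[, c("patient_id", "enroll_order")])
  pat <- pat[order(pat$enroll_order, pat$patient_id), ]
  n <- nrow(pat)
  nTrain <- as.integer(ceiling(n * ratio / (ratio + 1)))
  tags <- c(rep("train", nTrain), rep("test", n - nTrain))
  names(tags) <- pat$patient_id
  list(train = pat$patient_id[seq_len(nTrain)],
       test = pat$patient_id[setdiff(seq_len(n), seq_len(nTrain))],
       tags = tags)
}

.checkKeys <- function(cfg, allowed, what) {
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown ", what, " configuration keys: ",
         paste(unknown, collapse = ", "))
  cfg
}

#' Read a YAML simulation configuration
#'
#' Keys mirror the arguments of [cohortParams()]; unknown keys are errors
#' (typo guard).
#'
#' @param path YAML file.
#' @return a [CohortParams-class].
#' @export
readCohortConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  .checkKeys(cfg, names(formals(cohortParams)), "simulation")
  do.call(cohortParams, cfg)
}

#' Read a YAML training configuration
#'
#' Keys mirror the arguments of [modelConfig()]; unknown keys are errors.
#'
#' @param path YAML file.
#' @return a `ModelConfig` list.
#' @export
readTrainConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  .checkKeys(cfg, names(formals(modelConfig)), "training")
  do.call(modelConfig, cfg)
}
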