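#' Write a plan case as NIfTI volumes
#'
#' Writes `ct.nii.gz`, `dose.nii.gz`, one `mask_<name>.nii.gz` per structure
#' (uint8) and a `manifest.yaml` recording the structure order, roles,
#' prescription and voxel spacing. The round trip through
#' [read_nifti_case()] is lossless for values and spacing.
#'
#' @param case a [plan_case()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_nifti_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pd <- RNifti::asNifti(case$ct, pixdim = case$spacing)
  RNifti::writeNifti(pd, file.path(dir, "ct.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(case$reference_dose$values, pixdim = case$spacing),
                     file.path(dir, "dose.nii.gz"))
  for (nm in names(case$structures$masks)) {
    m <- case$structures$masks[[nm]]
    storage.mode(m) <- "integer"
    RNifti::writeNifti(RNifti::asNifti(m, pixdim = case$spacing, datatype = "uint8"),
                       file.path(dir, paste0("mask_", nm, ".nii.gz")))
  }
  manifest <- list(
    case_id = case$case_id,
    prescription = case$prescription,
    spacing = as.numeric(case$spacing),
    structures = lapply(names(case$structures$masks), function(nm)
      list(name = nm, role = unname(case$structures$roles[nm])))
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a plan case from NIfTI volumes
#'
#' Counterpart of [write_nifti_case()]; expects the manifest plus one NIfTI
#' file per volume, all with identical dimensions.
#'
#' @param dir case directory.
#' @return A [plan_case()].
#' @export
read_nifti_case <- function(dir) {
  mf <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  ct <- read_nifti_array(file.path(dir, "ct.nii.gz"))
  dose <- read_nifti_array(file.path(dir, "dose.nii.gz"))
  masks <- list(); roles <- character()
  for (s in mf$structures) {
    m <- read_nifti_array(file.path(dir, paste0("mask_", s$name, ".nii.gz")))
    if (!identical(dim(m), dim(ct)))
      stop("format error: mask_", s$name, ".nii.gz does not match the ct grid")
    masks[[s$name]] <- (m != 0) * 1
    roles[s$name] <- s$role
  }
  if (!identical(dim(dose), dim(ct)))
    stop("format error: dose.nii.gz does not match the ct grid")
  spacing <- as.numeric(mf$spacing)
  plan_case(ct, structure_set(masks, roles),
            dose_volume(dose, spacing = spacing),
            prescription = mf$prescription, case_id = mf$case_id, spacing = spacing)
}

read_nifti_array <- function(path) {
  if (!file.exists(path)) stop("format error: missing file ", path)
  v <- RNifti::readNifti(path)
  array(as.numeric(v), dim(v))
}

# OpenKBP-style sparse CSV cases live on a fixed 128^3 grid.
openkbp_grid <- c(128L, 128L, 128L)

#' Read a case in the OpenKBP sparse-CSV layout
#'
#' One directory per case holding `ct.csv`, `dose.csv`,
#' `possible_dose_mask.csv` and one CSV per structure. Value-carrying volumes
#' (`ct`, `dose`) store `index,value` rows; masks store one voxel index per
#' row. Indices are 0-based flattened positions on the fixed 128x128x128 grid
#' in C order with the third axis fastest
#' (`index = x * 128^2 + y * 128 + z`). Unlisted voxels are zero. The
#' prescription of every public head-and-neck case is 70 Gy (35 fractions).
#'
#' @param path case directory.
#' @param target_roles named roles; defaults tag `PTV*` as targets.
#' @return A [plan_case()] on a dense 128^3 grid.
#' @export
read_openkbp_case <- function(path, target_roles = NULL) {
  files <- list.files(path, pattern = "\\.csv$", full.names = FALSE)
  if (!"ct.csv" %in% files) stop("format error: ", file.path(path, "ct.csv"), " is missing")
  if (!"dose.csv" %in% files) stop("format error: ", file.path(path, "dose.csv"), " is missing")
  ct <- read_sparse_volume(file.path(path, "ct.csv"), values = TRUE)
  dose <- read_sparse_volume(file.path(path, "dose.csv"), values = TRUE)
  struct_files <- setdiff(files, c("ct.csv", "dose.csv", "possible_dose_mask.csv"))
  if (length(struct_files) == 0) stop("format error: no structure CSVs in ", path)
  masks <- list()
  for (f in struct_files) {
    nm <- sub("\\.csv$", "", f)
    masks[[nm]] <- read_sparse_volume(file.path(path, f), values = FALSE)
  }
  roles <- if (is.null(target_roles)) {
    setNames(ifelse(grepl("^PTV", names(masks), ignore.case = TRUE), "target", "oar"),
             names(masks))
  } else target_roles
  plan_case(ct, structure_set(masks, roles), dose_volume(dose),
            prescription = 70, case_id = basename(path))
}

#' Write a case in the OpenKBP sparse-CSV layout
#'
#' Inverse of [read_openkbp_case()]; only nonzero voxels are listed, sorted by
#' flattened index.
#'
#' @param case a [plan_case()] on a 128^3 grid.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_openkbp_case <- function(case, dir) {
  if (!identical(dim(case$ct), as.integer(openkbp_grid)))
    stop("OpenKBP cases must be on a 128x128x128 grid")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sparse_volume(case$ct, file.path(dir, "ct.csv"), values = TRUE)
  write_sparse_volume(case$reference_dose$values, file.path(dir, "dose.csv"), values = TRUE)
  for (nm in names(case$structures$masks)) {
    write_sparse_volume(case$structures$masks[[nm]],
                        file.path(dir, paste0(nm, ".csv")), values = FALSE)
  }
  invisible(dir)
}

# flattened C-order index (z fastest) <-> array positions on the 128^3 grid
flat_to_xyz <- function(idx) {
  z <- idx %% 128L
  y <- (idx %/% 128L) %% 128L
  x <- idx %/% (128L * 128L)
  cbind(x, y, z) + 1L
}
xyz_to_flat <- function(x, y, z) (x - 1L) * 128L * 128L + (y - 1L) * 128L + (z - 1L)

read_sparse_volume <- function(file, values) {
  v <- array(0, openkbp_grid)
  dat <- tryCatch(read.csv(file, header = TRUE),
                  error = function(e) stop("format error in ", file, ": ", conditionMessage(e)))
  if (nrow(dat) == 0) return(v)
  idx <- as.integer(dat[[1]])
  if (anyNA(idx) || any(idx < 0) || any(idx >= prod(openkbp_grid)))
    stop("format error in ", file, ": voxel indices out of range")
  pos <- flat_to_xyz(idx)
  lin <- pos[, 1] + 128L * (pos[, 2] - 1L) + 128L * 128L * (pos[, 3] - 1L)
  v[lin] <- if (values) {
    if (ncol(dat) < 2) stop("format error in ", file, ": missing value column")
    as.numeric(dat[[2]])
  } else 1
  v
}

write_sparse_volume <- function(v, file, values) {
  nz <- which(v != 0)
  pos <- arrayInd(nz, dim(v))
  idx <- xyz_to_flat(pos[, 1], pos[, 2], pos[, 3])
  ord <- order(idx)
  if (values) {
    write.csv(data.frame(index = idx[ord], value = v[nz][ord]), file, row.names = FALSE)
  } else {
    write.csv(data.frame(index = idx[ord]), file, row.names = FALSE)
  }
  invisible(file)
}
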