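#' Write a cohort to disk as NIfTI volumes plus a manifest
#'
#' Writes each subject's intensity volume and any masks as NIfTI-1 files with
#' correct voxel-size metadata, together with a CSV manifest recording subject
#' id, group, file paths and true volumes. Intensities are stored as float64 so
#' the round trip is lossless; masks as uint8.
#'
#' @param volumes list of [labeled_volume()] objects.
#' @param directory output directory (created if missing).
#' @return Path of the manifest CSV, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(volumes, directory) {
  stopifnot(length(volumes) > 0)
  ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop_param("cannot create output directory '%s'", directory)
  rows <- lapply(seq_along(volumes), function(i) {
    v <- volumes[[i]]
    id <- if (is.na(v$subject_id)) sprintf("sub%03d", i) else v$subject_id
    write_one <- function(arr, suffix, datatype) {
      path <- file.path(directory, paste0(id, suffix))
      RNifti::pixdim(arr) <- v$voxel_size
      RNifti::writeNifti(arr, path, datatype = datatype)
      path
    }
    t1w <- write_one(v$intensity, "_T1w.nii.gz", "double")
    tgt <- if (!is.null(v$target_mask))
      write_one(v$target_mask + 0L, "_target-mask.nii.gz", "uint8") else NA
    icv <- if (!is.null(v$icv_mask))
      write_one(v$icv_mask + 0L, "_icv-mask.nii.gz", "uint8") else NA
    data.frame(subject_id = id, group = v$group,
               t1w = basename(t1w),
               target_mask = ifelse(is.na(tgt), NA, basename(tgt)),
               icv_mask = ifelse(is.na(icv), NA, basename(icv)),
               true_target_volume_mm3 = v$true_target_volume,
               true_icv_volume_mm3 = v$true_icv_volume,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(directory, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest path to a manifest CSV (or its directory).
#' @return List of [labeled_volume()] objects.
#' @export
read_cohort <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.csv")
  if (!file.exists(manifest)) stop_param("manifest not found: '%s'", manifest)
  tab <- read.csv(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  lapply(seq_len(nrow(tab)), function(i) {
    img <- RNifti::readNifti(file.path(dir, tab$t1w[i]))
    vs <- RNifti::pixdim(img)
    arr <- as.array(img)
    attributes(arr) <- list(dim = dim(arr))
    read_mask <- function(col) {
      if (is.na(tab[[col]][i])) return(NULL)
      m <- as.array(RNifti::readNifti(file.path(dir, tab[[col]][i])))
      attributes(m) <- list(dim = dim(m))
      m > 0
    }
    v <- labeled_volume(arr, target_mask = read_mask("target_mask"),
                        icv_mask = read_mask("icv_mask"),
                        voxel_size = vs,
                        subject_id = tab$subject_id[i],
                        group = tab$group[i])
    v
  })
}
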