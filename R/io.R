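# Cohort serialization: HDF5 (one group per subject) and per-subject CSV
# (rows = samples, columns = ROIs) with a JSON metadata sidecar.

#' Write a cohort to HDF5
#'
#' Layout: one group per subject holding a `data` dataset (ROIs x
#' samples) and `class`, `fs`, `roi_labels` attributes; file-level
#' `roi_labels` attribute records the canonical order.
#'
#' @param cohort A `megcoh_cohort`.
#' @param path Output .h5 path (overwritten).
#' @return `path`, invisibly.
#' @export
write_cohort_h5 <- function(cohort, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  rhdf5::h5writeAttribute(cohort$roi_labels, fid, "roi_labels")
  for (subj in cohort$subjects) {
    g <- subj$subject_id
    rhdf5::h5createGroup(fid, g)
    rhdf5::h5write(subj$data, fid, paste0(g, "/data"))
    gid <- rhdf5::H5Gopen(fid, g)
    rhdf5::h5writeAttribute(subj$class_label, gid, "class")
    rhdf5::h5writeAttribute(subj$fs, gid, "fs")
    rhdf5::h5writeAttribute(cohort$roi_labels, gid, "roi_labels")
    rhdf5::H5Gclose(gid)
  }
  invisible(path)
}

#' Read a cohort from HDF5
#'
#' @param path .h5 file written by [write_cohort_h5()].
#' @return A `megcoh_cohort` (with `params` set to a provenance note).
#' @export
read_cohort_h5 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  labels <- as.character(rhdf5::h5readAttributes(path, "/")$roi_labels)
  if (length(labels) == 0L) stop("missing file-level 'roi_labels' attribute")
  groups <- rhdf5::h5ls(path, recursive = FALSE)
  groups <- groups$name[groups$otype == "H5I_GROUP"]
  subjects <- lapply(groups, function(g) {
    at <- rhdf5::h5readAttributes(path, g)
    for (field in c("class", "fs")) {
      if (is.null(at[[field]])) {
        stop("subject group '", g, "' is missing the '", field,
             "' attribute")
      }
    }
    d <- rhdf5::h5read(path, paste0(g, "/data"))
    rownames(d) <- labels
    structure(list(subject_id = g, class_label = as.character(at$class),
                   fs = as.numeric(at$fs), data = d),
              class = "megcoh_subject")
  })
  structure(list(subjects = subjects,
                 params = list(provenance = paste0("read from ", path)),
                 roi_labels = labels),
            class = "megcoh_cohort")
}

#' Write a cohort as per-subject CSV plus JSON sidecars
#'
#' Each subject yields `<id>.csv` (rows = samples, columns = ROIs, 17
#' significant digits) and `<id>.json` with `subject_id`, `class_label`,
#' `fs`, `roi_labels`.
#'
#' @param cohort A `megcoh_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (subj in cohort$subjects) {
    df <- as.data.frame(t(subj$data))
    utils::write.csv(format(df, digits = 17, scientific = TRUE),
                     file.path(dir, paste0(subj$subject_id, ".csv")),
                     row.names = FALSE, quote = FALSE)
    meta <- list(subject_id = subj$subject_id,
                 class_label = subj$class_label, fs = subj$fs,
                 roi_labels = cohort$roi_labels)
    jsonlite::write_json(meta, file.path(dir, paste0(subj$subject_id, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort from per-subject CSV + JSON sidecars
#'
#' Columns are matched to the canonical ROI order by header label, so
#' reordered CSVs are accepted.
#'
#' @param dir Directory written by [write_cohort_csv()].
#' @return A `megcoh_cohort`.
#' @export
read_cohort_csv <- function(dir) {
  metas <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (length(metas) == 0L) stop("no subject .json sidecars in ", dir)
  labels <- NULL
  subjects <- lapply(metas, function(mp) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    for (field in c("subject_id", "class_label", "fs", "roi_labels")) {
      if (is.null(meta[[field]])) {
        stop("sidecar ", basename(mp), " is missing the '", field,
             "' field")
      }
    }
    if (is.null(labels)) labels <<- meta$roi_labels
    df <- utils::read.csv(sub("\\.json$", ".csv", mp), check.names = FALSE)
    if (!setequal(colnames(df), meta$roi_labels)) {
      stop("CSV columns of ", meta$subject_id,
           " do not match the ROI labels in its sidecar")
    }
    d <- t(as.matrix(df[, meta$roi_labels]))
    structure(list(subject_id = meta$subject_id,
                   class_label = meta$class_label,
                   fs = meta$fs, data = d),
              class = "megcoh_subject")
  })
  structure(list(subjects = subjects,
                 params = list(provenance = paste0("read from ", dir)),
                 roi_labels = labels),
            class = "megcoh_cohort")
}
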