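#' @include AllClasses.R AllGenerics.R
NULL

#' Write a movement dataset to delimited text
#'
#' Writes one CSV matrix per subject (columns = channels, header row with the
#' channel names) plus a `manifest.csv` listing subject id, group, sampling
#' rate, height, handedness and the per-subject file path. Values are written
#' at full double precision so that [readDataset()] round-trips bit-exactly.
#'
#' @param ds a \linkS4class{MovementDataset}.
#' @param dir output directory; created if absent.
#' @return the manifest path, invisibly.
#' @seealso [readDataset()]
#' @export
writeDataset <- function(ds, dir) {
  stopifnot(is(ds, "MovementDataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(profiles(ds), function(p) {
    file <- paste0(p@subjectID, ".csv")
    mat <- p@channels
    txt <- do.call(paste, c(
      lapply(seq_len(ncol(mat)), function(j) sprintf("%.17g", mat[, j])),
      list(sep = ",")))
    writeLines(c(paste(colnames(mat), collapse = ","), txt),
               file.path(dir, file))
    data.frame(subject_id = p@subjectID, group = p@group,
               rate_hz = p@rateHz, height = p@height,
               handedness = ifelse(is.na(p@handedness), "", p@handedness),
               file = file, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifestPath <- file.path(dir, "manifest.csv")
  numCols <- c("rate_hz", "height")
  out <- manifest
  for (cc in numCols) out[[cc]] <- sprintf("%.17g", manifest[[cc]])
  utils::write.csv(out, manifestPath, row.names = FALSE, quote = FALSE)
  invisible(manifestPath)
}

#' Read a movement dataset from a manifest
#'
#' Inverse of [writeDataset()]: reads the manifest and every referenced
#' per-subject channel matrix.
#'
#' @param manifestPath path to a `manifest.csv` written by [writeDataset()].
#' @return a \linkS4class{MovementDataset}.
#' @export
readDataset <- function(manifestPath) {
  if (!file.exists(manifestPath)) stop("manifest not found: ", manifestPath)
  man <- utils::read.csv(manifestPath, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character"))
  if (anyDuplicated(man$subject_id))
    stop("duplicate subject ids in manifest")
  dir <- dirname(manifestPath)
  header <- NULL
  prof <- lapply(seq_len(nrow(man)), function(i) {
    path <- file.path(dir, man$file[i])
    if (!file.exists(path)) stop("profile file missing: ", path)
    mat <- as.matrix(utils::read.csv(path, check.names = FALSE))
    if (is.null(header)) header <<- colnames(mat)
    if (!identical(colnames(mat), header))
      stop("inconsistent channel headers in ", path)
    hd <- man$handedness[i]
    new("MovementProfile", subjectID = man$subject_id[i],
        group = as.integer(man$group[i]), channels = mat,
        rateHz = man$rate_hz[i], height = as.numeric(man$height[i]),
        handedness = if (is.na(hd) || !nzchar(hd)) NA_character_ else hd)
  })
  new("MovementDataset", profiles = prof,
      metadata = list(manifest = manifestPath))
}

#' Restrict a dataset to the channels of one hand
#'
#' Selects the six positional channels of a single hand and strips the hand
#' suffix from the channel names, so that datasets recorded for different
#' hands become comparable (as required by the cross-study transfer
#' protocol, where training uses right-hand movements and each validation
#' subject contributes the hand matching their handedness).
#'
#' @param ds a \linkS4class{MovementDataset} whose channel names end in
#'   `_left` / `_right`.
#' @param hand `"right"`, `"left"`, or `"by_handedness"` (per-subject choice
#'   from the profile's handedness flag).
#' @return a \linkS4class{MovementDataset} with channels
#'   `global_x, global_y, global_z, local_x, local_y, local_z`.
#' @export
selectHandChannels <- function(ds, hand = c("right", "left",
                                            "by_handedness")) {
  hand <- match.arg(hand)
  prof <- lapply(profiles(ds), function(p) {
    h <- if (hand == "by_handedness") {
      if (is.na(p@handedness))
        stop("subject ", p@subjectID, " has no handedness flag")
      p@handedness
    } else hand
    want <- paste(c("global_x", "global_y", "global_z",
                    "local_x", "local_y", "local_z"), h, sep = "_")
    missing <- setdiff(want, colnames(p@channels))
    if (length(missing))
      stop("subject ", p@subjectID, " lacks channels: ",
           paste(missing, collapse = ", "))
    mat <- p@channels[, want, drop = FALSE]
    colnames(mat) <- sub("_(left|right)$", "", colnames(mat))
    initialize(p, channels = mat)
  })
  new("MovementDataset", profiles = prof, metadata = ds@metadata)
}

#' Restrict a dataset to named channels
#'
#' @param ds a \linkS4class{MovementDataset}.
#' @param channels channel names to keep (order preserved as given).
#' @return the restricted dataset.
#' @export
selectChannels <- function(ds, channels) {
  prof <- lapply(profiles(ds), function(p) {
    missing <- setdiff(channels, colnames(p@channels))
    if (length(missing))
      stop("unknown channels: ", paste(missing, collapse = ", "))
    initialize(p, channels = p@channels[, channels, drop = FALSE])
  })
  new("MovementDataset", profiles = prof, metadata = ds@metadata)
}
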