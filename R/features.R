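#' @include AllClasses.R AllGenerics.R
NULL

#' Basic summary features of a channel matrix
#'
#' Per channel, in fixed order: mean, standard deviation (population
#' convention, divisor N), minimum and maximum — the four "basic features"
#' used throughout the classification protocols. A matrix with C channels
#' yields 4 C features named `<channel>_{mean,sd,min,max}`.
#'
#' @param mat numeric T x C matrix (a whole profile or a segment).
#' @param channels optional channel names; defaults to `colnames(mat)`.
#' @return named numeric vector of length 4 C.
#' @examples
#' basicFeatures(cbind(a = c(1, 2, 3)))
#' @export
basicFeatures <- function(mat, channels = colnames(mat)) {
  if (!is.matrix(mat) || nrow(mat) < 1L || ncol(mat) < 1L)
    stop("mat must be a non-empty matrix")
  if (is.null(channels)) stop("channel names required")
  out <- numeric(4L * ncol(mat))
  n <- nrow(mat)
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    m <- sum(x) / n
    idx <- (j - 1L) * 4L
    out[idx + 1L] <- m
    out[idx + 2L] <- sqrt(max(sum(x * x) / n - m * m, 0))
    r <- range(x)
    out[idx + 3L] <- r[1]
    out[idx + 4L] <- r[2]
  }
  names(out) <- paste0(rep(channels, each = 4L),
                       c("_mean", "_sd", "_min", "_max"))
  out
}

# segment basic features computed straight from the profiles, without
# materialising Segment objects (hot path of the segmental protocols)
fastSegmentFeatures <- function(ds, W, m, seed) {
  W <- as.integer(W)
  cn <- channelNames(ds)
  p <- 4L * length(cn)
  nSeg <- length(ds) * m
  feats <- matrix(0, nSeg, p)
  labels <- integer(nSeg)
  subj <- character(nSeg)
  withSeed(seed, {
    k <- 0L
    for (pr in profiles(ds)) {
      T <- nrow(pr@channels)
      if (T < W)
        stop(sprintf("subject '%s' has only %d time points (< W = %d)",
                     pr@subjectID, T, W))
      starts <- sample.int(T - W + 1L, m, replace = TRUE) - 1L
      for (s in starts) {
        k <- k + 1L
        feats[k, ] <- basicFeatures(
          pr@channels[(s + 1L):(s + W), , drop = FALSE], cn)
        labels[k] <- pr@group
        subj[k] <- pr@subjectID
      }
    }
  })
  colnames(feats) <- paste0(rep(cn, each = 4L),
                            c("_mean", "_sd", "_min", "_max"))
  new("LabeledFeatureSet", features = feats, labels = labels,
      subjectIDs = subj)
}

#' Whole-profile basic-feature set of a dataset
#'
#' @param ds a \linkS4class{MovementDataset}.
#' @return a \linkS4class{LabeledFeatureSet} with one row per subject and
#'   4 C columns.
#' @export
basicFeatureSet <- function(ds) {
  stopifnot(is(ds, "MovementDataset"))
  feats <- t(vapply(profiles(ds), function(p) basicFeatures(p@channels),
                    numeric(4L * length(channelNames(ds)))))
  new("LabeledFeatureSet", features = feats, labels = groupLabels(ds),
      subjectIDs = subjectIDs(ds))
}

#' Per-channel principal component analysis of whole profiles
#'
#' For each channel separately, performs a PCA of the n x T matrix whose
#' rows are the subjects' trajectories for that channel (observations =
#' subjects, variables = time points), retaining the first `k` components.
#' Centering only (the per-time-point training mean trajectory is
#' subtracted); no scaling. Computed via singular-value decomposition, so
#' n < T is handled naturally. Loadings are sign-fixed so that each
#' component's largest-magnitude entry is positive.
#'
#' The PCA is fitted on the profiles exactly as supplied — the evaluation
#' protocols pass the unstandardized training profiles.
#'
#' @param trainDs a \linkS4class{MovementDataset} whose profiles all share
#'   the same length T; n >= 2.
#' @param k components per channel; must satisfy `k <= min(n - 1, T)`.
#' @return a \linkS4class{ChannelPCAModel}.
#' @seealso [projectPCA()]
#' @export
fitChannelPCA <- function(trainDs, k = 4L) {
  stopifnot(is(trainDs, "MovementDataset"))
  n <- length(trainDs)
  if (n < 2L) stop("need at least two training profiles")
  Ts <- vapply(profiles(trainDs), function(p) nrow(p@channels), integer(1))
  if (length(unique(Ts)) != 1L)
    stop("all training profiles must have equal length")
  T <- Ts[1]
  if (k > min(n - 1L, T))
    stop(sprintf("k = %d exceeds min(n - 1, T) = %d", k, min(n - 1L, T)))
  cn <- channelNames(trainDs)
  loadings <- centers <- evr <- setNames(vector("list", length(cn)), cn)
  for (ch in cn) {
    X <- t(vapply(profiles(trainDs), function(p) p@channels[, ch],
                  numeric(T)))
    ctr <- colMeans(X)
    Xc <- sweep(X, 2L, ctr)
    sv <- svd(Xc, nu = 0, nv = k)
    L <- sv$v[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
      if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
    }
    tot <- sum(sv$d^2)
    loadings[[ch]] <- L
    centers[[ch]] <- ctr
    evr[[ch]] <- if (tot > 0) sv$d[seq_len(k)]^2 / tot else rep(0, k)
  }
  new("ChannelPCAModel", loadings = loadings, centers = centers, evr = evr,
      k = as.integer(k), T = as.integer(T))
}

#' Project profiles into a fitted per-channel PCA space
#'
#' Scores are `(trajectory - training mean) %*% loadings` per channel,
#' concatenated across channels; projecting the training set itself
#' reproduces the training scores.
#'
#' @param model a \linkS4class{ChannelPCAModel}.
#' @param ds a \linkS4class{MovementDataset} whose profiles have the
#'   training length and channel set.
#' @return a \linkS4class{LabeledFeatureSet} with `k * C` columns named
#'   `<channel>_pc<j>`.
#' @export
projectPCA <- function(model, ds) {
  stopifnot(is(model, "ChannelPCAModel"), is(ds, "MovementDataset"))
  cn <- names(model@loadings)
  if (!all(cn %in% channelNames(ds)))
    stop("dataset lacks channels of the PCA model")
  rows <- lapply(profiles(ds), function(p) {
    if (nrow(p@channels) != model@T)
      stop(sprintf("profile '%s' has length %d; PCA was trained at T = %d",
                   p@subjectID, nrow(p@channels), model@T))
    unlist(lapply(cn, function(ch) {
      sc <- as.numeric((p@channels[, ch] - model@centers[[ch]]) %*%
                         model@loadings[[ch]])
      setNames(sc, paste0(ch, "_pc", seq_along(sc)))
    }))
  })
  feats <- do.call(rbind, rows)
  new("LabeledFeatureSet", features = feats, labels = groupLabels(ds),
      subjectIDs = subjectIDs(ds))
}

#' Per-subject mean vertical position in both coordinate frames
#'
#' Extracts, for every subject, the two-feature summary (mean global y,
#' mean local y) over the full profile — the representation in which the
#' groups separate along a linear boundary.
#'
#' @param ds a \linkS4class{MovementDataset}.
#' @param hand hand suffix to use when the dataset carries per-hand channel
#'   names; ignored if the channels are already unsuffixed
#'   (`global_y` / `local_y`).
#' @return a \linkS4class{LabeledFeatureSet} with columns
#'   `mean_global_y`, `mean_local_y`.
#' @export
meanYFeatures <- function(ds, hand = "right") {
  stopifnot(is(ds, "MovementDataset"))
  cn <- channelNames(ds)
  gy <- if ("global_y" %in% cn) "global_y" else paste0("global_y_", hand)
  ly <- if ("local_y" %in% cn) "local_y" else paste0("local_y_", hand)
  if (!all(c(gy, ly) %in% cn))
    stop("dataset lacks the vertical-position channels ", gy, " / ", ly)
  feats <- t(vapply(profiles(ds), function(p)
    c(mean_global_y = mean(p@channels[, gy]),
      mean_local_y = mean(p@channels[, ly])), numeric(2)))
  new("LabeledFeatureSet", features = feats, labels = groupLabels(ds),
      subjectIDs = subjectIDs(ds))
}

#' Write a feature set to CSV
#'
#' Columns are the feature names plus `label` and `subject_id`.
#'
#' @param fs a \linkS4class{LabeledFeatureSet}.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFeatureSet <- function(fs, path) {
  df <- as.data.frame(fs@features)
  df$label <- fs@labels
  df$subject_id <- fs@subjectIDs
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
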