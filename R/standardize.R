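#' @include AllClasses.R AllGenerics.R
NULL

#' Fit pooled standardization parameters
#'
#' Computes, for every channel, the mean and standard deviation pooled over
#' all subjects and all time points of the dataset (population SD, divisor
#' N). The evaluation protocols fit these parameters separately on the
#' training and the test side, mirroring the study's train/test-separate
#' standardization.
#'
#' With `scope = "global"` a single scalar mean/SD pooled over all channels
#' is used instead (the alternative reading of "overall mean"); the default
#' per-channel scope keeps channels on different physical scales
#' comparable.
#'
#' @param ds a non-empty \linkS4class{MovementDataset}.
#' @param scope `"channel"` (default) or `"global"`.
#' @return a \linkS4class{StandardizationParams}.
#' @examples
#' cfg <- syntheticConfig(nGroup0 = 2, nGroup1 = 2, T = 50, seed = 1)
#' ds <- generateDataset(cfg)
#' fitStandardizer(ds)
#' @export
fitStandardizer <- function(ds, scope = c("channel", "global")) {
  scope <- match.arg(scope)
  stopifnot(is(ds, "MovementDataset"))
  if (!length(ds)) stop("dataset is empty")
  stacked <- do.call(rbind, lapply(profiles(ds), channelMatrix))
  cn <- colnames(stacked)
  if (scope == "channel") {
    m <- colMeans(stacked)
    s <- apply(stacked, 2L, popSD)
  } else {
    m <- rep(mean(stacked), ncol(stacked))
    s <- rep(popSD(as.vector(stacked)), ncol(stacked))
    names(m) <- names(s) <- cn
  }
  zero <- s <= 0 | !is.finite(s)
  if (any(zero))
    stop("zero-variance channel(s): ", paste(cn[zero], collapse = ", "))
  new("StandardizationParams", mean = m, sd = s, scope = scope)
}

#' Apply standardization parameters to a dataset
#'
#' Transforms every channel of every profile to `(x - mean) / sd` using the
#' supplied pooled parameters; shapes and metadata are preserved.
#'
#' @param ds a \linkS4class{MovementDataset}.
#' @param params a \linkS4class{StandardizationParams} whose channel names
#'   match the dataset's.
#' @return the standardized \linkS4class{MovementDataset}.
#' @export
applyStandardizer <- function(ds, params) {
  stopifnot(is(ds, "MovementDataset"), is(params, "StandardizationParams"))
  cn <- channelNames(ds)
  if (!identical(cn, names(params@mean)))
    stop("channel mismatch between dataset and standardization parameters")
  m <- params@mean
  s <- params@sd
  prof <- lapply(profiles(ds), function(p) {
    mat <- sweep(sweep(p@channels, 2L, m, "-"), 2L, s, "/")
    initialize(p, channels = mat)
  })
  new("MovementDataset", profiles = prof, metadata = ds@metadata)
}
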