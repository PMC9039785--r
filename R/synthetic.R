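#' @include AllClasses.R AllGenerics.R
NULL

#' Configuration of the synthetic movement generator
#'
#' Describes a synthetic study: group sizes, profile length and sampling
#' rate, the planted group effect, and the stochastic structure of the
#' simulated hand trajectories. Two linked coordinate systems are emulated:
#' each *local* (height-relative) axis is a smooth stationary latent process
#' plus a subject-specific offset and white observation noise, and the
#' *global* (laboratory) axis equals the local axis plus a per-subject
#' offset — for the vertical (y) axis an affine function of subject height,
#' `c0 + c1 * height`, so that per-subject mean global and local y positions
#' lie near a unit-slope line with height-driven scatter.
#'
#' The group effect shifts the mean of the channels named in
#' `effectChannels` (default: local vertical position) upward for group 0
#' by `effectDelta` pooled channel standard deviations, mirroring the
#' observation that the control group sustains a higher relative vertical
#' hand position.
#'
#' @param nGroup0,nGroup1 subjects per group (>= 1).
#' @param T time points per profile; a length-2 integer range means each
#'   subject's length is drawn uniformly from it (variable-duration mode).
#' @param rateHz sampling frequency in Hz.
#' @param effectDelta size of the planted group shift, in units of the
#'   pooled (over subjects and time) channel SD; >= 0.
#' @param smoothness correlation length of the latent trajectories, in time
#'   points (the moving-average window).
#' @param noiseSD observation noise SD.
#' @param subjectSD SD of the per-subject constant offset of each local axis
#'   (between-subject variability of mean position).
#' @param trajSD SD of the smooth latent trajectory.
#' @param heightMean,heightSD subject height distribution (metres).
#' @param hands `"right"`, `"left"` or `"both"` (6 or 12 channels).
#' @param c0,c1 coefficients of the height-dependent vertical offset
#'   between the global and local frame: offset_y = c0 + c1 * height.
#' @param stanceSD SD of the per-subject constant global-frame offset of the
#'   horizontal axes (x, z).
#' @param leftFraction fraction of left-handed subjects in variable-duration
#'   (study-2) mode; default 4/43.
#' @param effectChannels base channel names (without hand suffix) that carry
#'   the group shift; default `"local_y"`.
#' @param seed master integer seed; all generation is deterministic given it.
#' @return a `SyntheticConfig` object.
#' @examples
#' cfg <- syntheticConfig(nGroup0 = 3, nGroup1 = 3, T = 100, seed = 1)
#' ds <- generateDataset(cfg)
#' ds
#' @export
syntheticConfig <- function(nGroup0 = 35L, nGroup1 = 37L, T = 4970L,
                            rateHz = 10, effectDelta = 1.0,
                            smoothness = 30L, noiseSD = 0.1,
                            subjectSD = 0.15, trajSD = 1.0,
                            heightMean = 1.75, heightSD = 0.09,
                            hands = c("right", "left", "both"),
                            c0 = 0, c1 = 5, stanceSD = 0.3,
                            leftFraction = 4 / 43,
                            effectChannels = "local_y",
                            seed = 1L) {
  hands <- match.arg(hands)
  if (nGroup0 < 1L || nGroup1 < 1L) stop("both groups must have >= 1 subject")
  if (any(T < 2L)) stop("T must be >= 2")
  if (!length(T) %in% c(1L, 2L)) stop("T must be a scalar or a length-2 range")
  if (effectDelta < 0) stop("effectDelta must be >= 0")
  if (noiseSD < 0) stop("noiseSD must be >= 0")
  if (rateHz <= 0) stop("rateHz must be positive")
  if (smoothness < 1L) stop("smoothness must be >= 1")
  structure(list(
    nGroup0 = as.integer(nGroup0), nGroup1 = as.integer(nGroup1),
    T = as.integer(T), rateHz = rateHz, effectDelta = effectDelta,
    smoothness = as.integer(smoothness), noiseSD = noiseSD,
    subjectSD = subjectSD, trajSD = trajSD,
    heightMean = heightMean, heightSD = heightSD, hands = hands,
    c0 = c0, c1 = c1, stanceSD = stanceSD, leftFraction = leftFraction,
    effectChannels = effectChannels, seed = as.integer(seed)
  ), class = "SyntheticConfig")
}

#' @export
print.SyntheticConfig <- function(x, ...) {
  cat(sprintf(
    "SyntheticConfig: %d + %d subjects, T = %s @ %g Hz, delta = %g (%s)\n",
    x$nGroup0, x$nGroup1, paste(x$T, collapse = "-"), x$rateHz,
    x$effectDelta, paste(x$effectChannels, collapse = ", ")))
  invisible(x)
}

# pooled channel SD implied by the generative model; the scale of effectDelta
impliedChannelSD <- function(cfg) {
  sqrt(cfg$trajSD^2 + cfg$subjectSD^2 + cfg$noiseSD^2)
}

# smooth stationary latent trajectory: moving-average-filtered white noise,
# rescaled to SD = trajSD
smoothLatent <- function(T, smoothness, trajSD) {
  L <- min(smoothness, T)
  w <- stats::rnorm(T + L - 1L)
  s <- as.numeric(stats::filter(w, rep(1 / L, L), sides = 1))[L:(T + L - 1L)]
  s * sqrt(L) * trajSD
}

#' Generate one synthetic movement profile
#'
#' Draws a single subject's T x C channel matrix under the generative model
#' of [syntheticConfig()]. Deterministic given `(cfg$seed, subjectSeed)`.
#'
#' @param cfg a `SyntheticConfig`.
#' @param group 0 or 1.
#' @param subjectSeed integer; per-subject randomness stream.
#' @param subjectID identifier; default derived from the seed.
#' @param handedness optional override (`"left"`/`"right"`); defaults to
#'   right.
#' @return a \linkS4class{MovementProfile} with 6 channels per requested
#'   hand, named `{global|local}_{x|y|z}_{left|right}`.
#' @export
generateProfile <- function(cfg, group, subjectSeed,
                            subjectID = sprintf("subj%d", subjectSeed),
                            handedness = "right") {
  if (!inherits(cfg, "SyntheticConfig")) stop("cfg must be a SyntheticConfig")
  if (!length(group) == 1L || !group %in% c(0, 1))
    stop("group must be 0 or 1")
  if (any(cfg$T <= 0L)) stop("T must be positive")
  combined <- (as.numeric(cfg$seed) * 1000003 + as.numeric(subjectSeed)) %%
    2147483647
  withSeed(as.integer(combined), {
    T <- if (length(cfg$T) == 2L) {
      sample(cfg$T[1]:cfg$T[2], 1L)
    } else cfg$T
    height <- stats::rnorm(1L, cfg$heightMean, cfg$heightSD)
    handsUsed <- if (cfg$hands == "both") c("left", "right") else cfg$hands
    shift <- if (group == 0) cfg$effectDelta * impliedChannelSD(cfg) else 0
    cols <- list()
    for (h in handsUsed) {
      for (ax in c("x", "y", "z")) {
        latent <- smoothLatent(T, cfg$smoothness, cfg$trajSD)
        intercept <- stats::rnorm(1L, 0, cfg$subjectSD)
        noise <- if (cfg$noiseSD > 0) stats::rnorm(T, 0, cfg$noiseSD) else 0
        loc <- latent + intercept + noise
        base <- paste0("local_", ax)
        if (base %in% cfg$effectChannels) loc <- loc + shift
        offset <- if (ax == "y") cfg$c0 + cfg$c1 * height else
          stats::rnorm(1L, 0, cfg$stanceSD)
        glo <- loc + offset
        if (paste0("global_", ax) %in% cfg$effectChannels)
          glo <- glo + shift
        cols[[paste0("global_", ax, "_", h)]] <- glo
        cols[[paste0("local_", ax, "_", h)]] <- loc
      }
    }
    ord <- as.vector(outer(
      c("global_x", "global_y", "global_z", "local_x", "local_y", "local_z"),
      handsUsed, paste, sep = "_"))
    mat <- do.call(cbind, cols[ord])
    new("MovementProfile", subjectID = subjectID, group = as.integer(group),
        channels = mat, rateHz = cfg$rateHz, height = height,
        handedness = handedness)
  })
}

#' Generate a full synthetic movement dataset
#'
#' Produces `nGroup0 + nGroup1` profiles under the model of
#' [syntheticConfig()]. In `"study1"` mode every profile has the fixed
#' length `cfg$T`; in `"study2"` mode per-subject lengths are drawn
#' uniformly from the configured range and a fraction of subjects
#' (default 4/43) is marked left-handed. Bit-identical output for identical
#' configuration and seed.
#'
#' @param cfg a `SyntheticConfig`.
#' @param mode `"study1"` (fixed length) or `"study2"` (variable length,
#'   handedness flags).
#' @return a \linkS4class{MovementDataset}.
#' @export
generateDataset <- function(cfg, mode = c("study1", "study2")) {
  mode <- match.arg(mode)
  if (!inherits(cfg, "SyntheticConfig")) stop("cfg must be a SyntheticConfig")
  if (cfg$nGroup0 < 1L || cfg$nGroup1 < 1L) stop("empty group")
  if (mode == "study1" && length(cfg$T) != 1L)
    stop("study1 mode requires a fixed scalar T")
  n <- cfg$nGroup0 + cfg$nGroup1
  seeds <- spawnSeeds(cfg$seed, n + 1L)
  groups <- rep(c(0L, 1L), c(cfg$nGroup0, cfg$nGroup1))
  handed <- rep("right", n)
  if (mode == "study2") {
    nLeft <- round(cfg$leftFraction * n)
    if (nLeft > 0L)
      handed[withSeed(seeds[n + 1L], sample.int(n, nLeft))] <- "left"
  }
  prof <- vector("list", n)
  for (i in seq_len(n)) {
    prof[[i]] <- generateProfile(
      cfg, groups[i], seeds[i],
      subjectID = sprintf("subj%03d", i), handedness = handed[i])
  }
  new("MovementDataset", profiles = prof,
      metadata = list(mode = mode, config = unclass(cfg)))
}
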