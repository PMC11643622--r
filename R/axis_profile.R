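#' Construct an apical-basal axis profile
#'
#' An ordered set of intensity samples along a rectangular ROI drawn
#' from apical (position 0) to basal, with one intensity column per
#' antibody channel.
#'
#' @param section_id Identifier of the tissue section / ROI.
#' @param position Strictly increasing numeric positions along the axis.
#' @param channels Named list or data frame of per-position intensities.
#' @param normalized Whether the profile is already min-max normalized.
#' @return Object of class `vr_profile`.
#' @export
axis_profile <- function(section_id, position, channels,
                         normalized = FALSE) {
  channels <- as.data.frame(channels)
  if (length(position) < 2) stop("a profile needs >= 2 samples")
  if (any(diff(position) <= 0))
    stop("positions must be strictly increasing")
  if (nrow(channels) != length(position))
    stop("channel lengths do not match positions")
  structure(list(section_id = section_id, position = as.numeric(position),
                 channels = channels, normalized = normalized),
            class = "vr_profile")
}

#' @export
print.vr_profile <- function(x, ...) {
  cat("vr_profile ", x$section_id, ": ", length(x$position), " samples, ",
      "channels: ", paste(names(x$channels), collapse = ", "),
      if (x$normalized) " (normalized)", "\n", sep = "")
  invisible(x)
}

minmax <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) {
    warning("constant vector in min-max normalization; returning zeros")
    return(rep(0, length(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Min-max normalize an axis profile
#'
#' Rescales the position axis and every channel to [0, 1] via
#' x' = (x - min(x)) / (max(x) - min(x)), making ROIs of different
#' lengths and imaging sessions comparable. A constant channel maps to
#' all zeros with a warning. Idempotent.
#'
#' @param profile A `vr_profile`.
#' @return Normalized `vr_profile`.
#' @export
normalize_profile <- function(profile) {
  axis_profile(profile$section_id,
               minmax(profile$position),
               lapply(profile$channels, minmax),
               normalized = TRUE)
}

#' Fit an intensity trendline along the normalized axis
#'
#' Pools the (position, intensity) points of one channel across all
#' profiles and fits a locally weighted degree-1 regression (tricube
#' weights, tunable span), evaluated on a 101-point grid over [0, 1].
#'
#' @param profiles List of normalized `vr_profile` objects.
#' @param channel Channel name.
#' @param span Smoother span (default 0.5).
#' @return Data frame with columns position, fitted.
#' @export
fit_trendline <- function(profiles, channel, span = 0.5) {
  if (inherits(profiles, "vr_profile")) profiles <- list(profiles)
  x <- unlist(lapply(profiles, `[[`, "position"))
  y <- unlist(lapply(profiles, function(p) {
    if (!p$normalized) stop("profiles must be normalized first")
    if (!channel %in% names(p$channels))
      stop("channel ", channel, " absent from profile ", p$section_id)
    p$channels[[channel]]
  }))
  if (length(x) < 10) stop("need >= 10 pooled points to fit a trendline")
  fit <- stats::loess(y ~ x, degree = 1, span = span,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(0, 1, length.out = 101)
  data.frame(position = grid,
             fitted = as.numeric(stats::predict(fit, newdata = data.frame(x = grid))))
}

#' Rank correlation between two channel trendlines
#'
#' Spearman correlation between the fitted trendlines of two channels
#' on the common position grid; near +1 means the channels co-increase
#' along the apical-basal axis.
#'
#' @param profiles List of normalized `vr_profile` objects.
#' @param channel_a,channel_b Channel names.
#' @param span Smoother span passed to [fit_trendline].
#' @return Correlation in [-1, 1].
#' @export
channel_cotrend <- function(profiles, channel_a, channel_b, span = 0.5) {
  fa <- fit_trendline(profiles, channel_a, span = span)
  fb <- fit_trendline(profiles, channel_b, span = span)
  stats::cor(fa$fitted, fb$fitted, method = "spearman")
}

#' Read axis profiles from a long-format TSV
#'
#' @param path TSV with columns section_id, position, channel, intensity.
#' @return List of `vr_profile` objects, one per section_id.
#' @export
read_profiles <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("section_id", "position", "channel", "intensity")
  if (!all(req %in% names(df)))
    stop("validation error: profile table needs columns ",
         paste(req, collapse = ", "))
  lapply(split(df, df$section_id), function(s) {
    wide <- stats::reshape(s[, c("position", "channel", "intensity")],
                           idvar = "position", timevar = "channel",
                           direction = "wide")
    wide <- wide[order(wide$position), ]
    names(wide) <- sub("^intensity\\.", "", names(wide))
    axis_profile(s$section_id[1], wide$position,
                 wide[, -1, drop = FALSE])
  })
}

#' Write normalized profile points as a long-format TSV
#'
#' @param profiles List of `vr_profile` objects.
#' @param path Output TSV.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "vr_profile")) profiles <- list(profiles)
  long <- do.call(rbind, lapply(profiles, function(p) {
    do.call(rbind, lapply(names(p$channels), function(ch) {
      data.frame(section_id = p$section_id, position = p$position,
                 channel = ch, intensity = p$channels[[ch]],
                 stringsAsFactors = FALSE)
    }))
  }))
  write_table(long, path)
}
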