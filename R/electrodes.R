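#' Sensorimotor montage
#'
#' The 20-channel sensorimotor montage used throughout the package: three
#' rows of electrodes (frontocentral, central, centroparietal) surrounding
#' C3, Cz and C4.
#'
#' @return `smr_channels()` returns a character vector of 20 channel labels.
#' @export
smr_channels <- function() {
  c("FC5", "FC3", "FC1", "FC2", "FC4", "FC6",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6")
}

#' @rdname smr_channels
#' @return `channel_positions()` returns a tibble with columns `channel`,
#'   `x` (left negative, in electrode-spacing units) and `y` (anterior
#'   positive).
#' @export
channel_positions <- function() {
  xs <- function(labels) {
    num <- sub("^(FC|CP|C)", "", labels)
    nv <- suppressWarnings(as.numeric(num))
    nv[num == "z"] <- 0
    # odd numbers are left hemisphere
    side <- ifelse(nv == 0, 0, ifelse(nv %% 2 == 1, -1, 1))
    side * ceiling(nv / 2)
  }
  labels <- smr_channels()
  y <- c(rep(1, 6), rep(0, 7), rep(-1, 7))
  tibble(channel = labels, x = xs(labels), y = y)
}

# Gaussian gain map over the montage, centred near C3 (x = -2) or C4 (x = 2)
# with an optional lateral shift and spatial width (electrode-spacing units).
topography_gain <- function(side = c("C3", "C4"), shift = 0, width = 1.2) {
  side <- match.arg(side)
  pos <- channel_positions()
  cx <- if (side == "C3") -2 else 2
  d2 <- (pos$x - (cx + shift))^2 + pos$y^2
  g <- exp(-d2 / (2 * width^2))
  names(g) <- pos$channel
  g
}

# spatial correlation kernel for the shared background noise
background_kernel <- function(length_scale = 1.5) {
  pos <- channel_positions()
  d2 <- outer(pos$x, pos$x, "-")^2 + outer(pos$y, pos$y, "-")^2
  k <- exp(-d2 / (2 * length_scale^2))
  dimnames(k) <- list(pos$channel, pos$channel)
  k
}
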